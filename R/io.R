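## Readers/writers for the flat-file formats the pipeline consumes.  All
## tables are plain TSV (CSV for AI records); missing parents are written as
## "0" (conventional pedigree dialect), missing genotype calls as -1, and an
## empty clipped sequence as ".".

read_table_checked <- function(path, sep = "\t") {
  if (!file.exists(path))
    stop_hemidel(paste("file not found:", path), "hemidel_io_error")
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    colClasses = NA, check.names = FALSE, quote = "",
                    comment.char = "")
}

#' Read a marker map from markers.tsv
#' @param path TSV with columns marker_id, chrom, pos, allele_a, allele_b, maf.
#' @return a [marker_map()].
#' @export
read_marker_map <- function(path) {
  df <- read_table_checked(path)
  for (col in c("marker_id", "chrom", "allele_a", "allele_b"))
    if (col %in% names(df)) df[[col]] <- as.character(df[[col]])
  marker_map(df)
}

#' Write a marker map
#' @param map a [marker_map()].
#' @param path output path.
#' @export
write_marker_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix from genotypes.tsv
#'
#' Rows are samples, columns markers; the header row carries marker ids and
#' the first column sample ids.  In strict mode (default) any token outside
#' {0, 1, 2, -1} is an error; in lenient mode unknown tokens become -1.
#'
#' @param path TSV path.
#' @param map optional [marker_map()]; when given, the file's marker ids must
#'   match the map's order exactly.
#' @param strict error on illegal call tokens (default TRUE).
#' @return a validated [genotype_matrix()].
#' @export
read_genotypes <- function(path, map = NULL, strict = TRUE) {
  df <- read_table_checked(path)
  if (ncol(df) < 1)
    stop_hemidel("genotype file has no columns", "hemidel_io_error")
  sample_ids <- as.character(df[[1]])
  marker_ids <- colnames(df)[-1]
  if (!is.null(map) && !identical(marker_ids, map$marker_id))
    stop_hemidel("genotype file marker ids do not match marker map order",
                 "hemidel_io_error")
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(mi <- matrix(as.integer(m), nrow = nrow(m)))
  legal <- mi %in% GENOTYPE_CALLS & !is.na(mi)
  if (!all(legal)) {
    if (strict) {
      bad <- unique(m[!legal])
      stop_hemidel(sprintf("illegal genotype call token(s): %s",
                           paste(bad, collapse = ", ")),
                   "hemidel_call_error")
    }
    mi[!legal] <- -1L
  }
  genotype_matrix(mi, sample_ids, marker_ids)
}

#' Write a genotype matrix to genotypes.tsv
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @export
write_genotypes <- function(gm, path) {
  df <- data.frame(sample_id = rownames(gm), gm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pedigree from pedigree.tsv
#'
#' Missing parents are encoded as "0" on disk and NA internally.
#' @param path TSV with columns animal_id, sire_id, dam_id, sex, phenotype.
#' @return a [pedigree()].
#' @export
read_pedigree <- function(path) {
  df <- read_table_checked(path)
  for (col in c("animal_id", "sire_id", "dam_id")) {
    if (col %in% names(df)) df[[col]] <- as.character(df[[col]])
  }
  df$sire_id[df$sire_id %in% "0"] <- NA_character_
  df$dam_id[df$dam_id %in% "0"] <- NA_character_
  pedigree(df)
}

#' Write a pedigree
#' @param ped a [pedigree()].
#' @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire_id[is.na(out$sire_id)] <- "0"
  out$dam_id[is.na(out$dam_id)] <- "0"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a windowed depth track from depth.tsv
#'
#' Windows are 1-based inclusive (this is the internal convention, not BED).
#' @param path TSV with columns chrom, start, end, depth.
#' @param genome_median_depth optional; recomputed from the windows if absent.
#' @return a [depth_profile()].
#' @export
read_depth <- function(path, genome_median_depth = NULL) {
  df <- read_table_checked(path)
  if ("chrom" %in% names(df)) df$chrom <- as.character(df$chrom)
  depth_profile(df, genome_median_depth)
}

#' Write a depth profile's windows
#' @param dp a [depth_profile()].
#' @param path output path.
#' @export
write_depth <- function(dp, path) {
  utils::write.table(dp$windows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read read-pair/clip evidence from pairs.tsv
#'
#' An empty clipped sequence is encoded as "." on disk.
#' @param path TSV with columns read_id, chrom, pos, mate_pos, insert,
#'   clip_side, clipped_seq.
#' @return a [pair_evidence()] table.
#' @export
read_pairs <- function(path) {
  df <- read_table_checked(path)
  if (nrow(df) > 0) {
    for (col in c("read_id", "chrom", "clip_side", "clipped_seq"))
      df[[col]] <- as.character(df[[col]])
    df$clipped_seq[df$clipped_seq == "."] <- ""
  }
  pair_evidence(df)
}

#' Write read-pair/clip evidence
#' @param pe a [pair_evidence()] table.
#' @param path output path.
#' @export
write_pairs <- function(pe, path) {
  out <- as.data.frame(pe)
  if (nrow(out) > 0) out$clipped_seq[out$clipped_seq == ""] <- "."
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read stage-wise transmission count tables from counts.tsv
#'
#' @param path TSV with columns stage, sex, carrier, count.
#' @return named list of [transmission_counts()] objects, one per stage.
#' @export
read_counts <- function(path) {
  df <- read_table_checked(path)
  req <- c("stage", "sex", "carrier", "count")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop_hemidel(paste("counts file missing columns:", paste(miss, collapse = ", ")),
                 "hemidel_io_error")
  for (col in c("stage", "sex", "carrier"))
    df[[col]] <- as.character(df[[col]])
  out <- lapply(split(df, df$stage), function(d) {
    v <- stats::setNames(d$count, paste(d$sex, d$carrier, sep = "."))
    transmission_counts(d$stage[1], v)
  })
  out[intersect(c("sperm", "blastocyst", "birth"), names(out))]
}

#' Write stage-wise transmission count tables
#' @param counts named list of [transmission_counts()] objects.
#' @param path output path.
#' @export
write_counts <- function(counts, path) {
  rows <- do.call(rbind, lapply(counts, function(tc) {
    v <- as_count_vector(tc)
    sx <- sub("\\..*$", "", names(v))
    cr <- sub("^.*\\.", "", names(v))
    data.frame(stage = tc$stage, sex = sx, carrier = cr, count = as.integer(v))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read artificial-insemination records from ai_records.csv
#' @param path CSV with one row per AI event (see [ai_records()]).
#' @return validated [ai_records()] table.
#' @export
read_ai_records <- function(path) {
  df <- read_table_checked(path, sep = ",")
  df$cow_id <- as.character(df$cow_id)
  df$superovulation <- as.logical(df$superovulation)
  ai_records(df)
}

#' Write artificial-insemination records
#' @param rec an [ai_records()] table.
#' @param path output path.
#' @export
write_ai_records <- function(rec, path) {
  utils::write.table(rec, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED file into internal 1-based inclusive intervals
#'
#' @param path BED path (0-based half-open; first three columns chrom, start,
#'   end, optional fourth column label).
#' @return data.frame with columns chrom, start, end, label (internal
#'   coordinates).
#' @export
read_bed <- function(path) {
  if (!file.exists(path))
    stop_hemidel(paste("file not found:", path), "hemidel_io_error")
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  conv <- bed_to_internal(df[[2]], df[[3]])
  data.frame(chrom = as.character(df[[1]]), start = conv$start,
             end = conv$end,
             label = if (ncol(df) >= 4) as.character(df[[4]]) else NA_character_)
}

#' Write internal intervals as a BED file
#' @param regions data.frame with chrom, start, end (1-based inclusive) and
#'   optional label.
#' @param path output path.
#' @export
write_bed <- function(regions, path) {
  conv <- internal_to_bed(regions$start, regions$end)
  out <- data.frame(regions$chrom, conv$start, conv$end)
  if ("label" %in% names(regions)) out[[4]] <- regions$label
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
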