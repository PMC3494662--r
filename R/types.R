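#' @keywords internal
"_PACKAGE"

## Internal coordinate convention: 1-based, both ends inclusive, matching
## printed assembly positions.  BED input/output is converted at the boundary.

GENOTYPE_CALLS <- c(-1L, 0L, 1L, 2L)

stop_hemidel <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "hemidel_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Construct and validate a SNP marker map
#'
#' A marker map lists array markers with their chromosome, 1-based position,
#' the two alleles and the minor-allele frequency used by the simulator.
#'
#' @param df data.frame with columns `marker_id`, `chrom`, `pos`, `allele_a`,
#'   `allele_b`, `maf`.
#' @return The validated data.frame with class `marker_map`, sorted by
#'   (chrom, pos).
#' @export
marker_map <- function(df) {
  req <- c("marker_id", "chrom", "pos", "allele_a", "allele_b", "maf")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop_hemidel(paste("marker map missing columns:", paste(miss, collapse = ", ")),
                 "hemidel_schema_error")
  df <- df[, req]
  df$pos <- as.integer(df$pos)
  if (anyDuplicated(df$marker_id))
    stop_hemidel("duplicate marker_id in marker map", "hemidel_schema_error")
  if (any(df$pos < 1L))
    stop_hemidel("marker pos must be >= 1", "hemidel_schema_error")
  if (any(df$allele_a == df$allele_b))
    stop_hemidel("allele_a must differ from allele_b", "hemidel_schema_error")
  if (any(df$maf < 0 | df$maf > 0.5))
    stop_hemidel("maf must lie in [0, 0.5]", "hemidel_schema_error")
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("marker_map", "data.frame")
  df
}

#' Construct and validate a genotype matrix
#'
#' Genotypes are stored as an integer matrix of alt-allele (allele_b) dosages:
#' 0, 1, 2, with -1 as the missing-call sentinel.  Rows are samples, columns
#' markers; dimnames carry the identifiers.
#'
#' @param calls integer matrix of calls.
#' @param sample_ids,marker_ids optional identifier vectors; defaults to the
#'   existing dimnames of `calls`.
#' @return validated integer matrix with dimnames.
#' @export
genotype_matrix <- function(calls, sample_ids = rownames(calls),
                            marker_ids = colnames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(sample_ids) || is.null(marker_ids))
    stop_hemidel("genotype matrix needs sample and marker identifiers",
                 "hemidel_schema_error")
  if (length(sample_ids) != nrow(calls) || length(marker_ids) != ncol(calls))
    stop_hemidel("genotype matrix dimensions do not match identifier lengths",
                 "hemidel_schema_error")
  bad <- !(calls %in% GENOTYPE_CALLS)
  if (any(bad))
    stop_hemidel(sprintf("illegal genotype call value(s): %s",
                         paste(unique(calls[bad]), collapse = ", ")),
                 "hemidel_call_error")
  dimnames(calls) <- list(sample_ids, marker_ids)
  calls
}

#' Construct and validate a pedigree
#'
#' @param df data.frame with columns `animal_id`, `sire_id`, `dam_id`
#'   (NA = unknown/external parent), `sex` in M/F/U and `phenotype` in
#'   affected/unaffected/unknown.
#' @return validated data.frame with class `pedigree`.
#' @export
pedigree <- function(df) {
  req <- c("animal_id", "sire_id", "dam_id", "sex", "phenotype")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop_hemidel(paste("pedigree missing columns:", paste(miss, collapse = ", ")),
                 "hemidel_schema_error")
  df <- df[, req]
  if (anyDuplicated(df$animal_id))
    stop_hemidel("duplicate animal_id in pedigree", "hemidel_schema_error")
  if (!all(df$sex %in% c("M", "F", "U")))
    stop_hemidel("pedigree sex must be one of M, F, U", "hemidel_schema_error")
  if (!all(df$phenotype %in% c("affected", "unaffected", "unknown")))
    stop_hemidel("pedigree phenotype must be affected/unaffected/unknown",
                 "hemidel_schema_error")
  ## no animal may be its own ancestor
  parent_of <- function(id) {
    r <- df[match(id, df$animal_id), c("sire_id", "dam_id")]
    p <- unlist(r, use.names = FALSE)
    p[!is.na(p) & p %in% df$animal_id]
  }
  for (id in df$animal_id) {
    seen <- character(0)
    frontier <- parent_of(id)
    while (length(frontier) > 0) {
      if (id %in% frontier)
        stop_hemidel(sprintf("pedigree cycle: %s is its own ancestor", id),
                     "hemidel_schema_error")
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(lapply(frontier, parent_of))), seen)
    }
  }
  rownames(df) <- NULL
  class(df) <- c("pedigree", "data.frame")
  df
}

#' Construct and validate a windowed depth profile
#'
#' @param windows data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive, non-overlapping, sorted) and `depth` (non-negative raw depth).
#' @param genome_median_depth positive real; defaults to the median window
#'   depth.
#' @return list with elements `windows` and `genome_median_depth`, class
#'   `depth_profile`.
#' @export
depth_profile <- function(windows, genome_median_depth = NULL) {
  req <- c("chrom", "start", "end", "depth")
  miss <- setdiff(req, names(windows))
  if (length(miss) > 0)
    stop_hemidel(paste("depth profile missing columns:", paste(miss, collapse = ", ")),
                 "hemidel_schema_error")
  windows <- windows[, req]
  if (any(windows$end < windows$start))
    stop_hemidel("depth window end < start", "hemidel_schema_error")
  if (any(windows$depth < 0))
    stop_hemidel("negative depth", "hemidel_schema_error")
  o <- order(windows$chrom, windows$start)
  windows <- windows[o, , drop = FALSE]
  by_chr <- split(windows, windows$chrom)
  for (w in by_chr) {
    if (nrow(w) > 1 && any(w$start[-1] <= w$end[-nrow(w)]))
      stop_hemidel("overlapping depth windows", "hemidel_schema_error")
  }
  if (is.null(genome_median_depth))
    genome_median_depth <- stats::median(windows$depth)
  rownames(windows) <- NULL
  structure(list(windows = windows, genome_median_depth = genome_median_depth),
            class = "depth_profile")
}

#' Construct and validate a read-pair / clipped-read evidence table
#'
#' One row per read: `pos` is the leftmost aligned reference base, `mate_pos`
#' the mate's leftmost aligned base, `insert` the reference-implied insert
#' size of the pair, `clip_side` one of none/left/right and `clipped_seq`
#' the soft-clipped sequence (empty iff `clip_side == "none"`).
#'
#' @param df data.frame with columns `read_id`, `chrom`, `pos`, `mate_pos`,
#'   `insert`, `clip_side`, `clipped_seq`.
#' @return validated data.frame with class `pair_evidence`.
#' @export
pair_evidence <- function(df) {
  req <- c("read_id", "chrom", "pos", "mate_pos", "insert", "clip_side",
           "clipped_seq")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop_hemidel(paste("pair evidence missing columns:", paste(miss, collapse = ", ")),
                 "hemidel_schema_error")
  df <- df[, req]
  if (nrow(df) > 0) {
    if (!all(df$clip_side %in% c("none", "left", "right")))
      stop_hemidel("clip_side must be none/left/right", "hemidel_schema_error")
    if (any(df$insert <= 0))
      stop_hemidel("observed insert must be positive", "hemidel_schema_error")
    empty <- is.na(df$clipped_seq) | nchar(df$clipped_seq) == 0
    if (any(empty != (df$clip_side == "none")))
      stop_hemidel("clipped_seq must be empty iff clip_side is none",
                   "hemidel_schema_error")
    df$clipped_seq[df$clip_side == "none"] <- ""
  }
  rownames(df) <- NULL
  class(df) <- c("pair_evidence", "data.frame")
  df
}

#' Construct a per-stage transmission count table
#'
#' Four cells: sex (M, F) by deletion-carrier status (del, wt) at one
#' developmental stage (sperm, blastocyst or birth).
#'
#' @param stage one of "sperm", "blastocyst", "birth".
#' @param counts 2x2 non-negative integer matrix with rownames c("M","F") and
#'   colnames c("del","wt"), or a named vector with names like "M.del".
#' @return list with elements `stage` and `counts`, class
#'   `transmission_counts`.
#' @export
transmission_counts <- function(stage, counts) {
  if (!stage %in% c("sperm", "blastocyst", "birth"))
    stop_hemidel("stage must be sperm/blastocyst/birth", "hemidel_schema_error")
  if (!is.matrix(counts)) {
    nm <- c("M.del", "M.wt", "F.del", "F.wt")
    if (is.null(names(counts)) || !setequal(names(counts), nm))
      stop_hemidel("counts vector must be named M.del, M.wt, F.del, F.wt",
                   "hemidel_schema_error")
    counts <- matrix(counts[nm], nrow = 2, byrow = TRUE,
                     dimnames = list(c("M", "F"), c("del", "wt")))
  }
  counts <- counts[c("M", "F"), c("del", "wt"), drop = FALSE]
  storage.mode(counts) <- "integer"
  if (any(counts < 0) || anyNA(counts))
    stop_hemidel("transmission counts must be non-negative integers",
                 "hemidel_schema_error")
  structure(list(stage = stage, counts = counts), class = "transmission_counts")
}

#' Flatten a transmission count table to the canonical 4-vector
#'
#' Canonical cell order is M.del, M.wt, F.del, F.wt.
#' @param x a `transmission_counts` object, a 2x2 matrix, or a 4-vector.
#' @return named numeric vector of length 4.
#' @export
as_count_vector <- function(x) {
  if (inherits(x, "transmission_counts")) x <- x$counts
  if (is.matrix(x)) {
    x <- c(x["M", "del"], x["M", "wt"], x["F", "del"], x["F", "wt"])
  } else if (!is.null(names(x))) {
    x <- x[c("M.del", "M.wt", "F.del", "F.wt")]
  }
  if (length(x) != 4 || anyNA(x))
    stop_hemidel("expected a 4-cell count table", "hemidel_schema_error")
  stats::setNames(as.numeric(x), c("M.del", "M.wt", "F.del", "F.wt"))
}

#' Validate a table of artificial-insemination records
#'
#' `consecutive_failures_for_cow` is the length of the consecutive-failure run
#' the record belongs to (meaningful for failures; 1 for successes).
#'
#' @param df data.frame with columns `cow_id`, `ai_day`, `outcome`
#'   (success/failure), `superovulation` (logical), `next_event`
#'   (ai/calving/none), `next_event_day` (NA when `next_event == "none"`),
#'   `consecutive_failures_for_cow`.
#' @return validated data.frame with class `ai_records`.
#' @export
ai_records <- function(df) {
  req <- c("cow_id", "ai_day", "outcome", "superovulation", "next_event",
           "next_event_day", "consecutive_failures_for_cow")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop_hemidel(paste("AI records missing columns:", paste(miss, collapse = ", ")),
                 "hemidel_schema_error")
  df <- df[, req]
  if (nrow(df) > 0) {
    if (!all(df$outcome %in% c("success", "failure")))
      stop_hemidel("AI outcome must be success/failure", "hemidel_schema_error")
    if (!all(df$next_event %in% c("ai", "calving", "none")))
      stop_hemidel("next_event must be ai/calving/none", "hemidel_schema_error")
    has_next <- df$next_event != "none"
    if (any(has_next & is.na(df$next_event_day)))
      stop_hemidel("next_event_day required when next_event is set",
                   "hemidel_schema_error")
    bad <- which(has_next & df$next_event_day <= df$ai_day)
    if (length(bad) > 0)
      stop_hemidel(sprintf("next_event_day <= ai_day at record(s): %s",
                           paste(bad, collapse = ", ")),
                   "hemidel_schema_error", rows = bad)
    if (any(df$consecutive_failures_for_cow < 1))
      stop_hemidel("consecutive_failures_for_cow must be >= 1",
                   "hemidel_schema_error")
  }
  rownames(df) <- NULL
  class(df) <- c("ai_records", "data.frame")
  df
}

#' Convert BED (0-based half-open) intervals to internal 1-based inclusive form
#'
#' @param start,end BED start/end vectors.
#' @return data.frame with 1-based inclusive `start`, `end`.
#' @export
bed_to_internal <- function(start, end) {
  out <- data.frame(start = as.integer(start) + 1L, end = as.integer(end))
  if (any(out$start > out$end))
    stop_hemidel("degenerate BED interval (start >= end)", "hemidel_schema_error")
  out
}

#' Convert internal 1-based inclusive intervals to BED coordinates
#' @param start,end internal 1-based inclusive coordinates.
#' @return data.frame with BED `start`, `end`.
#' @export
internal_to_bed <- function(start, end) {
  data.frame(start = as.integer(start) - 1L, end = as.integer(end))
}
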