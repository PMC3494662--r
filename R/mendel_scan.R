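## Deletion mapping from sire-progeny genotype incompatibilities.  A
## transmitted hemizygous deletion makes the array call affected progeny
## homozygous for the maternal allele, so markers where sire and affected
## progeny are opposite homozygotes (AA vs BB) cluster over the deletion,
## while affected animals show no heterozygous calls inside it.

#' Flag sire-progeny opposite-homozygote (Mendelian error) markers
#'
#' A pair of calls is flagged when one is 0 (AA) and the other 2 (BB), in
#' either order; any missing call (-1) makes the flag FALSE.
#'
#' @param sire_calls,progeny_calls equal-length integer call vectors
#'   (values in -1, 0, 1, 2).
#' @return logical vector of per-marker error flags.
#' @export
opposite_homozygote_flags <- function(sire_calls, progeny_calls) {
  if (length(sire_calls) != length(progeny_calls))
    stop_hemidel("call vectors differ in length", "hemidel_schema_error")
  (sire_calls == 0L & progeny_calls == 2L) |
    (sire_calls == 2L & progeny_calls == 0L)
}

#' Tally per-marker Mendelian errors and affected heterozygosity
#'
#' For every genotyped progeny of `sire_id`, opposite-homozygote errors
#' against the sire are counted per marker, split by progeny phenotype.
#' Heterozygous calls are counted over affected progeny only (a hemizygous
#' animal cannot be truly heterozygous inside the deletion).
#' `n_informative` counts, per marker, the progeny comparisons capable of
#' revealing an opposite homozygote: sire call homozygous and progeny call
#' non-missing.
#'
#' @param gm a [genotype_matrix()].
#' @param ped a [pedigree()].
#' @param sire_id the informative parent's sample id.
#' @return data.frame of class `marker_error_profile` with columns
#'   `marker_id`, `n_errors_affected`, `n_errors_unaffected`,
#'   `n_het_affected`, `n_informative`.
#' @export
build_error_profile <- function(gm, ped, sire_id) {
  if (!sire_id %in% rownames(gm))
    stop_hemidel(sprintf("sire %s not in genotype matrix", sire_id),
                 "hemidel_schema_error")
  progeny <- ped$animal_id[!is.na(ped$sire_id) & ped$sire_id == sire_id]
  progeny <- intersect(progeny, rownames(gm))
  if (length(progeny) == 0)
    stop_hemidel("no genotyped progeny of the sire", "hemidel_schema_error")
  pheno <- ped$phenotype[match(progeny, ped$animal_id)]
  aff <- progeny[pheno == "affected"]
  unaff <- progeny[pheno == "unaffected"]
  sire <- gm[sire_id, ]

  err_counts <- function(ids) {
    if (length(ids) == 0) return(integer(ncol(gm)))
    flags <- vapply(ids, function(id) opposite_homozygote_flags(sire, gm[id, ]),
                    logical(ncol(gm)))
    as.integer(rowSums(flags))
  }
  n_het_aff <- if (length(aff) == 0) integer(ncol(gm)) else
    as.integer(colSums(gm[aff, , drop = FALSE] == 1L))
  sire_hom <- sire %in% c(0L, 2L)
  n_inf <- as.integer(colSums(gm[progeny, , drop = FALSE] != -1L) * sire_hom)

  out <- data.frame(marker_id = colnames(gm),
                    n_errors_affected = err_counts(aff),
                    n_errors_unaffected = err_counts(unaff),
                    n_het_affected = n_het_aff,
                    n_informative = n_inf,
                    stringsAsFactors = FALSE)
  class(out) <- c("marker_error_profile", "data.frame")
  out
}

#' Call candidate deletion regions from a marker error profile
#'
#' Seed markers have at least `min_affected_errors` affected-progeny errors
#' and no unaffected-progeny error.  Seeds on the same chromosome within
#' `max_gap_bp` of each other merge into clusters; clusters with fewer than
#' `min_cluster_size` seed markers are dropped.  Region bounds extend from
#' the outermost seed markers to the midpoints with their flanking
#' non-cluster markers (or to the marker position itself at a chromosome
#' edge).  Regions are scored as `n_error_markers - het_penalty *
#' n_het_markers_inside` (affected heterozygosity inside a real hemizygous
#' deletion can only come from call errors) and returned ranked by
#' decreasing score, ties broken leftmost.
#'
#' @param profile a `marker_error_profile` from [build_error_profile()].
#' @param map the [marker_map()] the profile was computed against (same
#'   marker order).
#' @param min_affected_errors,max_gap_bp,min_cluster_size,het_penalty
#'   clustering parameters (see description).
#' @return data.frame of class `candidate_regions` with columns `chrom`,
#'   `start`, `end`, `n_error_markers`, `n_het_markers_inside`, `score`
#'   (possibly 0 rows).
#' @export
call_candidate_regions <- function(profile, map, min_affected_errors = 2L,
                                   max_gap_bp = 1e6, min_cluster_size = 5L,
                                   het_penalty = 1) {
  if (!identical(profile$marker_id, map$marker_id))
    stop_hemidel("profile and map are not aligned", "hemidel_schema_error")
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_error_markers = integer(0),
                      n_het_markers_inside = integer(0), score = numeric(0))
  class(empty) <- c("candidate_regions", "data.frame")
  seed <- profile$n_errors_affected >= min_affected_errors &
    profile$n_errors_unaffected == 0L
  if (!any(seed)) return(empty)

  regions <- list()
  for (chr in unique(map$chrom[seed])) {
    on_chr <- which(map$chrom == chr)
    sidx <- on_chr[seed[on_chr]]
    pos <- map$pos[sidx]
    brk <- c(0, which(diff(pos) > max_gap_bp), length(pos))
    for (k in seq_len(length(brk) - 1)) {
      members <- sidx[(brk[k] + 1):brk[k + 1]]
      if (length(members) < min_cluster_size) next
      first <- min(members); last <- max(members)
      prev <- on_chr[on_chr < first]
      nxt <- on_chr[on_chr > last]
      start <- if (length(prev) > 0)
        floor((map$pos[max(prev)] + map$pos[first]) / 2) else map$pos[first]
      end <- if (length(nxt) > 0)
        ceiling((map$pos[last] + map$pos[min(nxt)]) / 2) else map$pos[last]
      inside <- on_chr[map$pos[on_chr] >= start & map$pos[on_chr] <= end]
      n_het <- sum(profile$n_het_affected[inside] > 0L)
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = chr, start = as.integer(start), end = as.integer(end),
        n_error_markers = length(members), n_het_markers_inside = n_het,
        score = length(members) - het_penalty * n_het)
    }
  }
  if (length(regions) == 0) return(empty)
  out <- do.call(rbind, regions)
  out <- out[order(-out$score, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_regions", "data.frame")
  out
}

#' Fraction of in-region markers consistent with maternal-only inheritance
#'
#' For every affected animal with a genotyped dam, each informative
#' in-region marker (both the affected's and the dam's calls non-missing) is
#' checked for consistency with hemizygosity: the affected's call must be
#' homozygous for an allele its dam carries, i.e. explainable by loss of the
#' paternal allele.  A heterozygous affected call inside the region counts
#' as inconsistent.
#'
#' @param region one-row data.frame (or list) with `chrom`, `start`, `end`.
#' @param gm a [genotype_matrix()].
#' @param map the [marker_map()] (provides marker positions).
#' @param ped a [pedigree()].
#' @param affected_ids ids of affected, genotyped animals.
#' @return fraction in \[0, 1\].
#' @export
hemizygosity_consistency <- function(region, gm, map, ped, affected_ids) {
  in_region <- map$chrom == region$chrom &
    map$pos >= region$start & map$pos <= region$end
  mk <- map$marker_id[in_region]
  n_cons <- 0L; n_inf <- 0L
  for (id in affected_ids) {
    dam <- ped$dam_id[match(id, ped$animal_id)]
    if (is.na(dam) || !dam %in% rownames(gm) || !id %in% rownames(gm)) next
    a <- gm[id, mk]; d <- gm[dam, mk]
    inf <- a != -1L & d != -1L
    n_inf <- n_inf + sum(inf)
    cons <- inf & ((a == 0L & d %in% c(0L, 1L)) | (a == 2L & d %in% c(1L, 2L)))
    n_cons <- n_cons + sum(cons)
  }
  if (n_inf == 0L)
    stop_hemidel("no informative marker in region for any affected/dam pair",
                 "hemidel_no_informative_error")
  n_cons / n_inf
}
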