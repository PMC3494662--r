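## Sequencing-evidence characterization of the deletion: depth-ratio
## segmentation (copy-number states), discordant-pair bracketing of the
## junction, clipped-read consensus reconstruction of the exact breakpoints
## and micro-insertion, and the flank-retained length arithmetic.

#' Normalize a depth profile to copy-number ratios
#'
#' @param profile a [depth_profile()] with positive `genome_median_depth`.
#' @return the profile with an added `ratio` column
#'   (`depth / genome_median_depth`), class `ratio_profile`.
#' @export
normalize_depth <- function(profile) {
  if (is.null(profile$genome_median_depth) || profile$genome_median_depth <= 0)
    stop_hemidel("genome median depth must be positive", "hemidel_depth_error")
  profile$windows$ratio <- profile$windows$depth / profile$genome_median_depth
  class(profile) <- c("ratio_profile", class(profile))
  profile
}

#' Segment a depth-ratio profile into copy-number states
#'
#' Ratios are smoothed with a running median (window `smooth_k`) and binned:
#' nullizygous `[0, 0.25)`, hemizygous `[0.25, 0.75)`, diploid `[0.75, Inf)`
#' by default.  Maximal runs of identical state shorter than `min_windows`
#' are absorbed into the longer neighbouring run, which suppresses isolated
#' dips such as local assembly artifacts and the short spurious runs that
#' Poisson depth noise produces at moderate coverage (the default of 25
#' windows is 250 kb at 10 kb windows: far above the run lengths noise
#' reaches, far below the Mb scale this caller targets).
#'
#' @param rp a `ratio_profile` from [normalize_depth()].
#' @param bands numeric vector `c(nullizygous_max, hemizygous_max)` of band
#'   upper bounds.
#' @param min_windows minimum run length kept as its own segment.
#' @param smooth_k running-median window (odd integer).
#' @return data.frame of class `depth_segments` with columns `chrom`,
#'   `start`, `end`, `state`, `mean_ratio`, `n_windows`.
#' @export
segment_depth <- function(rp, bands = c(nullizygous_max = 0.25,
                                        hemizygous_max = 0.75),
                          min_windows = 25L, smooth_k = 5L) {
  w <- rp$windows
  if (nrow(w) == 0)
    stop_hemidel("empty depth profile", "hemidel_depth_error")
  out <- list()
  for (chr in unique(w$chrom)) {
    wc <- w[w$chrom == chr, , drop = FALSE]
    sm <- if (nrow(wc) >= smooth_k)
      as.numeric(stats::runmed(wc$ratio, smooth_k)) else wc$ratio
    state <- cut(sm, breaks = c(-Inf, bands[1], bands[2], Inf),
                 labels = c("nullizygous", "hemizygous", "diploid"),
                 right = FALSE)
    state <- as.character(state)
    ## absorb short runs into the longer neighbour until stable
    repeat {
      r <- rle(state)
      if (length(r$lengths) <= 1) break
      short <- which(r$lengths < min_windows)
      if (length(short) == 0) break
      i <- short[which.min(r$lengths[short])]
      left_len <- if (i > 1) r$lengths[i - 1] else -1L
      right_len <- if (i < length(r$lengths)) r$lengths[i + 1] else -1L
      take <- if (left_len >= right_len) i - 1L else i + 1L
      r$values[i] <- r$values[take]
      state <- inverse.rle(r)
    }
    r <- rle(state)
    stop_idx <- cumsum(r$lengths)
    start_idx <- c(1L, stop_idx[-length(stop_idx)] + 1L)
    for (k in seq_along(r$values)) {
      idx <- start_idx[k]:stop_idx[k]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = wc$start[start_idx[k]], end = wc$end[stop_idx[k]],
        state = r$values[k], mean_ratio = mean(wc$ratio[idx]),
        n_windows = length(idx))
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("depth_segments", "data.frame")
  out
}

#' Bracket the deletion junction from discordant read pairs
#'
#' Pairs whose reference-implied insert exceeds
#' `insert_mean + z * insert_sd` are discordant.  Each fully aligned
#' discordant read contributes its own extent: left-side reads their aligned
#' end, right-side reads their aligned start.  The bracket
#' `[max left end, min right start]` contains the junction.
#'
#' @param pairs a [pair_evidence()] table.
#' @param insert_mean,insert_sd fragment-size distribution of the library.
#' @param z discordance threshold in SDs.
#' @param read_len read length (bp), used to turn a leftmost aligned base
#'   into an aligned end.
#' @return list with `lo`, `hi`, `n_discordant`, or NULL when no discordant
#'   pair exists (the "no junction" signal).
#' @export
locate_breakpoints_from_pairs <- function(pairs, insert_mean, insert_sd,
                                          z = 4, read_len = 100L) {
  disc <- pairs[pairs$insert > insert_mean + z * insert_sd &
                  pairs$clip_side == "none", , drop = FALSE]
  if (nrow(disc) == 0) return(NULL)
  is_left <- disc$pos < disc$mate_pos
  lefts <- disc$pos[is_left] + read_len - 1L
  rights <- disc$pos[!is_left]
  lo <- if (length(lefts) > 0) max(lefts) else
    max(pmin(disc$pos, disc$mate_pos)) + read_len - 1L
  hi <- if (length(rights) > 0) min(rights) else min(pmax(disc$pos, disc$mate_pos))
  list(lo = as.integer(lo), hi = as.integer(hi),
       n_discordant = nrow(disc))
}

## Majority-vote consensus over a set of clipped sequences.
## from = "left": sequences share their first base (right-clip tails);
## from = "right": sequences share their last base (left-clip heads).
clip_consensus <- function(seqs, threshold, from = c("left", "right")) {
  from <- match.arg(from)
  lens <- nchar(seqs)
  width <- max(lens)
  chars <- matrix(NA_character_, nrow = length(seqs), ncol = width)
  for (i in seq_along(seqs)) {
    s <- strsplit(seqs[i], "")[[1]]
    if (from == "left") chars[i, seq_len(lens[i])] <- s
    else chars[i, (width - lens[i] + 1L):width] <- s
  }
  cons <- character(width)
  for (j in seq_len(width)) {
    col <- chars[, j]
    col <- col[!is.na(col)]
    tab <- sort(table(col), decreasing = TRUE)
    if (tab[1] / length(col) < threshold)
      stop_hemidel(sprintf("no majority base at consensus column %d", j),
                   "hemidel_ambiguous_junction")
    cons[j] <- names(tab)[1]
  }
  paste(cons, collapse = "")
}

mode_int <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  as.integer(names(tab)[1])
}

#' Reconstruct the deletion junction from clipped reads
#'
#' Soft-clipped reads inside the discordant-pair bracket are split by clip
#' side.  Right-clipped reads fix the left flank (last aligned base);
#' left-clipped reads fix the right flank (first aligned base); when one
#' side is absent the missing flank is found by anchoring the other side's
#' clipped consensus against the reference inside the bracket.  The
#' non-template inserted sequence is the prefix of the right-side consensus
#' (equivalently the suffix of the left-side consensus) that does not match
#' the reference extension, cross-checked between sides when both exist.
#'
#' @param pairs a [pair_evidence()] table.
#' @param reference_fetch function(start, end) returning reference sequence.
#' @param bracket list with `lo`, `hi` from
#'   [locate_breakpoints_from_pairs()].
#' @param min_support minimum clipped reads required (default 3).
#' @param consensus_threshold minimum per-column majority fraction.
#' @param max_insert_len longest micro-insertion considered.
#' @param read_len read length (bp).
#' @param anchor_len bases used when anchoring a consensus against the
#'   reference.
#' @return list of class `junction_call` with `left_flank`, `right_flank`,
#'   `inserted_seq`, `support`.  Errors with class
#'   `hemidel_insufficient_support` or `hemidel_ambiguous_junction` rather
#'   than returning a doubtful coordinate.
#' @export
assemble_junction <- function(pairs, reference_fetch, bracket,
                              min_support = 3L, consensus_threshold = 0.6,
                              max_insert_len = 20L, read_len = 100L,
                              anchor_len = 12L) {
  slop <- read_len
  clips <- pairs[pairs$clip_side != "none", , drop = FALSE]
  clips <- clips[clips$pos >= bracket$lo - slop & clips$pos <= bracket$hi + slop, ,
                 drop = FALSE]
  if (nrow(clips) < min_support)
    stop_hemidel(sprintf("only %d clipped read(s) in bracket; need %d",
                         nrow(clips), min_support),
                 "hemidel_insufficient_support")
  rc <- clips[clips$clip_side == "right", , drop = FALSE]
  lc <- clips[clips$clip_side == "left", , drop = FALSE]

  left_flank <- if (nrow(rc) > 0)
    mode_int(rc$pos + (read_len - nchar(rc$clipped_seq)) - 1L) else NA_integer_
  right_flank <- if (nrow(lc) > 0) mode_int(lc$pos) else NA_integer_

  tail_cons <- if (nrow(rc) > 0)
    clip_consensus(rc$clipped_seq, consensus_threshold, "left") else NULL
  head_cons <- if (nrow(lc) > 0)
    clip_consensus(lc$clipped_seq, consensus_threshold, "right") else NULL

  ## anchor search for a flank missing clip support: slide the insertion
  ## length and look for a unique exact match of the remaining consensus
  ## against the reference near the bracket edge
  if (is.na(right_flank)) {
    right_flank <- anchor_right_flank(tail_cons, reference_fetch, bracket,
                                      max_insert_len, anchor_len)
  }
  if (is.na(left_flank)) {
    left_flank <- anchor_left_flank(head_cons, reference_fetch, bracket,
                                    max_insert_len, anchor_len)
  }
  if (is.na(left_flank) || is.na(right_flank))
    stop_hemidel("could not resolve both flanks", "hemidel_ambiguous_junction")

  ins_t <- if (!is.null(tail_cons))
    insert_from_tail(tail_cons, reference_fetch, right_flank, max_insert_len)
  else NULL
  ins_h <- if (!is.null(head_cons))
    insert_from_head(head_cons, reference_fetch, left_flank, max_insert_len)
  else NULL
  if (!is.null(ins_t) && !is.null(ins_h) && !identical(ins_t, ins_h))
    stop_hemidel(sprintf("insertion disagrees between clip sides (%s vs %s)",
                         ins_t, ins_h),
                 "hemidel_ambiguous_junction")
  inserted <- if (!is.null(ins_t)) ins_t else ins_h
  if (is.null(inserted))
    stop_hemidel("no consensus sequence to derive the insertion from",
                 "hemidel_ambiguous_junction")
  if (right_flank < left_flank + 2L)
    stop_hemidel("assembled flanks delete nothing", "hemidel_ambiguous_junction")
  structure(list(left_flank = as.integer(left_flank),
                 right_flank = as.integer(right_flank),
                 inserted_seq = inserted, support = nrow(clips)),
            class = "junction_call")
}

## Smallest insertion length i such that tail[(i+1)..] equals the reference
## starting at right_flank, requiring at least min_match matching bases so a
## chance 1-2 base agreement cannot fix the insert.  A consensus too short
## to test every candidate insert length is inconclusive (NULL: the other
## clip side decides); a consensus that tested the full range and never
## matched is a genuine conflict.
insert_from_tail <- function(tail_cons, reference_fetch, right_flank,
                             max_insert_len, min_match = 5L) {
  n <- nchar(tail_cons)
  i_max <- n - min_match
  if (i_max >= 0) {
    for (i in 0:min(max_insert_len, i_max)) {
      ref <- reference_fetch(right_flank, right_flank + (n - i) - 1L)
      if (substr(tail_cons, i + 1L, n) == ref)
        return(substr(tail_cons, 1L, i))
    }
  }
  if (i_max >= max_insert_len)
    stop_hemidel("clipped tail does not match reference after the junction",
                 "hemidel_ambiguous_junction")
  NULL
}

## mirror image: head[1..(n-j)] must equal the reference ending at left_flank
insert_from_head <- function(head_cons, reference_fetch, left_flank,
                             max_insert_len, min_match = 5L) {
  n <- nchar(head_cons)
  j_max <- n - min_match
  if (j_max >= 0) {
    for (j in 0:min(max_insert_len, j_max)) {
      ref <- reference_fetch(left_flank - (n - j) + 1L, left_flank)
      if (substr(head_cons, 1L, n - j) == ref)
        return(substr(head_cons, n - j + 1L, n))
    }
  }
  if (j_max >= max_insert_len)
    stop_hemidel("clipped head does not match reference before the junction",
                 "hemidel_ambiguous_junction")
  NULL
}

anchor_right_flank <- function(tail_cons, reference_fetch, bracket,
                               max_insert_len, anchor_len, pad = 500L) {
  if (is.null(tail_cons) || nchar(tail_cons) < anchor_len) return(NA_integer_)
  win_start <- bracket$hi - pad
  ref <- try(reference_fetch(win_start, bracket$hi + anchor_len), silent = TRUE)
  if (inherits(ref, "try-error")) return(NA_integer_)
  n <- nchar(tail_cons)
  for (i in 0:min(max_insert_len, n - anchor_len)) {
    anchor <- substr(tail_cons, i + 1L, i + anchor_len)
    hits <- gregexpr(anchor, ref, fixed = TRUE)[[1]]
    hits <- hits[hits > 0]
    if (length(hits) == 1) {
      cand <- win_start + hits - 1L
      rest <- reference_fetch(cand, cand + (n - i) - 1L)
      if (substr(tail_cons, i + 1L, n) == rest) return(as.integer(cand))
    }
  }
  NA_integer_
}

anchor_left_flank <- function(head_cons, reference_fetch, bracket,
                              max_insert_len, anchor_len, pad = 500L) {
  if (is.null(head_cons) || nchar(head_cons) < anchor_len) return(NA_integer_)
  win_start <- bracket$lo - anchor_len
  ref <- try(reference_fetch(win_start, bracket$lo + pad), silent = TRUE)
  if (inherits(ref, "try-error")) return(NA_integer_)
  n <- nchar(head_cons)
  for (j in 0:min(max_insert_len, n - anchor_len)) {
    anchor <- substr(head_cons, n - j - anchor_len + 1L, n - j)
    hits <- gregexpr(anchor, ref, fixed = TRUE)[[1]]
    hits <- hits[hits > 0]
    if (length(hits) == 1) {
      cand <- win_start + hits + anchor_len - 2L  # ref pos of anchor's last base
      core <- reference_fetch(cand - (n - j) + 1L, cand)
      if (substr(head_cons, 1L, n - j) == core) return(as.integer(cand))
    }
  }
  NA_integer_
}

#' Deleted length between two retained flanking bases
#'
#' The printed breakpoint positions are the last retained base before and
#' the first retained base after the deletion, so the deleted interval is
#' open: `length = right_flank - left_flank - 1`.
#'
#' @param left_flank,right_flank 1-based positions of the retained flanks;
#'   `right_flank >= left_flank + 2`.
#' @return deleted length in bp.
#' @export
deletion_length <- function(left_flank, right_flank) {
  if (any(right_flank < left_flank + 2))
    stop_hemidel("right_flank must be >= left_flank + 2 (nothing deleted otherwise)",
                 "hemidel_length_error")
  right_flank - left_flank - 1L
}

#' Merge depth-segmentation and junction evidence into one deletion call
#'
#' Junction coordinates take precedence over window-resolution depth
#' segments.  A junction without an overlapping hemizygous depth segment is
#' flagged discordant; a hemizygous segment without a junction yields a
#' window-resolution call.
#'
#' @param segments a `depth_segments` table from [segment_depth()] (or NULL).
#' @param junction a `junction_call` from [assemble_junction()] (or NULL).
#' @return list of class `deletion_call` with `junction`, `segment`,
#'   `interval` (deleted interval, 1-based inclusive), `length_bp` and
#'   `evidence` flag: "concordant", "junction_only_discordant_depth",
#'   "depth_only" or "no_evidence".
#' @export
merge_evidence <- function(segments, junction) {
  hemi <- if (!is.null(segments))
    segments[segments$state == "hemizygous", , drop = FALSE] else NULL
  seg <- NULL
  if (!is.null(junction)) {
    interval <- c(junction$left_flank + 1L, junction$right_flank - 1L)
    len <- deletion_length(junction$left_flank, junction$right_flank)
    overlap <- !is.null(hemi) && nrow(hemi) > 0 &&
      any(hemi$start <= interval[2] & hemi$end >= interval[1])
    if (overlap) {
      hit <- hemi[hemi$start <= interval[2] & hemi$end >= interval[1], ]
      seg <- hit[which.max(hit$end - hit$start), , drop = FALSE]
    }
    flag <- if (overlap) "concordant" else "junction_only_discordant_depth"
  } else if (!is.null(hemi) && nrow(hemi) > 0) {
    seg <- hemi[which.max(hemi$end - hemi$start), , drop = FALSE]
    interval <- c(seg$start, seg$end)
    len <- seg$end - seg$start + 1L
    flag <- "depth_only"
  } else {
    interval <- NULL; len <- NA_integer_; flag <- "no_evidence"
  }
  structure(list(junction = junction, segment = seg, interval = interval,
                 length_bp = len, evidence = flag),
            class = "deletion_call")
}
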