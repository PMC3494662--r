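## Seeded synthetic-cohort generator.  The model: a founder sire is germline
## mosaic (fraction m of germ cells heterozygous) for a multi-megabase
## deletion with a short non-template insertion at the junction; carrier
## males die before birth with probability lambda; SNP arrays call a
## hemizygous marker as homozygous for the remaining (maternal) allele.

#' Simulation configuration for the synthetic cohort
#'
#' Defaults reproduce the design scale of the study the generator emulates:
#' a sire genotyped with 19 unaffected and 3 affected daughters plus the
#' affected daughters' dams, a ~3.7 Mb deletion with a 4-bp "ACAT" junction
#' insertion, two sperm-FISH experiments of 1000 spermatozoa, 165 genotyped
#' blastocysts, 76 births, 61 AI records (26 successes, 35 failures of which
#' 1+6+8 are artifacts), germline mosaicism 0.68 and male-carrier lethality
#' 0.86.
#'
#' @param seed integer RNG seed; the whole bundle is a deterministic function
#'   of it.
#' @param n_markers number of array markers on the simulated chromosome.
#' @param chrom,chrom_length chromosome name and length (bp).
#' @param deletion_start_flank,deletion_end_flank last retained base before /
#'   first retained base after the deletion (1-based).
#' @param inserted_seq non-template sequence inserted at the junction.
#' @param mosaicism germline mosaicism m in \[0,1\] (fraction of germ cells
#'   heterozygous for the deletion); carrier-sperm fraction is m/2.
#' @param male_lethality probability lambda that a male carrier conceptus
#'   dies between blastocyst and birth.
#' @param n_progeny_birth number of recorded births.
#' @param n_sperm_scored integer vector of spermatozoa scored per sperm-FISH
#'   experiment.
#' @param n_blastocysts number of genotyped blastocysts.
#' @param genotyping_error_rate per-call probability of a random wrong call.
#' @param hemizygote_nocall_rate per-call no-call probability at hemizygous
#'   markers.
#' @param mean_depth mean sequencing depth per window at diploid copy number.
#' @param insert_mean,insert_sd sequencing fragment-size distribution (bp).
#' @param read_len read length (bp).
#' @param maf_range range minor-allele frequencies are drawn from.
#' @param n_unaffected_genotyped,n_affected_genotyped genotyped progeny counts.
#' @param depth_window_bp depth window width (bp).
#' @param n_junction_fragments sequencing fragments sampled around the
#'   deletion junction on the carrier haplotype.
#' @param n_background_pairs concordant background read pairs.
#' @param ref_flank_bp synthetic reference sequence cached on each side of
#'   each true flank.
#' @param n_ai_success,n_ai_failure AI outcome totals.
#' @param ai_artifact_counts named vector: failures attributable to
#'   superovulation, adjacent AI and low-fertility cows.
#' @param death_day_bound latent upper bound (days) on conceptus death day
#'   used to generate clean failure records.
#' @param cycle_days,gestation_days average sexual cycle and gestation
#'   lengths (days).
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_markers = 6000L,
                              chrom = "2",
                              chrom_length = 120e6,
                              deletion_start_flank = 49422588L,
                              deletion_end_flank = 53130732L,
                              inserted_seq = "ACAT",
                              mosaicism = 0.68,
                              male_lethality = 0.86,
                              n_progeny_birth = 76L,
                              n_sperm_scored = c(1000L, 1000L),
                              n_blastocysts = 165L,
                              genotyping_error_rate = 0.002,
                              hemizygote_nocall_rate = 0.02,
                              mean_depth = 12,
                              insert_mean = 300,
                              insert_sd = 30,
                              read_len = 100L,
                              maf_range = c(0.05, 0.5),
                              n_unaffected_genotyped = 19L,
                              n_affected_genotyped = 3L,
                              depth_window_bp = 10000L,
                              n_junction_fragments = 60L,
                              n_background_pairs = 200L,
                              ref_flank_bp = 1000L,
                              n_ai_success = 26L,
                              n_ai_failure = 35L,
                              ai_artifact_counts = c(superovulation = 1L,
                                                     adjacent_ai = 6L,
                                                     low_fertility = 8L),
                              death_day_bound = 88L,
                              cycle_days = 21L,
                              gestation_days = 285L) {
  cfg <- as.list(environment())
  rates <- c(mosaicism = mosaicism, male_lethality = male_lethality,
             genotyping_error_rate = genotyping_error_rate,
             hemizygote_nocall_rate = hemizygote_nocall_rate)
  if (any(rates < 0 | rates > 1))
    stop_hemidel("all rates must lie in [0, 1]", "hemidel_config_error")
  if (deletion_end_flank < deletion_start_flank + 2)
    stop_hemidel("deletion_end_flank must be >= deletion_start_flank + 2",
                 "hemidel_config_error")
  if (deletion_end_flank > chrom_length)
    stop_hemidel("deletion lies outside the chromosome", "hemidel_config_error")
  if (!grepl("^[ACGT]*$", inserted_seq))
    stop_hemidel("inserted_seq must be a DNA string", "hemidel_config_error")
  if (mean_depth < 0 || insert_mean <= 0 || insert_sd < 0 || read_len < 1)
    stop_hemidel("invalid sequencing parameters", "hemidel_config_error")
  if (sum(cfg$ai_artifact_counts) > n_ai_failure)
    stop_hemidel("AI artifact counts exceed failure total", "hemidel_config_error")
  if (!setequal(names(cfg$ai_artifact_counts),
                c("superovulation", "adjacent_ai", "low_fertility")))
    stop_hemidel("ai_artifact_counts must be named superovulation, adjacent_ai, low_fertility",
                 "hemidel_config_error")
  ## a cohort with no mosaic germ cells cannot contain affected progeny
  if (mosaicism == 0) cfg$n_affected_genotyped <- 0L
  structure(cfg, class = "simulation_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Reference cache: synthetic sequence around the two true flanks only.
## fetch(start, end) errors outside the cached segments; junction assembly
## never reads elsewhere.
make_reference_fetch <- function(left_flank, right_flank, flank_bp) {
  segs <- list(
    list(start = left_flank - flank_bp + 1L, seq = random_dna(2L * flank_bp)),
    list(start = right_flank - flank_bp,     seq = random_dna(2L * flank_bp))
  )
  function(start, end) {
    start <- as.integer(start); end <- as.integer(end)
    for (s in segs) {
      send <- s$start + nchar(s$seq) - 1L
      if (start >= s$start && end <= send)
        return(substr(s$seq, start - s$start + 1L, end - s$start + 1L))
    }
    stop_hemidel(sprintf("reference not cached for interval [%d, %d]", start, end),
                 "hemidel_reference_error")
  }
}

simulate_marker_map <- function(cfg) {
  pos <- sort(sample.int(as.integer(cfg$chrom_length), cfg$n_markers))
  marker_map(data.frame(
    marker_id = sprintf("M%05d", seq_len(cfg$n_markers)),
    chrom = cfg$chrom, pos = pos, allele_a = "A", allele_b = "B",
    maf = stats::runif(cfg$n_markers, cfg$maf_range[1], cfg$maf_range[2])
  ))
}

make_cohort_pedigree <- function(cfg) {
  n_u <- cfg$n_unaffected_genotyped
  n_a <- cfg$n_affected_genotyped
  unaff <- if (n_u > 0) sprintf("UNAFF%02d", seq_len(n_u)) else character(0)
  aff <- if (n_a > 0) sprintf("AFF%d", seq_len(n_a)) else character(0)
  dams_u <- if (n_u > 0) sprintf("DAM_U%02d", seq_len(n_u)) else character(0)
  dams_a <- if (n_a > 0) sprintf("DAM_A%d", seq_len(n_a)) else character(0)
  pedigree(data.frame(
    animal_id = c("SIRE", dams_u, dams_a, unaff, aff),
    sire_id = c(NA, rep(NA, n_u + n_a), rep("SIRE", n_u + n_a)),
    dam_id = c(NA, rep(NA, n_u + n_a), dams_u, dams_a),
    sex = c("M", rep("F", n_u + n_a),
            rep(c("M", "F"), length.out = n_u), rep("F", n_a)),
    phenotype = c("unaffected", rep("unknown", n_u + n_a),
                  rep("unaffected", n_u), rep("affected", n_a)),
    stringsAsFactors = FALSE
  ))
}

#' Simulate array genotypes for a sire-progeny cohort
#'
#' Founders (sire and dams) are drawn in Hardy-Weinberg proportions from each
#' marker's MAF; progeny receive one Mendelian allele from each parent.  For
#' deletion carriers, markers strictly inside the deleted interval lose the
#' paternal allele and are called homozygous for the maternal allele (what an
#' array reports for a hemizygote), with a small no-call rate; every call is
#' additionally subject to a random flip at `genotyping_error_rate`.
#'
#' The genotyped sample set is the sire, all progeny, and the dams of
#' affected progeny (matching the study design the generator emulates).
#'
#' @param ped a [pedigree()] as built by [simulate_cohort()].
#' @param map a [marker_map()].
#' @param truth list with `left_flank`, `right_flank`, `carrier_ids`.
#' @param cfg a [simulation_config()] (error/no-call rates are read from it).
#' @return a [genotype_matrix()].  Uses the current RNG state; seed before
#'   calling for reproducibility.
#' @export
simulate_genotypes <- function(ped, map, truth, cfg) {
  if (any(map$pos > cfg$chrom_length))
    stop_hemidel("marker outside chromosome", "hemidel_config_error")
  nm <- nrow(map)
  maf <- map$maf
  in_del <- map$chrom == truth$chrom &
    map$pos > truth$left_flank & map$pos < truth$right_flank

  founders <- ped$animal_id[is.na(ped$sire_id)]
  progeny <- ped$animal_id[!is.na(ped$sire_id)]
  ## founder haplotypes: per-allele Bernoulli(maf) for allele B
  hap <- list()
  for (id in founders)
    hap[[id]] <- rbind(stats::rbinom(nm, 1, maf), stats::rbinom(nm, 1, maf))

  transmit <- function(id) {
    h <- hap[[id]]
    pick <- stats::rbinom(nm, 1, 0.5)
    ifelse(pick == 1, h[2, ], h[1, ])
  }

  calls <- list()
  for (id in founders) calls[[id]] <- colSums(hap[[id]])
  for (id in progeny) {
    row <- ped[ped$animal_id == id, ]
    pat <- transmit(row$sire_id)
    mat <- transmit(row$dam_id)
    g <- pat + mat
    if (id %in% truth$carrier_ids) {
      ## paternal allele deleted: array sees the maternal allele only
      g[in_del] <- 2L * mat[in_del]
      nocall <- in_del & stats::runif(nm) < cfg$hemizygote_nocall_rate
      g[nocall] <- -1L
    }
    calls[[id]] <- g
  }

  sire <- unique(ped$sire_id[!is.na(ped$sire_id)])
  genotyped <- c(sire,
                 ped$animal_id[!is.na(ped$sire_id)],
                 ped$dam_id[ped$phenotype == "affected" & !is.na(ped$dam_id)])
  genotyped <- intersect(unique(genotyped), names(calls))
  gm <- do.call(rbind, calls[genotyped])

  if (cfg$genotyping_error_rate > 0) {
    flip <- gm != -1L & matrix(stats::runif(length(gm)) < cfg$genotyping_error_rate,
                               nrow = nrow(gm))
    if (any(flip)) {
      idx <- which(flip)
      gm[idx] <- vapply(gm[idx], function(g)
        sample(setdiff(c(0L, 1L, 2L), g), 1L), integer(1))
    }
  }
  genotype_matrix(gm, genotyped, map$marker_id)
}

#' Simulate a windowed sequencing depth profile
#'
#' Window depth is Poisson with mean `mean_depth * copy / 2`; copy number is
#' 1 inside the deletion for a carrier and 2 elsewhere (window membership by
#' midpoint).
#'
#' @param truth list with `left_flank`, `right_flank`, `chrom`.
#' @param cfg a [simulation_config()].
#' @param carrier logical; does the sequenced animal carry the deletion?
#' @return a [depth_profile()].
#' @export
simulate_depth <- function(truth, cfg, carrier) {
  starts <- seq(1L, as.integer(cfg$chrom_length), by = cfg$depth_window_bp)
  ends <- pmin(starts + cfg$depth_window_bp - 1L, as.integer(cfg$chrom_length))
  mid <- (starts + ends) / 2
  copy <- rep(2, length(starts))
  if (carrier)
    copy[mid > truth$left_flank & mid < truth$right_flank] <- 1
  depth <- stats::rpois(length(starts), cfg$mean_depth * copy / 2)
  depth_profile(data.frame(chrom = truth$chrom, start = starts, end = ends,
                           depth = depth),
                genome_median_depth = if (cfg$mean_depth > 0)
                  stats::median(depth) else NULL)
}

## Sequence of the carrier (deleted) haplotype in its own coordinates:
## ... left flank | inserted_seq | right flank ...
variant_seq_fetch <- function(truth, reference_fetch) {
  L <- truth$left_flank; R <- truth$right_flank
  I <- nchar(truth$inserted_seq); D <- R - L - 1L
  function(a, b) {
    out <- character(0)
    if (a <= L) out <- c(out, reference_fetch(a, min(b, L)))
    if (b > L && a <= L + I) {
      i0 <- max(a, L + 1L) - L; i1 <- min(b, L + I) - L
      out <- c(out, substr(truth$inserted_seq, i0, i1))
    }
    if (b > L + I) out <- c(out, reference_fetch(max(a, L + I + 1L) - I + D,
                                                 b - I + D))
    paste(out, collapse = "")
  }
}

#' Simulate read-pair and clipped-read evidence over the deletion junction
#'
#' Fragments are sampled on the carrier haplotype around the junction
#' (fragment size Normal(`insert_mean`, `insert_sd`)).  Pairs straddling the
#' junction get their reference-implied insert inflated by
#' (deletion length - insertion length); reads overlapping the junction are
#' emitted soft-clipped, with the clipped sequence read off the variant
#' haplotype (so it begins with, or ends in, the inserted sequence).
#' Concordant background pairs are added away from the junction.  Reads with
#' fewer than 20 alignable bases on either side are dropped (unmappable);
#' clips shorter than 5 bp are absorbed into a normal alignment.
#'
#' @param truth list with `chrom`, `left_flank`, `right_flank`,
#'   `inserted_seq`.
#' @param cfg a [simulation_config()].
#' @param reference_fetch function(start, end) returning reference sequence
#'   (as built by [simulate_cohort()]).
#' @return a [pair_evidence()] table.
#' @export
simulate_pairs <- function(truth, cfg, reference_fetch) {
  L <- as.integer(truth$left_flank); R <- as.integer(truth$right_flank)
  I <- nchar(truth$inserted_seq); D <- R - L - 1L
  rl <- as.integer(cfg$read_len)
  min_anchor <- 20L
  vfetch <- variant_seq_fetch(truth, reference_fetch)
  v2r <- function(u) ifelse(u <= L, u, u - I + D)  # variant -> reference (aligned part)

  rows <- list()
  add <- function(read_id, pos, mate_pos, insert, clip_side, clipped_seq) {
    rows[[length(rows) + 1L]] <<- data.frame(
      read_id = read_id, chrom = truth$chrom, pos = as.integer(pos),
      mate_pos = as.integer(mate_pos), insert = as.integer(insert),
      clip_side = clip_side, clipped_seq = clipped_seq,
      stringsAsFactors = FALSE)
  }

  ## describe one read [a, b] in variant coordinates; NULL = unmappable.
  ## Reads not touching the junction are fully aligned; junction-overlapping
  ## reads are soft-clipped at the flank provided the aligned side has at
  ## least min_anchor bases.
  describe <- function(a, b) {
    if (b <= L || a > L + I) {
      return(list(pos = v2r(a), clip = "none", seq = ""))
    }
    left_len <- max(0L, L - a + 1L)
    right_len <- max(0L, b - (L + I))
    if (left_len >= min_anchor) {
      list(pos = a, clip = "right", seq = vfetch(L + 1L, b))
    } else if (right_len >= min_anchor) {
      list(pos = R, clip = "left", seq = vfetch(a, L + I))
    } else {
      NULL
    }
  }

  if (cfg$n_junction_fragments > 0) {
    frag <- pmax(2L * rl + 10L,
                 as.integer(round(stats::rnorm(cfg$n_junction_fragments,
                                               cfg$insert_mean, cfg$insert_sd))))
    u0 <- as.integer(round(stats::runif(cfg$n_junction_fragments,
                                        L - cfg$insert_mean - 100, L + 100)))
    for (i in seq_len(cfg$n_junction_fragments)) {
      a1 <- u0[i]; b1 <- a1 + rl - 1L
      b2 <- a1 + frag[i] - 1L; a2 <- b2 - rl + 1L
      r1 <- describe(a1, b1); r2 <- describe(a2, b2)
      ins <- v2r(a2) + rl - v2r(a1)
      if (ins <= 0) next
      if (!is.null(r1) && !is.null(r2)) {
        add(sprintf("J%03d_1", i), r1$pos, r2$pos, ins, r1$clip, r1$seq)
        add(sprintf("J%03d_2", i), r2$pos, r1$pos, ins, r2$clip, r2$seq)
      }
    }
  }
  if (cfg$n_background_pairs > 0) {
    pos <- sample.int(as.integer(cfg$chrom_length) - 3L * as.integer(cfg$insert_mean),
                      cfg$n_background_pairs)
    ins <- pmax(2L * rl, as.integer(round(stats::rnorm(cfg$n_background_pairs,
                                                       cfg$insert_mean,
                                                       cfg$insert_sd))))
    for (i in seq_len(cfg$n_background_pairs)) {
      add(sprintf("B%04d_1", i), pos[i], pos[i] + ins[i] - rl, ins[i], "none", "")
      add(sprintf("B%04d_2", i), pos[i] + ins[i] - rl, pos[i], ins[i], "none", "")
    }
  }
  pair_evidence(if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(read_id = character(0), chrom = character(0), pos = integer(0),
               mate_pos = integer(0), insert = integer(0),
               clip_side = character(0), clipped_seq = character(0)))
}

#' Simulate per-stage transmission count tables
#'
#' Sperm: carrier count Binomial(n, m/2) per sperm-FISH experiment, sex
#' (X/Y) split 1:1 independently of carrier status.  Blastocysts: no
#' selection, carrier probability m/2, sex 1:1.  Births: survivors of
#' male-carrier lethality; each of `n_progeny_birth` births falls in a
#' category with probability proportional to (1-m/2)/2 for non-carriers of
#' each sex, (m/2)/2 for carrier females and (m/2)(1-lambda)/2 for carrier
#' males.
#'
#' @param cfg a [simulation_config()].
#' @return list with elements `sperm`, `blastocyst`, `birth`
#'   ([transmission_counts()] objects) and `sperm_experiments` (data.frame of
#'   per-experiment n and carrier count k).
#' @export
simulate_transmission_counts <- function(cfg) {
  m <- cfg$mosaicism; lam <- cfg$male_lethality
  four_cells <- function(n, p_del) {
    k <- stats::rbinom(1, n, p_del)
    m_del <- stats::rbinom(1, k, 0.5)
    m_wt <- stats::rbinom(1, n - k, 0.5)
    c(M.del = m_del, M.wt = m_wt, F.del = k - m_del, F.wt = n - k - m_wt)
  }
  k_exp <- stats::rbinom(length(cfg$n_sperm_scored), cfg$n_sperm_scored, m / 2)
  K <- sum(k_exp); N <- sum(cfg$n_sperm_scored)
  m_del <- stats::rbinom(1, K, 0.5)
  m_wt <- stats::rbinom(1, N - K, 0.5)
  sperm <- transmission_counts("sperm", c(M.del = m_del, M.wt = m_wt,
                                          F.del = K - m_del, F.wt = N - K - m_wt))
  blast <- transmission_counts("blastocyst",
                               four_cells(cfg$n_blastocysts, m / 2))
  p <- c(M.del = (m / 2) * (1 - lam), M.wt = (1 - m / 2),
         F.del = m / 2, F.wt = (1 - m / 2)) / 2
  birth_v <- stats::rmultinom(1, cfg$n_progeny_birth, p / sum(p))[, 1]
  birth <- transmission_counts("birth", birth_v)
  list(sperm = sperm, blastocyst = blast, birth = birth,
       sperm_experiments = data.frame(n = cfg$n_sperm_scored, k = k_exp))
}

#' Simulate artificial-insemination records
#'
#' Generates `n_ai_success` successes and `n_ai_failure` failures.  Clean
#' failures carry a next event (another AI or a calving) consistent with a
#' latent conceptus death day <= `death_day_bound`: the cow returns to heat
#' within one cycle of the death, so the implied gestation-length bound
#' (interval minus cycle length, minus gestation length for calvings) never
#' exceeds the truth bound.  Three disjoint artifact categories are injected
#' per `ai_artifact_counts`: a superovulation-flagged failure, failures with
#' another AI on the following day, and failures of low-fertility cows (>= 3
#' consecutive failures).
#'
#' @param cfg a [simulation_config()].
#' @return an [ai_records()] table.
#' @export
simulate_ai_records <- function(cfg) {
  art <- cfg$ai_artifact_counts
  n_clean <- cfg$n_ai_failure - sum(art)
  rows <- list()
  add <- function(cow, day, outcome, sup, nev, nev_day, cf) {
    rows[[length(rows) + 1L]] <<- data.frame(
      cow_id = cow, ai_day = as.integer(day), outcome = outcome,
      superovulation = sup, next_event = nev,
      next_event_day = if (is.na(nev_day)) NA_integer_ else as.integer(nev_day),
      consecutive_failures_for_cow = as.integer(cf), stringsAsFactors = FALSE)
  }
  ## clean failures: death day d in [8, bound], heat within one cycle
  if (n_clean > 0) {
    d <- sample(8:cfg$death_day_bound, n_clean, replace = TRUE)
    u <- sample(seq_len(cfg$cycle_days), n_clean, replace = TRUE)
    day0 <- sample.int(300L, n_clean, replace = TRUE)
    calve <- stats::runif(n_clean) < 0.5
    for (i in seq_len(n_clean)) {
      nev <- if (calve[i]) "calving" else "ai"
      nev_day <- day0[i] + d[i] + u[i] + if (calve[i]) cfg$gestation_days else 0L
      add(sprintf("CLEAN%02d", i), day0[i], "failure", FALSE, nev, nev_day, 1L)
    }
  }
  if (art[["superovulation"]] > 0) {
    for (i in seq_len(art[["superovulation"]]))
      add(sprintf("SUP%d", i), 50L + i, "failure", TRUE, "ai", 150L + i, 1L)
  }
  n_adj <- art[["adjacent_ai"]]
  if (n_adj > 0) {
    for (i in seq_len(n_adj)) {
      day <- 10L * i
      add(sprintf("ADJ%d", i), day, "failure", FALSE, "ai", day + 1L, 1L)
      ## the companion AI the next day (counted among the successes)
      add(sprintf("ADJ%d", i), day + 1L, "success", FALSE, "calving",
          day + 1L + cfg$gestation_days, 1L)
    }
  }
  n_lf <- art[["low_fertility"]]
  if (n_lf > 0) {
    per_cow <- c(rep(3L, n_lf %/% 3L - 1L),
                 3L + n_lf %% 3L)  # e.g. 8 -> one cow of 3 and one of 5
    if (n_lf < 3L) per_cow <- n_lf  # degenerate configs
    ci <- 0L
    for (nc in per_cow) {
      ci <- ci + 1L
      day <- 400L + 100L * ci
      for (j in seq_len(nc)) {
        nev <- if (j < nc) "ai" else "none"
        nev_day <- if (j < nc) day + j * cfg$cycle_days else NA
        add(sprintf("LF%d", ci), day + (j - 1L) * cfg$cycle_days, "failure",
            FALSE, nev, nev_day, j)
      }
    }
  }
  n_succ_extra <- cfg$n_ai_success - n_adj
  if (n_succ_extra > 0) {
    for (i in seq_len(n_succ_extra))
      add(sprintf("SUCC%02d", i), 5L * i, "success", FALSE, "calving",
          5L * i + cfg$gestation_days + sample(-5:5, 1L), 1L)
  }
  ai_records(do.call(rbind, rows))
}

#' Generate a complete seeded synthetic cohort with ground truth
#'
#' Produces, deterministically from `cfg$seed`: a cohort pedigree, marker
#' map, genotype matrix (hemizygous deletion rendered as apparent
#' homozygosity in affected progeny), carrier and control depth profiles,
#' read-pair/clip evidence over the junction, per-stage transmission counts,
#' AI records, a synthetic reference fetcher for the junction neighbourhood,
#' and the ground truth needed for parameter-recovery tests.
#'
#' @param cfg a [simulation_config()].
#' @return list of class `cohort_bundle` with elements `pedigree`,
#'   `marker_map`, `genotypes`, `depth_carrier`, `depth_control`, `pairs`,
#'   `counts`, `ai_records`, `reference_fetch`, `config` and `truth` (list:
#'   `chrom`, `left_flank`, `right_flank`, `deleted_interval`, `length_bp`,
#'   `inserted_seq`, `mosaicism`, `male_lethality`, `death_day_bound`,
#'   `carrier_ids`).
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  L <- as.integer(cfg$deletion_start_flank)
  R <- as.integer(cfg$deletion_end_flank)
  ped <- make_cohort_pedigree(cfg)
  truth <- list(
    chrom = cfg$chrom, left_flank = L, right_flank = R,
    deleted_interval = c(L + 1L, R - 1L), length_bp = R - L - 1L,
    inserted_seq = cfg$inserted_seq, mosaicism = cfg$mosaicism,
    male_lethality = cfg$male_lethality,
    death_day_bound = cfg$death_day_bound,
    carrier_ids = ped$animal_id[ped$phenotype == "affected"])
  map <- simulate_marker_map(cfg)
  gm <- simulate_genotypes(ped, map, truth, cfg)
  depth_carrier <- simulate_depth(truth, cfg, carrier = TRUE)
  depth_control <- simulate_depth(truth, cfg, carrier = FALSE)
  reference_fetch <- make_reference_fetch(L, R, as.integer(cfg$ref_flank_bp))
  pairs <- simulate_pairs(truth, cfg, reference_fetch)
  tc <- simulate_transmission_counts(cfg)
  ai <- simulate_ai_records(cfg)
  structure(list(
    pedigree = ped, marker_map = map, genotypes = gm,
    depth_carrier = depth_carrier, depth_control = depth_control,
    pairs = pairs,
    counts = tc[c("sperm", "blastocyst", "birth")],
    sperm_experiments = tc$sperm_experiments,
    ai_records = ai, reference_fetch = reference_fetch,
    config = cfg, truth = truth), class = "cohort_bundle")
}

#' Write a cohort bundle to a directory in the pipeline's file formats
#'
#' @param bundle a `cohort_bundle` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_pedigree(bundle$pedigree, file.path(dir, "pedigree.tsv"))
  write_marker_map(bundle$marker_map, file.path(dir, "markers.tsv"))
  write_genotypes(bundle$genotypes, file.path(dir, "genotypes.tsv"))
  write_depth(bundle$depth_carrier, file.path(dir, "depth_carrier.tsv"))
  write_depth(bundle$depth_control, file.path(dir, "depth_control.tsv"))
  write_pairs(bundle$pairs, file.path(dir, "pairs.tsv"))
  write_counts(bundle$counts, file.path(dir, "counts.tsv"))
  write_ai_records(bundle$ai_records, file.path(dir, "ai_records.csv"))
  truth <- bundle$truth
  jsonlite::write_json(truth[setdiff(names(truth), "carrier_ids")],
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
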