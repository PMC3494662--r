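test_that("the same seed reproduces the cohort bit-for-bit", {
  b1 <- simulate_cohort(small_cfg(seed = 11))
  b2 <- simulate_cohort(small_cfg(seed = 11))
  for (el in c("pedigree", "marker_map", "genotypes", "pairs", "ai_records"))
    expect_identical(b1[[el]], b2[[el]], label = el)
  expect_identical(b1$depth_carrier$windows, b2$depth_carrier$windows)
  expect_identical(b1$counts$birth$counts, b2$counts$birth$counts)
  expect_identical(b1$reference_fetch(b1$truth$left_flank - 50,
                                      b1$truth$left_flank),
                   b2$reference_fetch(b2$truth$left_flank - 50,
                                      b2$truth$left_flank))

  b3 <- simulate_cohort(small_cfg(seed = 12))
  expect_false(identical(b1$genotypes, b3$genotypes))
})

test_that("zero mosaicism means no carrier sperm and no affected progeny", {
  cfg <- small_cfg(seed = 2, mosaicism = 0)
  b <- simulate_cohort(cfg)
  sv <- as_count_vector(b$counts$sperm)
  bv <- as_count_vector(b$counts$birth)
  expect_identical(unname(sv[["M.del"]] + sv[["F.del"]]), 0)
  expect_identical(unname(bv[["M.del"]] + bv[["F.del"]]), 0)
  expect_identical(sum(b$pedigree$phenotype == "affected"), 0L)
})

test_that("full mosaicism without lethality gives half carriers in both sexes at birth", {
  # binomial oracle: pooled carrier count over seeds ~ Binom(total, 1/2)
  tot <- c(M = 0, F = 0); del <- c(M = 0, F = 0)
  for (s in 1:20) {
    cfg <- small_cfg(seed = s, mosaicism = 1, male_lethality = 0)
    v <- as_count_vector(simulate_cohort(cfg)$counts$birth)
    del <- del + c(M = v[["M.del"]], F = v[["F.del"]])
    tot <- tot + c(M = v[["M.del"]] + v[["M.wt"]], F = v[["F.del"]] + v[["F.wt"]])
  }
  for (sx in c("M", "F")) {
    se <- sqrt(tot[[sx]] * 0.25)
    expect_lt(abs(del[[sx]] - tot[[sx]] / 2), 3 * se)
  }
})

test_that("affected progeny appear homozygous (or no-call) across the deleted interval", {
  b <- simulate_cohort(simulation_config(seed = 7))
  in_del <- b$marker_map$pos > b$truth$left_flank &
    b$marker_map$pos < b$truth$right_flank
  for (id in b$truth$carrier_ids) {
    calls <- b$genotypes[id, in_del]
    n_het <- sum(calls == 1L)
    # heterozygous calls inside the deletion can only be genotyping errors
    expect_lte(n_het, stats::qbinom(0.999, sum(in_del),
                                    b$config$genotyping_error_rate))
  }
})

test_that("without genotyping error, Mendelian errors are confined to the deletion", {
  cfg <- simulation_config(seed = 5, genotyping_error_rate = 0,
                           n_unaffected_genotyped = 300L)
  b <- simulate_cohort(cfg)
  prof <- build_error_profile(b$genotypes, b$pedigree, "SIRE")
  in_del <- b$marker_map$pos > b$truth$left_flank &
    b$marker_map$pos < b$truth$right_flank
  expect_identical(sum(prof$n_errors_unaffected), 0L)
  expect_identical(sum(prof$n_errors_affected[!in_del]), 0L)
  expect_gt(sum(prof$n_errors_affected[in_del]), 0L)
  # and affected animals are never heterozygous inside the deletion
  expect_identical(sum(prof$n_het_affected[in_del]), 0L)
})

test_that("carrier depth halves inside the deletion (Poisson oracle)", {
  depth_in <- c(); depth_out <- c()
  for (s in 1:10) {
    cfg <- small_cfg(seed = s)
    b <- simulate_cohort(cfg)
    w <- b$depth_carrier$windows
    mid <- (w$start + w$end) / 2
    inside <- mid > b$truth$left_flank & mid < b$truth$right_flank
    depth_in <- c(depth_in, w$depth[inside])
    depth_out <- c(depth_out, w$depth[!inside])
  }
  mu <- small_cfg(1)$mean_depth
  expect_lt(abs(mean(depth_in) - mu / 2), 3 * sqrt(mu / 2 / length(depth_in)))
  expect_lt(abs(mean(depth_out) - mu), 3 * sqrt(mu / length(depth_out)))

  ctrl <- simulate_cohort(small_cfg(seed = 1))$depth_control
  r <- normalize_depth(ctrl)$windows$ratio
  expect_lt(abs(mean(r) - 1), 0.05)

  cfg0 <- small_cfg(seed = 1, mean_depth = 0)
  b0 <- simulate_depth(list(chrom = "2", left_flank = 8e6, right_flank = 8.6e6),
                       cfg0, carrier = TRUE)
  expect_identical(unique(b0$windows$depth), 0L)
})

test_that("junction-straddling pairs carry the deletion-inflated insert", {
  cfg <- small_cfg(seed = 4)
  b <- simulate_cohort(cfg)
  D <- b$truth$right_flank - b$truth$left_flank - 1L
  I <- nchar(b$truth$inserted_seq)
  disc <- b$pairs[b$pairs$insert > cfg$insert_mean + 4 * cfg$insert_sd, ]
  expect_gt(nrow(disc), 0)
  # observed insert = fragment + (deletion length - insertion length)
  frag_implied <- disc$insert - (D - I)
  expect_true(all(abs(frag_implied - cfg$insert_mean) < 6 * cfg$insert_sd))

  rc <- b$pairs[b$pairs$clip_side == "right" & nchar(b$pairs$clipped_seq) >= I, ]
  expect_gt(nrow(rc), 0)
  expect_true(all(startsWith(rc$clipped_seq, b$truth$inserted_seq)))
  lc <- b$pairs[b$pairs$clip_side == "left" & nchar(b$pairs$clipped_seq) >= I, ]
  expect_true(all(endsWith(lc$clipped_seq, b$truth$inserted_seq)))

  # no fragments sampled near the junction -> no junction-spanning evidence
  cfg0 <- small_cfg(seed = 4, n_junction_fragments = 0L, n_background_pairs = 0L)
  b0 <- simulate_cohort(cfg0)
  expect_identical(nrow(b0$pairs), 0L)
  expect_null(locate_breakpoints_from_pairs(b0$pairs, cfg0$insert_mean,
                                            cfg0$insert_sd))
})

test_that("generated AI records honour the configured artifact accounting", {
  set.seed(9)
  cfg <- simulation_config(seed = 9)
  rec <- simulate_ai_records(cfg)
  expect_identical(sum(rec$outcome == "failure"), 35L)
  expect_identical(sum(rec$outcome == "success"), 26L)
  flt <- filter_ai_records(rec)
  expect_identical(nrow(flt$retained), 20L)
  expect_identical(as.integer(table(flt$discarded$reason)[
    c("superovulation", "adjacent_ai", "low_fertility")]), c(1L, 6L, 8L))

  # clean records' implied bounds never exceed the generator's truth bound
  for (s in 1:10) {
    cfg <- simulation_config(seed = s)
    flt <- filter_ai_records(simulate_ai_records(cfg))
    lw <- lethality_window(flt$retained)
    expect_lte(lw$max_bound_days, cfg$death_day_bound)
  }

  cfg0 <- simulation_config(seed = 1, n_ai_failure = 0L,
                            ai_artifact_counts = c(superovulation = 0L,
                                                   adjacent_ai = 0L,
                                                   low_fertility = 0L))
  rec0 <- simulate_ai_records(cfg0)
  expect_identical(sum(rec0$outcome == "failure"), 0L)
})

test_that("sperm and birth fractions match their model moments across seeds", {
  m <- 0.68; lam <- 0.86
  k_tot <- 0; n_tot <- 0; mdel <- 0; births <- 0
  set.seed(1)
  for (s in 1:200) {
    cfg <- simulation_config(seed = s)
    tc <- simulate_transmission_counts(cfg)
    sv <- as_count_vector(tc$sperm)
    k_tot <- k_tot + sv[["M.del"]] + sv[["F.del"]]
    n_tot <- n_tot + sum(sv)
    bv <- as_count_vector(tc$birth)
    mdel <- mdel + bv[["M.del"]]
    births <- births + sum(bv)
  }
  # mean sperm carrier fraction within 3 SE of m/2
  expect_lt(abs(k_tot / n_tot - m / 2), 3 * sqrt((m / 2) * (1 - m / 2) / n_tot))
  # male-carrier birth fraction within 3 SE of its expectation
  p_mdel <- (m / 2) * (1 - lam) / 2
  p_mdel <- p_mdel / ((1 - m / 2) + (m / 2) / 2 + p_mdel)
  expect_lt(abs(mdel / births - p_mdel), 3 * sqrt(p_mdel * (1 - p_mdel) / births))
})

test_that("mosaicism and lethality are recoverable from generated data", {
  m_err <- c(); l_hat <- c()
  set.seed(101)
  for (s in 1:50) {
    cfg <- simulation_config(seed = s, n_progeny_birth = 760L)
    tc <- simulate_transmission_counts(cfg)
    sv <- as_count_vector(tc$sperm)
    est <- mosaicism_from_sperm(sv[["M.del"]] + sv[["F.del"]], sum(sv))
    m_err <- c(m_err, abs(est$mosaicism - cfg$mosaicism))
    l_hat <- c(l_hat, estimate_male_lethality(tc$birth))
  }
  n <- sum(simulation_config(1)$n_sperm_scored)
  binom_se <- 2 * sqrt((0.34) * (1 - 0.34) / n)
  expect_lte(stats::median(m_err), binom_se)
  expect_lt(abs(mean(l_hat) - 0.86), 0.1)
  expect_lte(stats::median(abs(l_hat - 0.86)), 0.1)
})
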