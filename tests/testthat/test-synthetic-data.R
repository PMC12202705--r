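# Generators: seeded determinism, truth bookkeeping, and agreement with
# the distributions they claim to draw from.

test_that("cohort generator is a pure function of its spec", {
  spec <- cohort_spec(50, half_time_weeks = 10, lag_weeks = 2,
                      followup_weeks = 40, seed = 42)
  a <- simulate_incidence_cohort(spec)
  b <- simulate_incidence_cohort(spec)
  expect_identical(a, b)
  c2 <- simulate_incidence_cohort(cohort_spec(50, 10, 2, 40, seed = 43))
  expect_false(identical(a$table$time_weeks, c2$table$time_weeks))
  # simulating must not disturb the caller's RNG stream
  set.seed(7); x1 <- runif(1)
  set.seed(7); invisible(simulate_incidence_cohort(spec)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("cohort event times follow lag + exponential with censoring", {
  # follow-up equal to the lag leaves no observation window
  none <- simulate_incidence_cohort(
    cohort_spec(30, half_time_weeks = 5, lag_weeks = 10,
                followup_weeks = 10, seed = 1)
  )
  expect_identical(sum(none$table$event), 0L)
  expect_true(all(none$table$time_weeks == 10))

  # event fraction matches the closed-form exponential CDF at
  # followup - lag: 1 - 2^(-56/33)
  sim <- simulate_incidence_cohort(
    cohort_spec(200, half_time_weeks = 33, lag_weeks = 4,
                followup_weeks = 60, seed = 1)
  )
  p <- 1 - 2^(-(60 - 4) / 33)
  expect_lt(abs(mean(sim$table$event) - p),
            3 * sqrt(p * (1 - p) / 200))
  # censored subjects sit exactly at follow-up; truth holds latent times
  cens <- sim$table$event == 0
  expect_true(all(sim$table$time_weeks[cens] == 60))
  expect_identical(sim$table$time_weeks[!cens],
                   sim$truth$latent_times[!cens])

  # definition of the half-time: empirical survival at lag + t1/2 is 1/2
  big <- simulate_incidence_cohort(
    cohort_spec(20000, half_time_weeks = 10, lag_weeks = 0,
                followup_weeks = 200, seed = 2)
  )
  expect_lt(abs(mean(big$truth$latent_times > 10) - 0.5), 0.02)
})

test_that("cohort spec validates its parameters", {
  expect_error(cohort_spec(10, half_time_weeks = 0, followup_weeks = 10),
               "half_time_weeks")
  expect_error(cohort_spec(10, 5, lag_weeks = 20, followup_weeks = 10),
               "followup")
  expect_error(cohort_spec(0, 5, followup_weeks = 10), "n_subjects")
})

test_that("loxP library honours the 2:1 site asymmetry and its truth", {
  cfg <- toy_loxp_config()
  # rho 0: only unrecombined junctions, equal numbers of 5' and 3' reads
  lib0 <- simulate_loxp_library(loxp_library_spec(0, 60, seed = 3), cfg)
  expect_identical(unname(lib0$class_counts["recombined"]), 0L)
  expect_identical(lib0$class_counts[["unrecombined_5"]],
                   lib0$class_counts[["unrecombined_3"]])
  expect_identical(length(lib0$reads), 120L)  # two templates per cell
  # rho 1: only recombined junctions, one template per cell
  lib1 <- simulate_loxp_library(loxp_library_spec(1, 60, seed = 3), cfg)
  expect_identical(unname(lib1$class_counts["unrecombined_5"]), 0L)
  expect_identical(unname(lib1$class_counts["unrecombined_3"]), 0L)
  expect_identical(length(lib1$reads), 60L)
  # truth bookkeeping matches the emitted reads
  lib <- simulate_loxp_library(loxp_library_spec(0.36, 200, seed = 7), cfg)
  expect_identical(as.vector(table(lib$truth$class)[names(lib$class_counts)]),
                   unname(lib$class_counts))
  expect_identical(lib$truth$read_id, names(lib$reads))
  # determinism
  expect_identical(
    lib$reads,
    simulate_loxp_library(loxp_library_spec(0.36, 200, seed = 7), cfg)$reads
  )
})

test_that("loxP library rejects reads too short for the junction", {
  short_flanks <- loxp_config(
    flank_5prime_up = "GATTACAGA",
    flank_5prime_down = "CCGGTTAAC",
    flank_3prime_up = "TTGACCATT",
    flank_3prime_down = "AGGCATTAG"
  )
  # read cannot fit core + min_flank context
  expect_error(
    simulate_loxp_library(
      loxp_library_spec(0.5, 10, read_length = 41, seed = 1),
      toy_loxp_config(min_flank = 4L)
    ),
    "too short"
  )
  # read longer than the junction template the flanks can support
  expect_error(
    simulate_loxp_library(
      loxp_library_spec(0.5, 10, read_length = 60, seed = 1),
      short_flanks
    ),
    "flanks of at least"
  )
  expect_error(loxp_library_spec(0.5, 10, read_length = 39), "read_length")
})

test_that("count generator reproduces the stated NB noise model", {
  # moment check: per-gene variance tracks mu + cv^2 mu^2
  sim <- simulate_count_matrix(counts_spec(
    n_genes = 500, n_cells = 2000, biological_cv = 0.55, seed = 3
  ))
  x <- as.matrix(sim$counts)
  expect_true(all(x >= 0) && all(x == round(x)))
  m <- rowMeans(x)
  v <- apply(x, 1, var)
  keep <- m > 1
  # pooled regression slope of (v - m) on m^2 estimates cv^2 = 0.3025
  c2_hat <- sum((v[keep] - m[keep]) * m[keep]^2) / sum(m[keep]^4)
  expect_lt(abs(c2_hat - 0.3025), 0.06)
  # and the moment estimator convenience agrees
  expect_lt(abs(estimate_cv(x) - 0.55), 0.08)

  # near-Poisson limit: variance approximately equals the mean
  sim0 <- simulate_count_matrix(counts_spec(
    n_genes = 200, n_cells = 1000, biological_cv = 1e-6, seed = 4
  ))
  x0 <- as.matrix(sim0$counts)
  m0 <- rowMeans(x0); v0 <- apply(x0, 1, var)
  expect_lt(abs(median(v0[m0 > 1] / m0[m0 > 1]) - 1), 0.1)
})

test_that("a log2fc of zero plants no signal", {
  sim <- planted_counts_sim(log2fc = 0, seed = 9)
  x <- as.matrix(sim$counts)
  pl <- sim$truth$cell_type == "planted"
  sig <- sim$signatures$sig_planted
  m_pl <- rowMeans(x[sig, pl])
  m_bg <- rowMeans(x[sig, !pl])
  # gene-wise means agree across types within sampling error
  pooled_se <- sqrt(apply(x[sig, pl], 1, var) / sum(pl) +
                      apply(x[sig, !pl], 1, var) / sum(!pl))
  expect_gt(mean(abs(m_pl - m_bg) < 3 * pooled_se), 0.95)
})

test_that("count generator seeds and truth are reproducible", {
  spec <- counts_spec(n_genes = 50, n_cells = 80, biological_cv = 0.55,
                      seed = 11)
  a <- simulate_count_matrix(spec)
  b <- simulate_count_matrix(spec)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_false(identical(
    as.matrix(a$counts),
    as.matrix(simulate_count_matrix(
      counts_spec(n_genes = 50, n_cells = 80, biological_cv = 0.55,
                  seed = 12)
    )$counts)
  ))
  # per-cell depth in truth matches the spec's constant default
  expect_true(all(a$truth$depth == 2000))
  expect_error(counts_spec(10, 10, biological_cv = 0), "biological_cv")
})
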