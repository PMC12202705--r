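# Junction classification and purity estimation.

test_that("config validation catches indistinguishable alleles", {
  expect_error(loxp_config("AAA", "CCC", "GGG", "TTT", core = "ACGT"),
               "34-base")
  expect_error(
    loxp_config(flank_5prime_up = "GATTACA", flank_5prime_down = "CCGGTTA",
                flank_3prime_up = "TTTTACA",  # same last 3 bases as A
                flank_3prime_down = "AGGCATT"),
    "identical in their last"
  )
  expect_error(
    loxp_config(flank_5prime_up = "GATTACA", flank_5prime_down = "CCGGTTA",
                flank_3prime_up = "TTGACCA",
                flank_3prime_down = "CCGTTAA"),  # same first 3 bases as B
    "identical in their first"
  )
})

test_that("definitional junction reads land in their classes", {
  cfg <- toy_loxp_config()
  reads <- c(
    u5  = junction_read(cfg, cfg$flank_5prime_up, cfg$flank_5prime_down),
    u3  = junction_read(cfg, cfg$flank_3prime_up, cfg$flank_3prime_down),
    rec = junction_read(cfg, cfg$flank_5prime_up, cfg$flank_3prime_down),
    # C upstream with B downstream is no valid junction
    odd = junction_read(cfg, cfg$flank_3prime_up, cfg$flank_5prime_down),
    # only 2 flank bases on the upstream side: unassignable at k = 3
    short = paste0("TA", cfg$core,
                   substring(cfg$flank_3prime_down, 1, 10)),
    none = strrep("ACGT", 30)
  )
  cc <- classify_reads(reads, cfg)
  expect_identical(cc$u5, 1L)
  expect_identical(cc$u3, 1L)
  expect_identical(cc$rec, 1L)
  expect_identical(cc$ambiguous, 2L)
  expect_identical(cc$total_core_hits, cc$u5 + cc$u3 + cc$rec + cc$ambiguous)
})

test_that("classification is strand- and order-invariant", {
  cfg <- toy_loxp_config()
  lib <- simulate_loxp_library(loxp_library_spec(0.4, 80, seed = 31), cfg)
  cc <- classify_reads(lib$reads, cfg)
  rc <- classify_reads(
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(lib$reads))), cfg)
  expect_identical(unclass(cc)[c("u5", "u3", "rec", "ambiguous")],
                   unclass(rc)[c("u5", "u3", "rec", "ambiguous")])
  sh <- classify_reads(rev(lib$reads), cfg)
  expect_identical(cc$rec, sh$rec)
  expect_identical(cc$u5, sh$u5)
})

test_that("error-free libraries round-trip exactly against truth", {
  cfg <- toy_loxp_config()
  for (rho in c(0, 0.19, 0.36, 0.55, 1)) {
    lib <- simulate_loxp_library(
      loxp_library_spec(rho, 100, per_base_error = 0, seed = 7), cfg
    )
    cc <- classify_reads(lib$reads, cfg)
    expect_identical(cc$u5, lib$class_counts[["unrecombined_5"]])
    expect_identical(cc$u3, lib$class_counts[["unrecombined_3"]])
    expect_identical(cc$rec, lib$class_counts[["recombined"]])
    expect_identical(cc$ambiguous, 0L)
  }
})

test_that("substitution errors degrade gracefully", {
  cfg <- toy_loxp_config()
  lib <- simulate_loxp_library(
    loxp_library_spec(0.4, 150, per_base_error = 0.01, seed = 13), cfg
  )
  cc <- classify_reads(lib$reads, cfg)
  truth <- lib$class_counts
  informative <- cc$u5 + cc$u3 + cc$rec
  # an error in the core kills the exact match; most reads still classify
  expect_gt(informative / sum(truth), 0.5)
  # misassignment between informative classes requires a flank to mutate
  # into another flank's key: should not happen at this error rate
  expect_lte(cc$rec, truth[["recombined"]])
  expect_lte(cc$u5, truth[["unrecombined_5"]])
  expect_lte(cc$u3, truth[["unrecombined_3"]])
})

test_that("classify_reads reads FASTQ and FASTA from disk", {
  cfg <- toy_loxp_config()
  lib <- simulate_loxp_library(loxp_library_spec(0.5, 40, seed = 3), cfg)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(lib$reads, fq)
  expect_identical(unclass(classify_reads(fq, cfg)),
                   unclass(classify_reads(lib$reads, cfg)))
  fa <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(lib$reads), "\n", lib$reads), fa)
  expect_identical(unclass(classify_reads(fa, cfg)),
                   unclass(classify_reads(lib$reads, cfg)))
})

test_that("purity follows R / (R + U/2)", {
  expect_equal(estimate_purity(loxp_class_counts(60, 64, 0),
                               bootstrap_reps = 0)$rho, 0)
  est <- estimate_purity(loxp_class_counts(u5 = 45, u3 = 55, rec = 10),
                         bootstrap_reps = 0)
  expect_equal(est$rho, 10 / 60)
  expect_identical(est$n_informative, 110L)
  expect_error(estimate_purity(loxp_class_counts(0, 0, 0, ambiguous = 5)),
               "undefined")
  # monotone in R with U fixed; always within [0, 1]
  rhos <- vapply(0:50, function(r) {
    estimate_purity(loxp_class_counts(40, 40, r), bootstrap_reps = 0)$rho
  }, numeric(1))
  expect_true(all(diff(rhos) > 0))
  expect_true(all(rhos >= 0 & rhos <= 1))
})

test_that("bootstrap CI brackets the estimate and is seed-reproducible", {
  cc <- loxp_class_counts(u5 = 50, u3 = 60, rec = 40)
  a <- estimate_purity(cc, bootstrap_reps = 500, seed = 5)
  b <- estimate_purity(cc, bootstrap_reps = 500, seed = 5)
  expect_identical(a, b)
  expect_true(a$ci_low <= a$rho && a$rho <= a$ci_high)
  expect_true(a$ci_low >= 0 && a$ci_high <= 1)
})

test_that("the estimator is consistent and its CI roughly calibrated", {
  cfg <- toy_loxp_config()
  err_at <- function(n_cells, seeds) {
    mean(vapply(seeds, function(s) {
      lib <- simulate_loxp_library(loxp_library_spec(0.3, n_cells,
                                                     seed = s), cfg)
      cc <- classify_reads(lib$reads, cfg)
      abs(estimate_purity(cc, bootstrap_reps = 0)$rho - 0.3)
    }, numeric(1)))
  }
  expect_lt(err_at(1600, 1:5), err_at(50, 1:5))

  # CI coverage of the true fraction at the study-like regime of
  # ~150 informative reads
  hits <- vapply(1:100, function(s) {
    lib <- simulate_loxp_library(loxp_library_spec(0.36, 90, seed = s),
                                 cfg)
    est <- estimate_purity(classify_reads(lib$reads, cfg),
                           bootstrap_reps = 400, seed = s)
    est$ci_low <= 0.36 && 0.36 <= est$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.85)
})
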