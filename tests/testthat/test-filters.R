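cfg <- filter_config()

test_that("quality thresholds are inclusive at the boundary", {
  calls <- random_calls(2, seed = 1)
  calls$dp <- c(9L, 10L); calls$gq <- c(99L, 30L)
  out <- qc_filter(calls, cfg)
  expect_equal(nrow(out), 1L)
  expect_identical(out$dp, 10L)
})

test_that("rarity filter keeps the 0.005 boundary and treats absence as rare", {
  calls <- random_calls(4, seed = 2)
  calls$maf_exac <- c(0.004, 0.01, NA, 0.005)
  calls$maf_csvs <- c(0.001, NA, NA, 0.005)
  out <- rarity_filter(calls, cfg)
  expect_equal(variant_id(out), variant_id(calls[c(1, 3, 4), ]))
})

test_that("synonymous calls are excluded, missense retained", {
  calls <- random_calls(2, seed = 3)
  calls$consequence <- c("synonymous", "missense")
  out <- consequence_filter(calls, cfg)
  expect_identical(out$consequence, "missense")
  expect_equal(nrow(consequence_filter(calls[0, ], cfg)), 0L)
})

test_that("per-call filters match an independent predicate scan", {
  for (seed in c(11, 12, 13)) {
    calls <- random_calls(100, seed = seed)
    mine <- rarity_filter(consequence_filter(qc_filter(calls, cfg), cfg), cfg)
    oracle <- oracle_filter_scan(calls, cfg)
    expect_equal(variant_id(mine), variant_id(oracle))
    expect_equal(mine$sample_id, oracle$sample_id)
  }
})

test_that("control subtraction equals a brute-force set difference and is zygosity-blind", {
  set.seed(21)
  for (rep in 1:5) {
    calls <- random_calls(80, samples = sprintf("S%02d", 1:8))
    chrt <- cohort(calls, cases = sprintf("S%02d", 1:6),
                   controls = sprintf("S%02d", 7:8))
    out <- control_subtract(chrt)
    ctrl_ids <- unique(variant_id(calls[calls$sample_id %in% chrt$controls, ]))
    case_calls <- calls[calls$sample_id %in% chrt$cases, ]
    expected <- case_calls[!variant_id(case_calls) %in% ctrl_ids, ]
    expect_equal(variant_id(out), variant_id(expected))
    expect_false(any(variant_id(out) %in% ctrl_ids))
  }
  # a heterozygous control observation removes a homozygous case call
  calls <- random_calls(1, samples = "S01", seed = 5)
  calls$zygosity <- "homozygous"
  dup <- calls; dup$sample_id <- "S07"; dup$zygosity <- "heterozygous"
  chrt <- cohort(rbind(calls, dup), cases = "S01", controls = "S07")
  expect_equal(nrow(control_subtract(chrt)), 0L)
  # no controls: identity on case calls
  chrt0 <- cohort(calls, cases = "S01")
  expect_equal(nrow(control_subtract(chrt0)), 1L)
})

test_that("prioritization excludes on any failing predictor (disjunction)", {
  calls <- random_calls(4, seed = 4)
  calls$cadd <- c(25, 19.9, 25, NA)
  calls$sift <- c("tolerated", "deleterious", "deleterious", NA)
  calls$polyphen <- c("probably_damaging", "probably_damaging",
                      "possibly_damaging", NA)
  out <- prioritize_damaging(calls, cfg)
  # row 1: the SIFT-tolerated-but-otherwise-damaging pattern is excluded;
  # row 2 fails CADD; row 3 retained (possibly_damaging is not benign);
  # row 4 retained under the default missing-prediction policy
  expect_equal(variant_id(out), variant_id(calls[c(3, 4), ]))
  strict <- filter_config(missing_prediction_policy = "fail")
  expect_equal(variant_id(prioritize_damaging(calls, strict)),
               variant_id(calls[3, ]))
})

test_that("qc/consequence/rarity commute, are idempotent and monotone", {
  filters <- list(qc = qc_filter, cons = consequence_filter,
                  rar = rarity_filter)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  set.seed(31)
  for (rep in 1:10) {
    calls <- random_calls(100)
    results <- lapply(perms, function(p) {
      out <- calls
      for (i in p) out <- filters[[i]](out, cfg)
      sort(paste(out$sample_id, variant_id(out)))
    })
    for (r in results[-1]) expect_identical(r, results[[1]])
    for (f in filters) {
      once <- f(calls, cfg)
      expect_equal(f(once, cfg), once)
    }
    # monotonicity: loosening every threshold never shrinks the survivor set
    loose <- filter_config(dp_min = 5, gq_min = 10, maf_max = 0.05,
                           cadd_min = 10)
    strict_out <- rarity_filter(consequence_filter(qc_filter(calls, cfg), cfg), cfg)
    loose_out <- rarity_filter(consequence_filter(qc_filter(calls, loose), loose), loose)
    expect_true(all(variant_id(strict_out) %in% variant_id(loose_out)))
  }
})

test_that("cascade recovers planted ground truth exactly and reports stages", {
  sim <- simulate_cohort(cohort_sim_config(seed = 99))
  casc <- run_cascade(sim$cohort, cfg, prioritize = TRUE)
  expect_identical(call_keys(casc$survivors),
                   sim$truth$surviving_variant_keys)
  expect_identical(casc$report$stage[1], "input_case_calls")
  expect_true(all(diff(casc$report$n_calls) <= 0))
})

test_that("an all-control cohort yields no survivors and zero counts", {
  calls <- random_calls(20, samples = c("C1", "C2"), seed = 8)
  chrt <- cohort(calls, cases = character(), controls = c("C1", "C2"))
  casc <- run_cascade(chrt, cfg)
  expect_equal(nrow(casc$survivors), 0L)
  expect_true(all(casc$report$n_calls == 0L))
})
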