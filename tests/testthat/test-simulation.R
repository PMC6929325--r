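test_that("null-pair generator: marginals, reproducibility, validation", {
    sim <- simulate_null_pairs(2000, 100, 0.3, seed = 61)
    expect_equal(dim(sim$y1), c(2000L, 100L))
    # empirical occurrence frequency within 3 binomial SEs of p
    n_draws <- length(sim$y1) + length(sim$y2)
    se <- sqrt(0.3 * 0.7 / n_draws)
    expect_lt(abs(mean(c(sim$y1, sim$y2)) - 0.3), 3 * se)

    # byte-identical reproduction under the same seed
    sim2 <- simulate_null_pairs(2000, 100, 0.3, seed = 61)
    expect_identical(sim$y1, sim2$y1)
    expect_identical(sim$y2, sim2$y2)

    expect_error(simulate_null_pairs(10, 50, 0), "strictly inside")
    expect_error(simulate_null_pairs(10, 50, 1), "strictly inside")
})

test_that("mixture generator: truth labels and dependence limits", {
    # pi0 = 1: everything is null
    mix <- simulate_mixture(50, 30, 0.5, pi0 = 1, seed = 62)
    expect_false(any(mix$associated))

    # pi0 = 0.75 with n = 2000 gives 500 associated companions
    mix <- simulate_mixture(2000, 20, 0.5, pi0 = 0.75, seed = 63)
    expect_equal(sum(mix$associated), 500L)

    # rho = 1: associated companions are identical to the query
    mix <- simulate_mixture(20, 40, 0.5, pi0 = 0.5, rho = 1, seed = 64)
    for (k in which(mix$associated))
        expect_identical(mix$companions[k, ], mix$query)
    # and their centered statistic is maximal (positive association)
    cs <- centered_jaccard(mix$query, mix$companions[1, ])
    expect_gt(cs$centered, 0)

    # rho preserves the occurrence probability: conditionally on the
    # realized query, the companion mean is rho * mean(query) + (1-rho) p
    mix <- simulate_mixture(400, 200, 0.3, pi0 = 0, rho = 0.5, seed = 65)
    cond_mean <- 0.5 * mean(mix$query) + 0.5 * 0.3
    se <- sqrt(0.25 / length(mix$companions))
    expect_lt(abs(mean(mix$companions) - cond_mean), 5 * se)
})

test_that("null calibration harness returns per-method diagnostics", {
    cal <- run_null_calibration(n_pairs = 300, m = 60, p = 0.5,
                                methods = c("mca", "asymptotic"),
                                seed = 66)
    expect_equal(names(cal$pvalues), c("mca", "asymptotic"))
    expect_equal(nrow(cal$diagnostics), 2L)
    expect_true(all(cal$pvalues$mca > 0 & cal$pvalues$mca <= 1))
    # a calibrated engine on null data should not be wildly non-uniform
    expect_gt(cal$diagnostics$ks_pvalue[cal$diagnostics$method == "mca"],
              1e-4)
})

test_that("fdr study scores exact false discovery proportions", {
    fdr <- run_fdr_study(n = 120, m = 60, p = 0.5, pi0 = c(0.5, 1),
                         replicates = 2, methods = "asymptotic",
                         thresholds = c(0.05, 0.10), seed = 67)
    expect_equal(nrow(fdr), 2 * 2 * 2)
    expect_true(all(fdr$fdp >= 0 & fdr$fdp <= 1))
    # pi0 = 1: no true positives, so every discovery is false
    null_rows <- fdr$pi0 == 1
    expect_true(all(fdr$fdp[null_rows] %in%
                        c(0, 1)[1 + (fdr$discoveries[null_rows] > 0)]))
    # reproducible under the master seed
    fdr2 <- run_fdr_study(n = 120, m = 60, p = 0.5, pi0 = c(0.5, 1),
                          replicates = 2, methods = "asymptotic",
                          thresholds = c(0.05, 0.10), seed = 67)
    expect_equal(fdr, fdr2)
})

test_that("timing harness records refusals and validates repeats", {
    old <- options(jaccardtest.exact_cap = 30)
    on.exit(options(old))
    tm <- run_timing_comparison(m_grid = c(20, 40),
                                methods = c("exact", "asymptotic"),
                                repeats = 1, seed = 68)
    expect_equal(nrow(tm), 4L)
    # exact refused above the cap is recorded as not run
    row <- tm[tm$m == 40 & tm$method == "exact", ]
    expect_false(row$ran)
    expect_true(is.na(row$seconds))
    expect_true(all(tm$ran[tm$method == "asymptotic"]))

    expect_error(run_timing_comparison(20, repeats = 0),
                 "positive integer")
})
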