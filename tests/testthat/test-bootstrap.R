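test_that("bootstrap null statistics are valid and deterministic", {
    # constant vectors: every resample is the same pair, statistic 0
    bn <- bootstrap_null(rep(1, 8), rep(1, 8), B = 50, seed = 1)
    expect_equal(bn$stats, rep(0, 50))

    # determinism under a fixed seed
    y1 <- c(1, 0, 1, 1, 0, 0, 1, 0)
    y2 <- c(0, 1, 1, 0, 1, 0, 1, 1)
    expect_identical(bootstrap_null(y1, y2, B = 200, seed = 9)$stats,
                     bootstrap_null(y1, y2, B = 200, seed = 9)$stats)

    # all statistics in [-1, 1], length B
    bn <- bootstrap_null(y1, y2, B = 500, seed = 2)
    expect_length(bn$stats, 500)
    expect_true(all(abs(bn$stats) <= 1))

    # the resampled pair's counts are multinomial at the observed plug-in
    # cell probabilities, so the empirical mean of the null statistics
    # must match the exact enumerated expectation of the re-centered
    # statistic under that measure (which is near, but not exactly, zero:
    # re-estimating the expectation on each resample leaves an O(1/m)
    # bias -- the very bias the exact test's per-state re-centering
    # removes)
    set.seed(3)
    m <- 100
    y1 <- rbinom(m, 1, 0.5)
    y2 <- rbinom(m, 1, 0.5)
    bn <- bootstrap_null(y1, y2, B = 1e5)
    p1 <- mean(y1)
    p2 <- mean(y2)
    st <- enumerate_states(m)
    u <- rowSums(st[, 1:3, drop = FALSE])
    pi <- (st[, 1] + st[, 2]) / m
    pj <- (st[, 1] + st[, 3]) / m
    stat <- ifelse(u > 0,
                   st[, 1] / u - ifelse(pi + pj > 0,
                                        pi * pj / (pi + pj - pi * pj), 0),
                   0)
    lw <- lgamma(m + 1) - rowSums(lgamma(st + 1)) +
        st %*% log(pmax(.cell_probs_for_test(p1, p2), 1e-300))
    exact_mean <- sum(exp(lw) * stat)
    se <- stats::sd(bn$stats) / sqrt(bn$B)
    expect_lt(abs(mean(bn$stats) - exact_mean), 3 * se)
    expect_lt(abs(exact_mean), 0.05)  # near-centered at the null
})

test_that("bootstrap p-value: pseudocount rule and degenerate cases", {
    # observed statistic 0 -> every |stat_b| >= 0 -> p-value exactly 1
    r <- jaccard_test_bootstrap(c(1, 1, 0, 0), c(1, 0, 1, 0), B = 100,
                                seed = 4)  # T = 1/3 = E at p-hats 0.5
    expect_equal(r$centered, 0)
    expect_equal(r$pvalue, 1)

    # never zero, and bounded below by 1/(B+1)
    y1 <- c(rep(1, 10), rep(0, 10))
    r <- jaccard_test_bootstrap(y1, y1, B = 200, seed = 5)
    expect_gte(r$pvalue, 1 / 201)
    expect_lte(r$pvalue, 1)
})

test_that("bootstrap p-values converge to the exact p-value", {
    # the resampled pair's contingency counts are multinomial with the
    # observed plug-in cell probabilities, and the resample statistic is
    # re-centered with the resample's own estimates -- exactly the exact
    # test's measure and region.  So the bootstrap hit indicator is
    # Bernoulli(p_exact) and the binomial Monte-Carlo error bound applies
    # (plus the pseudocount offset (1 - p)/(B + 1)).
    set.seed(6)
    B <- 4000
    for (i in 1:15) {
        pr <- random_pair(40)
        pe <- jaccard_test_exact(pr$y1, pr$y2)$pvalue
        pb <- jaccard_test_bootstrap(pr$y1, pr$y2, B = B)$pvalue
        bound <- 3 * sqrt(pe * (1 - pe) / B) + 1 / (B + 1)
        expect_lt(abs(pb - pe), bound + 1e-12)
    }
})

test_that("pooled nulls: degenerate single pair, resolution, validity", {
    y1 <- c(1, 0, 1, 1, 0, 0)
    y2 <- c(0, 1, 1, 0, 1, 1)
    # single pair at the same seed schedule reproduces the per-pair test
    p_single <- pooled_null_pvalues(list(list(y1 = y1, y2 = y2)),
                                    B_per_pair = 300, seed = 7)
    p_direct <- jaccard_test_bootstrap(y1, y2, B = 300, seed = 7)$pvalue
    expect_equal(p_single, p_direct)

    # resolution: the smallest achievable p-value is 1/(n B + 1)
    set.seed(8)
    pairs <- lapply(1:4, function(i) random_pair(12))
    pooled <- pooled_null_pvalues(pairs, B_per_pair = 100, seed = 8)
    expect_true(all(pooled >= 1 / 401))
    expect_length(pooled, 4)

    expect_error(pooled_null_pvalues(list(), 100), "nonempty")
    expect_error(pooled_null_pvalues(
        list(list(y1 = c(1, 0), y2 = c(0, 1)),
             list(y1 = c(1, 0, 1), y2 = c(0, 1, 1))), 100),
        "same length")
})

test_that("pooled and per-pair p-values agree in distribution under the null", {
    set.seed(9)
    n <- 150
    m <- 40
    sim <- simulate_null_pairs(n, m, 0.5)
    pairs <- lapply(seq_len(n), function(k)
        list(y1 = sim$y1[k, ], y2 = sim$y2[k, ]))
    pooled <- pooled_null_pvalues(pairs, B_per_pair = 50, seed = 10)
    per_pair <- vapply(pairs, function(pr)
        jaccard_test_bootstrap(pr$y1, pr$y2, B = 200)$pvalue, 0)
    ks <- suppressWarnings(stats::ks.test(pooled, per_pair))
    expect_gt(ks$p.value, 0.01)
})
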