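test_that("contingency reduces pairs to the four cell counts", {
    q <- contingency(c(1, 1, 0, 0), c(1, 0, 1, 0))
    expect_equal(unname(as.integer(q)), c(1L, 1L, 1L, 1L))
    expect_equal(attr(q, "m"), 4L)

    # identical vectors with k ones
    y <- c(1, 1, 1, 0, 0, 0, 0)
    expect_equal(unname(as.integer(contingency(y, y))), c(3L, 0L, 0L, 4L))

    # degenerate all-zero pair
    expect_equal(unname(as.integer(contingency(rep(0, 5), rep(0, 5)))),
                 c(0L, 0L, 0L, 5L))

    # swap symmetry exchanges n2 and n3
    set.seed(4)
    for (i in 1:10) {
        y1 <- rbinom(12, 1, 0.5)
        y2 <- rbinom(12, 1, 0.5)
        a <- as.integer(contingency(y1, y2))
        b <- as.integer(contingency(y2, y1))
        expect_identical(a, b[c(1, 3, 2, 4)])
        expect_identical(sum(a), 12L)
    }

    expect_error(contingency(c(1, 0), c(1, 0, 1)), "equal length")
    expect_error(contingency(c(1, 2), c(1, 0)), "only 0 and 1")
    expect_error(contingency(numeric(0), numeric(0)), "length m >= 1")
})

test_that("jaccard_coefficient handles both branches of the definition", {
    expect_equal(jaccard_coefficient(c(1, 1, 0), c(1, 0, 1)), 1 / 3)
    # identical nonempty vectors
    expect_equal(jaccard_coefficient(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
    # empty union falls back to the expectation under independence
    expect_equal(jaccard_coefficient(rep(0, 5), rep(0, 5),
                                     p1 = 0.5, p2 = 0.5), 1 / 3)
    expect_error(jaccard_coefficient(rep(0, 4), rep(0, 4)),
                 "empty union")
    expect_error(jaccard_coefficient(rep(0, 4), rep(0, 4), p1 = 0, p2 = 0),
                 "undefined")
})

test_that("expected_jaccard matches the closed form and its properties", {
    expect_equal(expected_jaccard(0.5, 0.5), 1 / 3)
    expect_equal(expected_jaccard(1, 1), 1)
    expect_equal(expected_jaccard(0, 0.7), 0)
    expect_error(expected_jaccard(0, 0), "undefined")

    # symmetry, monotonicity, and the p/(2-p) diagonal
    set.seed(5)
    for (i in 1:20) {
        p1 <- runif(1)
        p2 <- runif(1, min = 0.01)
        expect_equal(expected_jaccard(p1, p2), expected_jaccard(p2, p1))
        expect_gte(expected_jaccard(min(p1 + 0.1, 1), p2),
                   expected_jaccard(p1, p2))
    }
    p <- seq(0.05, 1, by = 0.05)
    expect_equal(vapply(p, function(x) expected_jaccard(x, x), 0),
                 p / (2 - p))
})

test_that("expectation equals the exhaustive weighted mean (brute force)", {
    set.seed(6)
    for (m in c(3, 5, 6)) {
        p1 <- runif(1, 0.15, 0.85)
        p2 <- runif(1, 0.15, 0.85)
        expect_equal(brute_force_expected_T(m, p1, p2),
                     expected_jaccard(p1, p2), tolerance = 1e-12)
    }
})

test_that("Monte-Carlo mean of the coefficient matches the expectation", {
    # 1e5 independent pairs at m=100 via their multinomial reduction
    set.seed(7)
    p1 <- 0.3; p2 <- 0.6
    N <- stats::rmultinom(1e5, 100, .cell_probs_for_test(p1, p2))
    u <- colSums(N[1:3, , drop = FALSE])
    Tv <- ifelse(u > 0, N[1, ] / u, expected_jaccard(p1, p2))
    se <- stats::sd(Tv) / sqrt(length(Tv))
    expect_lt(abs(mean(Tv) - expected_jaccard(p1, p2)), 3 * se)
})

test_that("centered statistic: arithmetic, sign convention, symmetry", {
    cs <- centered_jaccard(c(1, 1, 0, 0), c(1, 1, 0, 0))
    expect_equal(cs$coefficient, 1)
    expect_equal(cs$expectation, 1 / 3)
    expect_equal(cs$centered, 2 / 3)

    # disjoint vectors: negative association
    cs2 <- centered_jaccard(c(1, 1, 0, 0), c(0, 0, 1, 1))
    expect_equal(cs2$coefficient, 0)
    expect_equal(cs2$centered, -1 / 3)

    set.seed(8)
    for (i in 1:15) {
        pr <- random_pair(20)
        a <- centered_jaccard(pr$y1, pr$y2)
        b <- centered_jaccard(pr$y2, pr$y1)
        expect_equal(a$centered, b$centered)
        # consistency of the decomposition, and ranges
        expect_equal(a$centered, a$coefficient - a$expectation,
                     tolerance = 1e-12)
        expect_true(a$coefficient >= 0 && a$coefficient <= 1)
        expect_true(a$centered >= -1 && a$centered <= 1)
    }
    # identical nonconstant vectors: positive association
    y <- c(1, 0, 1, 0, 0)
    expect_gt(centered_jaccard(y, y)$centered, 0)

    expect_error(centered_jaccard(rep(0, 4), rep(0, 4)), "all zero")
})
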