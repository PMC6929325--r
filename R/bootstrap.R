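# Bootstrap empirical null.  Resampling the positions of each vector with
# replacement, separately for the two vectors, destroys any dependence
# between them while preserving the marginal occurrence frequencies; the
# centered statistic of each resampled pair — with the expectation
# re-estimated from the resampled vectors themselves, which removes the
# bias of centering on the observed sample — forms an empirical null
# distribution.

# Draw B resampled pairs and return their centered statistics.  Draw
# order: all B resamples of y1 first, then all of y2 (within a pair,
# vector 1 before vector 2); callers looping over pairs draw pair-major.
.bootstrap_stats <- function(y1, y2, B) {
    m <- length(y1)
    Y1 <- matrix(sample(y1, m * B, replace = TRUE), nrow = B)
    Y2 <- matrix(sample(y2, m * B, replace = TRUE), nrow = B)
    n1 <- rowSums(Y1 * Y2)
    s1 <- rowSums(Y1)
    s2 <- rowSums(Y2)
    u <- s1 + s2 - n1
    p1 <- s1 / m
    p2 <- s2 / m
    den <- p1 + p2 - p1 * p2
    e <- ifelse(den > 0, p1 * p2 / den, 0)
    # empty union: the coefficient falls back to the resample's expected
    # value, so the centered statistic is 0 (also when p-hats are 0/0)
    ifelse(u > 0, n1 / u - e, 0)
}

#' Bootstrap null distribution of the centered coefficient
#'
#' For `b = 1..B`, resample the `m` positions of each vector with
#' replacement (independently for the two vectors) and compute the
#' centered coefficient of the resampled pair, estimating the expectation
#' from the resampled vectors.
#'
#' @inheritParams contingency
#' @param B number of bootstrap iterations; at least `5 * m` to `10 * m`
#'   is recommended.
#' @param seed optional integer seed for reproducibility (sets the RNG
#'   via [set.seed()]).
#' @return A list of class `"bootstrap_null"` with elements `stats`
#'   (numeric vector of length `B`, each in `[-1, 1]`), `B`, `seed`.
#' @examples
#' bn <- bootstrap_null(c(1, 0, 1, 1), c(0, 1, 1, 0), B = 100, seed = 1)
#' range(bn$stats)
#' @export
bootstrap_null <- function(y1, y2, B, seed = NULL) {
    v <- .validate_pair(y1, y2)
    B <- .validate_count(B, "B")
    if (!is.null(seed)) set.seed(seed)
    structure(list(stats = .bootstrap_stats(v$y1, v$y2, B), B = B,
                   seed = seed, pooled = FALSE),
              class = "bootstrap_null")
}

#' Bootstrap p-value of the Jaccard/Tanimoto similarity test
#'
#' Empirical two-sided p-value of the observed centered statistic against
#' the bootstrap null, with the pseudocount rule
#' `(1 + #\{|stat_b| >= |T^c|\}) / (B + 1)` so p-values are never exactly
#' zero (and the test errs slightly conservative).
#'
#' @inheritParams bootstrap_null
#' @param B number of bootstrap iterations, default `5 * m`.
#' @return An object of class `"jaccard_test"`.
#' @examples
#' jaccard_test_bootstrap(rbinom(50, 1, .4), rbinom(50, 1, .4), seed = 7)
#' @export
jaccard_test_bootstrap <- function(y1, y2, B = 5 * length(y1),
                                   seed = NULL) {
    stat <- centered_jaccard(y1, y2)
    B <- .validate_count(B, "B")
    if (!is.null(seed)) set.seed(seed)
    stats <- .bootstrap_stats(.validate_binary(y1, "y1"),
                              .validate_binary(y2, "y2"), B)
    hits <- sum(abs(stats) >= abs(stat$centered) - .TIE_GUARD)
    .new_jaccard_test(stat, (1 + hits) / (B + 1), "bootstrap",
                      extras = list(B = B, seed = seed))
}

#' Pooled-null bootstrap p-values for a collection of pairs
#'
#' When screening many pairs, pooling the null statistics across pairs
#' raises the p-value resolution: each pair's observed statistic is
#' compared against the union of all pairs' bootstrap nulls, so the
#' smallest achievable p-value is `1 / (n_pairs * B_per_pair + 1)`.
#'
#' @param pairs a list of pairs, each a list or two-element list with
#'   components `y1` and `y2` (equal length across all pairs).
#' @param B_per_pair bootstrap iterations contributed by each pair.
#' @param seed optional integer seed; resamples are drawn pair-major in
#'   list order, vector 1 before vector 2 within each pair.
#' @return A numeric vector of p-values, one per pair.
#' @examples
#' pairs <- list(list(y1 = c(1, 0, 1, 0), y2 = c(1, 1, 0, 0)),
#'               list(y1 = c(1, 1, 1, 0), y2 = c(0, 1, 1, 1)))
#' pooled_null_pvalues(pairs, B_per_pair = 200, seed = 1)
#' @export
pooled_null_pvalues <- function(pairs, B_per_pair, seed = NULL) {
    if (!is.list(pairs) || length(pairs) == 0L)
        stop("`pairs` must be a nonempty list of pairs", call. = FALSE)
    B_per_pair <- .validate_count(B_per_pair, "B_per_pair")
    pairs <- lapply(pairs, function(pr) {
        if (is.null(pr$y1) || is.null(pr$y2)) {
            if (length(pr) != 2L)
                stop("each pair must have components `y1` and `y2`",
                     call. = FALSE)
            pr <- list(y1 = pr[[1]], y2 = pr[[2]])
        }
        .validate_pair(pr$y1, pr$y2)
    })
    m <- pairs[[1]]$m
    if (any(vapply(pairs, `[[`, 0L, "m") != m))
        stop("all pairs must share the same length m", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    obs <- vapply(pairs,
                  function(pr) centered_jaccard(pr$y1, pr$y2)$centered,
                  0)
    null_stats <- unlist(lapply(pairs, function(pr)
        .bootstrap_stats(pr$y1, pr$y2, B_per_pair)))
    total <- length(null_stats)
    abs_null <- abs(null_stats)
    vapply(obs, function(tc)
        (1 + sum(abs_null >= abs(tc) - .TIE_GUARD)) / (total + 1), 0)
}
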