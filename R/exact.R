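# Exact test: the null distribution of the contingency counts is
# multinomial, so the p-value is the null mass of the critical region —
# the set of states whose re-centered statistic is at least as extreme as
# the observed one.  With estimated occurrence probabilities the region
# statistic is re-centered per state with that state's own plug-in
# estimates (p~_i = (N1+N2)/m, p~_j = (N1+N3)/m): plugging the observed
# p-hats into every state would bias the expectation toward the observed
# coefficient and make the test conservative.

# Absolute floating guard for the inclusive (>=) region comparison: a
# state within this distance below the threshold is counted in, so exact
# ties are never lost to rounding.
.TIE_GUARD <- 1e-12

#' Enumerate the multinomial state space
#'
#' All quadruples of nonnegative integers `(n1, n2, n3, n4)` summing to
#' `m`, in lexicographic order of `(n1, n2, n3)`.  There are
#' `choose(m + 3, 3)` such states.
#'
#' @param m total count (vector length), a positive integer.
#' @return An integer matrix with columns `n1..n4`, one row per state.
#' @examples
#' nrow(enumerate_states(2)) # choose(5, 3) = 10
#' @export
enumerate_states <- function(m) {
    m <- .validate_count(m, "m")
    blocks <- lapply(0:m, function(n1) {
        r <- m - n1
        n2 <- rep.int(0:r, (r:0) + 1L)
        n3 <- sequence((r:0) + 1L) - 1L
        cbind(n1 = n1, n2 = n2, n3 = n3, n4 = r - n2 - n3)
    })
    st <- do.call(rbind, blocks)
    storage.mode(st) <- "integer"
    st
}

.validate_count <- function(x, arg) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 ||
        x != round(x))
        stop(sprintf("`%s` must be a positive integer", arg), call. = FALSE)
    as.integer(x)
}

# Cap on m for the full enumeration (the state count grows as m^3/6).
.exact_cap <- function(cap = getOption("jaccardtest.exact_cap", 1000L)) {
    as.integer(cap)
}

.check_exact_cap <- function(m) {
    cap <- .exact_cap()
    if (m > cap)
        stop("exact enumeration over choose(m + 3, 3) states is refused ",
             "for m = ", m, " > ", cap, "; use jaccard_test_mca() or ",
             "jaccard_test_bootstrap(), or raise ",
             "options(jaccardtest.exact_cap = ...)", call. = FALSE)
    invisible(m)
}

#' Exact p-value with known occurrence probabilities
#'
#' When `p1` and `p2` are known, the critical region collects the
#' multinomial states whose coefficient deviates from the known
#' expectation `p1 p2 / (p1 + p2 - p1 p2)` by at least the observed
#' absolute centered statistic; the p-value is the region's null mass
#' under `Multinomial(m; p1 p2, p1(1-p2), (1-p1)p2, (1-p1)(1-p2))`.
#'
#' @inheritParams contingency
#' @param p1,p2 known occurrence probabilities, strictly inside `(0, 1)`.
#' @return An object of class `"jaccard_test"`.
#' @examples
#' jaccard_test_exact_known(c(1, 1, 0), c(1, 0, 1), 0.5, 0.5)
#' @export
jaccard_test_exact_known <- function(y1, y2, p1, p2) {
    v <- .validate_pair(y1, y2)
    p1 <- .validate_prob(p1, "p1")
    p2 <- .validate_prob(p2, "p2")
    if (p1 <= 0 || p1 >= 1 || p2 <= 0 || p2 >= 1)
        stop("known-probability exact test requires p1, p2 strictly ",
             "inside (0, 1)", call. = FALSE)
    .check_exact_cap(v$m)
    expectation <- expected_jaccard(p1, p2)
    q <- contingency(v$y1, v$y2)
    coef <- .jaccard_from_quad(q[["n1"]], q[["n2"]], q[["n3"]], p1, p2)
    centered <- coef - expectation
    res <- exact_region_known_core(v$m, .cell_probs(p1, p2), expectation,
                                   abs(centered), .TIE_GUARD)
    stat <- list(coefficient = coef, expectation = expectation,
                 centered = centered, m = v$m)
    # the region sum can exceed 1 by accumulated rounding (~1e-15)
    .new_jaccard_test(stat, min(res$pvalue, 1), "exact",
                      extras = list(known_p = c(p1, p2),
                                    total_mass = res$total))
}

#' Exact p-value of the Jaccard/Tanimoto similarity test
#'
#' Full enumeration of the multinomial state space.  The observed
#' statistic centers the coefficient with plug-in estimates from the
#' data; the critical region re-centers each enumerated state with that
#' state's own plug-in estimates (which removes the bias of estimating
#' the expectation on the sample being tested), while the null mass is
#' measured by the multinomial pmf with cell probabilities built from the
#' observed data's estimates.  Cost grows as `m^3/6` states; above the
#' cap (`options(jaccardtest.exact_cap = 1000)` by default) the function
#' refuses and points to the measure concentration or bootstrap routes.
#'
#' @inheritParams contingency
#' @return An object of class `"jaccard_test"`.
#' @examples
#' jaccard_test_exact(c(1, 1, 1, 0, 0), c(1, 1, 0, 1, 0))
#' @export
jaccard_test_exact <- function(y1, y2) {
    stat <- centered_jaccard(y1, y2)
    .check_exact_cap(stat$m)
    res <- exact_region_core(stat$m, .cell_probs(stat$p_hat1, stat$p_hat2),
                             abs(stat$centered), .TIE_GUARD)
    # the region sum can exceed 1 by accumulated rounding (~1e-15)
    .new_jaccard_test(stat, min(res$pvalue, 1), "exact",
                      extras = list(total_mass = res$total))
}
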