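# Asymptotic test.  Writing q1 = p1 p2 (both present) and
# q2 = p1 + p2 - 2 p1 p2 (exactly one present), the multinomial CLT plus
# the delta method applied to g(x1, x2) = x1/(x1 + x2) at
# (N1, N2 + N3)/m gives sqrt(m) T^c -> N(0, sigma^2).  Carrying the
# algebra through exactly, grad g Sigma grad g' collapses to
# q1 q2 / (q1 + q2)^3; the form in circulation for this statistic carries
# an extra factor (1 - q2), which halves the variance at p1 = p2 = 0.5
# and is what produces the test's well-known anti-conservative behavior
# at mid-range occurrence probabilities (and conservative behavior at
# high ones).  The test defaults to the classical form to reproduce those
# published operating characteristics; `corrected = TRUE` selects the
# exact delta-method variance.

#' Asymptotic variance of the centered coefficient
#'
#' The variance of the limiting normal distribution of
#' `sqrt(m) * T^c` under independence, where `q1` is the probability
#' both vectors have a one at a position and `q2` the probability exactly
#' one does.  The classical form (default) is
#' `q1 q2 (1 - q2) / (q1 + q2)^3`; carrying the delta method through
#' exactly, the cross terms collapse and the variance is
#' `q1 q2 / (q1 + q2)^3` (`corrected = TRUE`) — this is the value the
#' Monte-Carlo variance of `sqrt(m) * T^c` converges to.  The classical
#' form underestimates it by the factor `1 - q2`, which is the source of
#' the asymptotic test's anti-conservative bias at mid-range occurrence
#' probabilities.
#'
#' @param q1,q2 the two probabilities; `q1 + q2` must be positive.
#' @param corrected use the exact delta-method variance instead of the
#'   classical form.
#' @return The variance (a nonnegative number).
#' @examples
#' asymptotic_variance(0.25, 0.5)                  # 0.1481..., classical
#' asymptotic_variance(0.25, 0.5, corrected = TRUE) # 0.2962...
#' @export
asymptotic_variance <- function(q1, q2, corrected = FALSE) {
    q1 <- .validate_prob(q1, "q1")
    q2 <- .validate_prob(q2, "q2")
    if (q1 + q2 <= 0)
        stop("q1 + q2 must be positive", call. = FALSE)
    if (corrected) q1 * q2 / (q1 + q2)^3
    else q1 * q2 * (1 - q2) / (q1 + q2)^3
}

#' Asymptotic p-value of the Jaccard/Tanimoto similarity test
#'
#' Normal approximation of the centered coefficient's null distribution:
#' `z = sqrt(m) * (T - q1/(q1 + q2)) / sigma` with `q1`, `q2` and `sigma`
#' evaluated at the plug-in occurrence probability estimates, and the
#' two-sided p-value `2 * (1 - Phi(|z|))`.
#'
#' With the default (classical) variance this reproduces the method's
#' published operating characteristics: anti-conservative at moderate `m`
#' for mid-range occurrence probabilities, conservative for high ones.
#' It is intended for situations where computing time is the bottleneck;
#' the exact, measure-concentration and bootstrap engines are calibrated.
#'
#' @inheritParams contingency
#' @param corrected passed to [asymptotic_variance()].
#' @return An object of class `"jaccard_test"`.
#' @examples
#' jaccard_test_asymptotic(rbinom(200, 1, 0.5), rbinom(200, 1, 0.5))
#' @export
jaccard_test_asymptotic <- function(y1, y2, corrected = FALSE) {
    stat <- centered_jaccard(y1, y2)
    q1 <- stat$p_hat1 * stat$p_hat2
    q2 <- stat$p_hat1 + stat$p_hat2 - 2 * q1
    sigma2 <- asymptotic_variance(q1, q2, corrected = corrected)
    if (sigma2 <= 0)
        stop("degenerate asymptotic variance (sigma^2 = 0): the plug-in ",
             "probabilities give q1 = 0 or q2 in {0, 1}; use the exact, ",
             "mca or bootstrap test", call. = FALSE)
    z <- sqrt(stat$m) * (stat$coefficient - q1 / (q1 + q2)) / sqrt(sigma2)
    pvalue <- 2 * pnorm(-abs(z))
    .new_jaccard_test(stat, pvalue, "asymptotic",
                      extras = list(z = z, sigma2 = sigma2,
                                    q1 = q1, q2 = q2,
                                    corrected = corrected))
}
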