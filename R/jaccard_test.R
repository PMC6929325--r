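#' Test similarity of two presence-absence vectors
#'
#' Dispatcher over the four p-value engines.  The default engine is the
#' measure concentration algorithm: it matches the exact test to within
#' `epsilon` at a small fraction of the cost, while the asymptotic
#' approximation is only recommended when computing time is the
#' bottleneck (it is anti-conservative at moderate `m` for mid-range
#' occurrence probabilities).
#'
#' @inheritParams contingency
#' @param method p-value engine: `"mca"` (default), `"exact"`,
#'   `"bootstrap"` or `"asymptotic"`.
#' @param epsilon accuracy of the mca engine.
#' @param B bootstrap iterations (default `5 * m`).
#' @param seed optional integer seed (bootstrap engine).
#' @return An object of class `"jaccard_test"`.
#' @examples
#' set.seed(1)
#' y1 <- rbinom(100, 1, 0.5); y2 <- rbinom(100, 1, 0.5)
#' jaccard_test(y1, y2)
#' jaccard_test(y1, y2, method = "bootstrap", seed = 2)
#' @export
jaccard_test <- function(y1, y2,
                         method = c("mca", "exact", "bootstrap",
                                    "asymptotic"),
                         epsilon = 1e-5, B = 5 * length(y1),
                         seed = NULL) {
    method <- match.arg(method)
    switch(method,
           mca = jaccard_test_mca(y1, y2, epsilon = epsilon),
           exact = jaccard_test_exact(y1, y2),
           bootstrap = jaccard_test_bootstrap(y1, y2, B = B, seed = seed),
           asymptotic = jaccard_test_asymptotic(y1, y2))
}
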