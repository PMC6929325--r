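# Measure concentration algorithm (MCA).  The multinomial null
# concentrates around its mode, so a high-probability set I_eps of states
# with total mass >= 1 - eps can be built by starting at the mode and
# repeatedly adding neighbors (states reachable by moving one unit
# between cells) of states already accepted.  Summing the pmf of the
# accepted states that fall in the critical region gives a lower bound
# p^L on the exact p-value with p^L <= p_exact <= p^L + eps.

#' Mode of a four-cell multinomial distribution
#'
#' Hill climbing from the componentwise-rounded mean: move one unit
#' between cells while the pmf increases.  The multinomial pmf is
#' unimodal over this neighbor graph, so the local maximum is global.
#'
#' @param m number of trials, a positive integer.
#' @param cell_probs four cell probabilities summing to 1.
#' @return An integer vector `(n1, n2, n3, n4)` maximizing the pmf.
#' @examples
#' multinomial_mode(4, rep(0.25, 4)) # c(1, 1, 1, 1)
#' @export
multinomial_mode <- function(m, cell_probs) {
    m <- .validate_count(m, "m")
    cell_probs <- .validate_cell_probs(cell_probs)
    multinomial_mode_core(m, cell_probs)
}

.validate_cell_probs <- function(cell_probs) {
    if (!is.numeric(cell_probs) || length(cell_probs) != 4L ||
        anyNA(cell_probs) || any(cell_probs < 0))
        stop("`cell_probs` must be four nonnegative probabilities",
             call. = FALSE)
    if (abs(sum(cell_probs) - 1) > 1e-8)
        stop("`cell_probs` must sum to 1", call. = FALSE)
    as.numeric(cell_probs)
}

#' Build the high-probability concentration set of a multinomial
#'
#' Best-first expansion from the mode: the frontier is a priority queue
#' over the pmf; the highest-probability unaccepted neighbor of the
#' accepted set is added until the accumulated mass reaches `1 - epsilon`
#' (or the whole simplex is consumed, in which case the mass is 1).
#'
#' @inheritParams multinomial_mode
#' @param epsilon target residual mass, in `(0, 1)`.
#' @return A list of class `"concentration_set"` with elements `states`
#'   (integer matrix, one accepted state per row), `mass` (accumulated
#'   probability, `>= 1 - epsilon`), `epsilon`, `mode`, `m`.
#' @examples
#' cs <- build_concentration_set(6, rep(0.25, 4), 1e-12)
#' nrow(cs$states) # 84: the full simplex
#' @export
build_concentration_set <- function(m, cell_probs, epsilon) {
    m <- .validate_count(m, "m")
    cell_probs <- .validate_cell_probs(cell_probs)
    .validate_epsilon(epsilon)
    res <- mca_core(m, cell_probs, t_abs = 0, eps = epsilon,
                    guard = .TIE_GUARD, keep_states = TRUE)
    structure(list(states = res$states, mass = res$mass,
                   epsilon = epsilon, mode = res$mode, m = m),
              class = "concentration_set")
}

#' @export
print.concentration_set <- function(x, ...) {
    cat("Concentration set: ", nrow(x$states), " of ",
        choose(x$m + 3, 3), " states, mass = ", format(x$mass),
        " (epsilon = ", format(x$epsilon), ")\n", sep = "")
    invisible(x)
}

.validate_epsilon <- function(epsilon) {
    if (!is.numeric(epsilon) || length(epsilon) != 1L || is.na(epsilon) ||
        epsilon <= 0 || epsilon >= 1)
        stop("`epsilon` must be a single number in (0, 1)", call. = FALSE)
    invisible(epsilon)
}

#' Measure-concentration p-value of the Jaccard/Tanimoto similarity test
#'
#' Computes the exact test's region sum restricted to the concentration
#' set `I_eps`, giving a lower bound `p_lower` with the sandwich
#' guarantee `p_lower <= p_exact <= p_lower + epsilon`.  The reported
#' p-value is `p_lower`; both bounds are returned in `extras` (note
#' `p_upper = p_lower + epsilon` always, so `p_upper` may exceed 1).
#' The region rule and per-state statistic are shared with
#' [jaccard_test_exact()], so the bounds bracket that function's value.
#'
#' @inheritParams contingency
#' @param epsilon accuracy: the residual mass left outside the summed
#'   set, default `1e-5`.
#' @return An object of class `"jaccard_test"`; `extras` carries
#'   `p_lower`, `p_upper`, `epsilon`, `mass` and `n_states`.
#' @examples
#' jaccard_test_mca(c(1, 1, 1, 0, 0), c(1, 1, 0, 1, 0), epsilon = 1e-6)
#' @export
jaccard_test_mca <- function(y1, y2, epsilon = 1e-5) {
    .validate_epsilon(epsilon)
    stat <- centered_jaccard(y1, y2)
    res <- mca_core(stat$m, .cell_probs(stat$p_hat1, stat$p_hat2),
                    abs(stat$centered), epsilon, .TIE_GUARD,
                    keep_states = FALSE)
    p_lower <- min(res$p_lower, 1)  # guard accumulated rounding
    .new_jaccard_test(stat, p_lower, "mca",
                      extras = list(p_lower = p_lower,
                                    p_upper = p_lower + epsilon,
                                    epsilon = epsilon,
                                    mass = res$mass,
                                    n_states = res$n_states))
}
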