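# Core statistics: contingency reduction, the (refined) Jaccard/Tanimoto
# coefficient, its expectation under independence, and the centered
# statistic.  Vectors are validated once at ingestion; everything
# downstream works on the four contingency counts.

.validate_binary <- function(y, arg = "y") {
    if (is.logical(y)) y <- as.integer(y)
    if (!is.numeric(y))
        stop(sprintf("`%s` must be a numeric or logical 0/1 vector", arg),
             call. = FALSE)
    if (length(y) < 1L)
        stop(sprintf("`%s` must have length m >= 1", arg), call. = FALSE)
    if (anyNA(y) || any(y != 0 & y != 1))
        stop(sprintf("`%s` must contain only 0 and 1 (no NA)", arg),
             call. = FALSE)
    as.integer(y)
}

.validate_pair <- function(y1, y2) {
    y1 <- .validate_binary(y1, "y1")
    y2 <- .validate_binary(y2, "y2")
    if (length(y1) != length(y2))
        stop("`y1` and `y2` must have equal length, got ",
             length(y1), " and ", length(y2), call. = FALSE)
    list(y1 = y1, y2 = y2, m = length(y1))
}

.validate_prob <- function(p, arg = "p") {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
        stop(sprintf("`%s` must be a single probability in [0, 1]", arg),
             call. = FALSE)
    as.numeric(p)
}

#' Contingency counts of a pair of presence-absence vectors
#'
#' Reduces two equal-length binary vectors to the four cell counts
#' `(n1, n2, n3, n4)`: positions where both are present, only the first,
#' only the second, and neither.  Under independence the quadruple is
#' multinomial with `m` trials and cell probabilities
#' `(p1 p2, p1 (1 - p2), (1 - p1) p2, (1 - p1)(1 - p2))`.
#'
#' @param y1,y2 binary (0/1 or logical) vectors of equal length `m >= 1`.
#' @return A named integer vector of class `"contingency_quad"` with
#'   elements `n1`, `n2`, `n3`, `n4` and attribute `m`.
#' @examples
#' contingency(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
contingency <- function(y1, y2) {
    v <- .validate_pair(y1, y2)
    n1 <- sum(v$y1 & v$y2)
    n2 <- sum(v$y1) - n1
    n3 <- sum(v$y2) - n1
    quad <- c(n1 = n1, n2 = n2, n3 = n3, n4 = v$m - n1 - n2 - n3)
    structure(as.integer(quad), names = names(quad), m = v$m,
              class = "contingency_quad")
}

#' @export
print.contingency_quad <- function(x, ...) {
    cat("Contingency counts (m =", attr(x, "m"), "):\n")
    print(unclass(structure(as.integer(x), names = names(x))))
    invisible(x)
}

# Coefficient from counts; probabilities only needed for the empty-union
# fallback branch.
.jaccard_from_quad <- function(n1, n2, n3, p1 = NULL, p2 = NULL) {
    u <- n1 + n2 + n3
    if (u > 0) return(n1 / u)
    if (is.null(p1) || is.null(p2))
        stop("empty union: occurrence probabilities are required for the ",
             "fallback value of the coefficient", call. = FALSE)
    expected_jaccard(p1, p2)
}

#' Jaccard/Tanimoto similarity coefficient
#'
#' The ratio of the intersection to the union of two binary vectors.
#' When the union is empty the conventional ratio is 0/0; the refined
#' definition used throughout this package assigns the expected value
#' under independence, `p1 p2 / (p1 + p2 - p1 p2)`, so that the centered
#' coefficient of an empty-union pair is exactly zero.
#'
#' @inheritParams contingency
#' @param p1,p2 occurrence probabilities, required only when the union is
#'   empty (both vectors all zero).
#' @return The coefficient, a number in `[0, 1]`.
#' @examples
#' jaccard_coefficient(c(1, 1, 0), c(1, 0, 1))
#' jaccard_coefficient(rep(0, 5), rep(0, 5), p1 = 0.5, p2 = 0.5)
#' @export
jaccard_coefficient <- function(y1, y2, p1 = NULL, p2 = NULL) {
    q <- contingency(y1, y2)
    if (!is.null(p1)) p1 <- .validate_prob(p1, "p1")
    if (!is.null(p2)) p2 <- .validate_prob(p2, "p2")
    .jaccard_from_quad(q[["n1"]], q[["n2"]], q[["n3"]], p1, p2)
}

#' Expected Jaccard/Tanimoto coefficient under independence
#'
#' For independent Bernoulli vectors with occurrence probabilities `p1`
#' and `p2`, the expectation of the (refined) coefficient is
#' `p1 p2 / (p1 + p2 - p1 p2)` — the conditional distribution of the
#' intersection count given a nonempty union is binomial with exactly
#' this success probability, and the empty-union fallback equals it by
#' construction.
#'
#' @param p1,p2 occurrence probabilities in `[0, 1]`, not both zero.
#' @return The expectation, a number in `[0, 1]`, symmetric and monotone
#'   nondecreasing in each argument.
#' @examples
#' expected_jaccard(0.5, 0.5) # 1/3
#' @export
expected_jaccard <- function(p1, p2) {
    p1 <- .validate_prob(p1, "p1")
    p2 <- .validate_prob(p2, "p2")
    den <- p1 + p2 - p1 * p2
    if (den <= 0)
        stop("expected coefficient is undefined when p1 = p2 = 0",
             call. = FALSE)
    p1 * p2 / den
}

#' Centered Jaccard/Tanimoto coefficient
#'
#' The observed coefficient minus its expectation under independence,
#' with occurrence probabilities estimated from the data
#' (`p-hat = sum(y)/m`).  Negative values indicate negative association
#' (fewer co-occurrences than expected by chance), positive values
#' positive association.
#'
#' @inheritParams contingency
#' @return A list of class `"jaccard_stat"` with elements `coefficient`,
#'   `expectation`, `centered`, `p_hat1`, `p_hat2`, `m`.
#' @examples
#' centered_jaccard(c(1, 1, 0, 0), c(1, 1, 0, 0))$centered # 2/3
#' @export
centered_jaccard <- function(y1, y2) {
    q <- contingency(y1, y2)
    m <- attr(q, "m")
    p1 <- (q[["n1"]] + q[["n2"]]) / m
    p2 <- (q[["n1"]] + q[["n3"]]) / m
    if (p1 == 0 && p2 == 0)
        stop("both vectors are all zero: occurrence probabilities cannot ",
             "be estimated and the centered coefficient is undefined",
             call. = FALSE)
    expectation <- expected_jaccard(p1, p2)
    coef <- .jaccard_from_quad(q[["n1"]], q[["n2"]], q[["n3"]], p1, p2)
    structure(list(coefficient = coef, expectation = expectation,
                   centered = coef - expectation,
                   p_hat1 = p1, p_hat2 = p2, m = m, quad = q),
              class = "jaccard_stat")
}

#' @export
print.jaccard_stat <- function(x, ...) {
    cat("Jaccard/Tanimoto coefficient: ", format(x$coefficient),
        "\nExpectation under independence: ", format(x$expectation),
        "\nCentered coefficient: ", format(x$centered), "\n", sep = "")
    invisible(x)
}

# Multinomial cell probabilities for a pair of occurrence probabilities.
.cell_probs <- function(p1, p2) {
    c(p1 * p2, p1 * (1 - p2), (1 - p1) * p2, (1 - p1) * (1 - p2))
}

# Shared constructor for test results.
.new_jaccard_test <- function(stat, pvalue, method, extras = list()) {
    structure(list(coefficient = stat$coefficient,
                   expectation = stat$expectation,
                   centered = stat$centered,
                   pvalue = pvalue, method = method, m = stat$m,
                   extras = extras),
              class = "jaccard_test")
}

#' @export
print.jaccard_test <- function(x, ...) {
    cat("Jaccard/Tanimoto similarity test (", x$method, ")\n",
        "  m = ", x$m,
        ", coefficient = ", format(x$coefficient),
        ", expectation = ", format(x$expectation), "\n",
        "  centered statistic = ", format(x$centered),
        ", p-value = ", format.pval(x$pvalue), "\n", sep = "")
    if (identical(x$method, "mca"))
        cat("  bounds: [", format(x$extras$p_lower), ", ",
            format(x$extras$p_upper), "] (epsilon = ",
            format(x$extras$epsilon), ")\n", sep = "")
    if (identical(x$method, "bootstrap"))
        cat("  B = ", x$extras$B, "\n", sep = "")
    invisible(x)
}
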