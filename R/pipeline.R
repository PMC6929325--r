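# All-pairs screening of a presence-absence matrix: tabular input,
# generalist/absent species filtering, method dispatch over every
# unordered pair, and Storey-type q-value FDR control.

#' Read a presence-absence matrix from a delimited text file
#'
#' Expects a header row of unit labels and a first column of species
#' labels; all remaining cells must be 0 or 1.  The separator is taken
#' from the file extension (`.csv` comma, otherwise tab) unless given.
#'
#' @param path file path.
#' @param orientation `"species_rows"` (default) if rows are species and
#'   columns are biogeographic units, `"species_columns"` for the
#'   transpose.
#' @param sep field separator; `NULL` (default) picks by extension.
#' @return An integer matrix, species in rows, units in columns, with
#'   unique dimnames.
#' @export
read_presence_absence <- function(path,
                                  orientation = c("species_rows",
                                                  "species_columns"),
                                  sep = NULL) {
    orientation <- match.arg(orientation)
    if (is.null(sep))
        sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                     stringsAsFactors = FALSE)
    labels <- as.character(df[[1]])
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- labels
    if (orientation == "species_columns") mat <- t(mat)
    if (anyDuplicated(rownames(mat)))
        stop("duplicate species labels: ",
             paste(unique(rownames(mat)[duplicated(rownames(mat))]),
                   collapse = ", "), call. = FALSE)
    if (anyDuplicated(colnames(mat)))
        stop("duplicate unit labels: ",
             paste(unique(colnames(mat)[duplicated(colnames(mat))]),
                   collapse = ", "), call. = FALSE)
    suppressWarnings(storage.mode(mat) <- "numeric")
    bad <- which(is.na(mat) | (mat != 0 & mat != 1), arr.ind = TRUE)
    if (nrow(bad) > 0)
        stop("non-binary entry at species '", rownames(mat)[bad[1, 1]],
             "', unit '", colnames(mat)[bad[1, 2]], "'", call. = FALSE)
    storage.mode(mat) <- "integer"
    mat
}

#' Remove constant species from a presence-absence matrix
#'
#' Species present in every unit (generalists) or absent from all units
#' carry no information for the similarity test: their occurrence
#' probability estimate is degenerate (1 or 0).  They are removed before
#' pairwise screening.
#'
#' @param mat presence-absence matrix, species in rows.
#' @param drop_constant if `FALSE`, the matrix is returned unchanged with
#'   an empty report.
#' @return A list with elements `matrix` (the filtered matrix) and
#'   `removed` (a data frame of removed species and the reason,
#'   `"present everywhere"` or `"absent everywhere"`).
#' @examples
#' m <- rbind(a = c(1, 1, 1), b = c(1, 0, 1), c = c(0, 0, 0))
#' filter_species(m)$removed
#' @export
filter_species <- function(mat, drop_constant = TRUE) {
    .validate_matrix(mat)
    if (!drop_constant)
        return(list(matrix = mat,
                    removed = data.frame(species = character(0),
                                         reason = character(0))))
    rs <- rowSums(mat)
    all_ones <- rs == ncol(mat)
    all_zero <- rs == 0
    removed <- data.frame(
        species = rownames(mat)[all_ones | all_zero],
        reason = ifelse(all_ones[all_ones | all_zero],
                        "present everywhere", "absent everywhere"),
        stringsAsFactors = FALSE)
    kept <- mat[!(all_ones | all_zero), , drop = FALSE]
    if (nrow(kept) == 0)
        warning("all species are constant; the filtered matrix is empty")
    list(matrix = kept, removed = removed)
}

.validate_matrix <- function(mat) {
    if (!is.matrix(mat) || !is.numeric(mat))
        stop("`mat` must be a numeric matrix with 0/1 entries",
             call. = FALSE)
    if (anyNA(mat) || any(mat != 0 & mat != 1))
        stop("`mat` must contain only 0 and 1 (no NA): missing values ",
             "are not supported", call. = FALSE)
    if (is.null(rownames(mat)))
        stop("`mat` must have species labels as rownames", call. = FALSE)
    invisible(mat)
}

#' Test all pairs of species in a presence-absence matrix
#'
#' Runs the selected p-value engine on every unordered pair of rows and
#' attaches Storey-type q-values.  Pairs are ordered lexicographically by
#' label; a pair in which both species are absent everywhere carries no
#' evidence against independence and is flagged with p-value 1.
#'
#' @param mat presence-absence matrix, species in rows, `n >= 2` rows.
#' @param method p-value engine (default `"mca"`).
#' @param epsilon mca accuracy.
#' @param B bootstrap iterations per pair (default `5 * ncol(mat)`).
#' @param seed optional integer seed (bootstrap engine; resamples are
#'   drawn pair-major in output order).
#' @param pool_nulls pool bootstrap null statistics across pairs for
#'   higher p-value resolution (bootstrap engine only).
#' @param pi0_method,fixed_lambda passed to [estimate_qvalues()].
#' @return A data frame of class `"pairwise_results"` with one row per
#'   pair and columns `pair_a`, `pair_b`, `jaccard`, `expectation`,
#'   `centered`, `pvalue`, `qvalue`, `method`; the Storey `pi0` estimate
#'   is attached as attribute `"pi0"`.
#' @examples
#' set.seed(1)
#' m <- matrix(rbinom(5 * 30, 1, 0.5), nrow = 5,
#'             dimnames = list(paste0("sp", 1:5), NULL))
#' pairwise_jaccard_test(m, method = "asymptotic")
#' @export
pairwise_jaccard_test <- function(mat,
                                  method = c("mca", "exact", "bootstrap",
                                             "asymptotic"),
                                  epsilon = 1e-5, B = 5 * ncol(mat),
                                  seed = NULL, pool_nulls = FALSE,
                                  pi0_method = c("smoother", "fixed"),
                                  fixed_lambda = 0.5) {
    method <- match.arg(method)
    .validate_matrix(mat)
    if (nrow(mat) < 2)
        stop("need at least two species to form a pair", call. = FALSE)
    mat <- mat[order(rownames(mat)), , drop = FALSE]
    idx <- combn(nrow(mat), 2)
    labs <- rownames(mat)
    if (!is.null(seed)) set.seed(seed)

    one_pair <- function(a, b) {
        y1 <- mat[a, ]
        y2 <- mat[b, ]
        if (sum(y1) == 0 && sum(y2) == 0)
            return(list(jaccard = NA_real_, expectation = NA_real_,
                        centered = NA_real_, pvalue = 1, note = "degenerate"))
        res <- tryCatch(
            switch(method,
                   mca = jaccard_test_mca(y1, y2, epsilon = epsilon),
                   exact = jaccard_test_exact(y1, y2),
                   bootstrap = jaccard_test_bootstrap(y1, y2, B = B),
                   asymptotic = jaccard_test_asymptotic(y1, y2)),
            error = function(e)
                stop("pair (", labs[a], ", ", labs[b], "): ",
                     conditionMessage(e), call. = FALSE))
        list(jaccard = res$coefficient, expectation = res$expectation,
             centered = res$centered, pvalue = res$pvalue, note = "")
    }

    rows <- lapply(seq_len(ncol(idx)),
                   function(k) one_pair(idx[1, k], idx[2, k]))
    out <- data.frame(
        pair_a = labs[idx[1, ]],
        pair_b = labs[idx[2, ]],
        jaccard = vapply(rows, `[[`, 0, "jaccard"),
        expectation = vapply(rows, `[[`, 0, "expectation"),
        centered = vapply(rows, `[[`, 0, "centered"),
        pvalue = vapply(rows, `[[`, 0, "pvalue"),
        stringsAsFactors = FALSE)

    if (method == "bootstrap" && pool_nulls) {
        pairs <- lapply(seq_len(ncol(idx)), function(k)
            list(y1 = mat[idx[1, k], ], y2 = mat[idx[2, k], ]))
        ok <- !vapply(rows, function(r) identical(r$note, "degenerate"),
                      TRUE)
        out$pvalue[ok] <- pooled_null_pvalues(pairs[ok],
                                              B_per_pair = B)
    }

    qv <- estimate_qvalues(out$pvalue, pi0_method = pi0_method,
                           fixed_lambda = fixed_lambda)
    out$qvalue <- qv$qvalues
    out$method <- method
    out$note <- vapply(rows, `[[`, "", "note")
    attr(out, "pi0") <- qv$pi0
    class(out) <- c("pairwise_results", "data.frame")
    out
}

#' Storey-type q-values and null-proportion estimate
#'
#' Estimates the proportion of true nulls `pi0` from the p-value
#' distribution (counts of p-values above a grid of cutoffs `lambda`,
#' extrapolated to `lambda -> 1` with a cubic smoothing spline) and
#' converts p-values to q-values — the minimum FDR at which each test
#' would be called significant — via the monotone step-up transform
#' `q(p) = min over p' >= p of pi0 * n * p' / rank(p')`.
#'
#' With heavily discrete p-value supports (e.g. the exact test at small
#' `m`) the smoother can misbehave; `pi0_method = "fixed"` uses the
#' single-cutoff estimate at `fixed_lambda` instead.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param pi0_method `"smoother"` (default) or `"fixed"`.
#' @param lambda grid of cutoffs for the smoother.
#' @param fixed_lambda single cutoff for `pi0_method = "fixed"`.
#' @return A list with `qvalues` (same order as the input) and `pi0`
#'   (clipped to `(0, 1]`).
#' @examples
#' p <- runif(1000)
#' estimate_qvalues(p)$pi0 # close to 1
#' @export
estimate_qvalues <- function(pvalues,
                             pi0_method = c("smoother", "fixed"),
                             lambda = seq(0, 0.90, by = 0.05),
                             fixed_lambda = 0.5) {
    pi0_method <- match.arg(pi0_method)
    if (length(pvalues) == 0L)
        stop("`pvalues` must be nonempty", call. = FALSE)
    if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
        stop("`pvalues` must lie in [0, 1]", call. = FALSE)
    n <- length(pvalues)

    if (pi0_method == "fixed") {
        pi0 <- mean(pvalues > fixed_lambda) / (1 - fixed_lambda)
    } else {
        pi0_lambda <- vapply(lambda,
                             function(l) mean(pvalues > l) / (1 - l), 0)
        fit <- smooth.spline(lambda, pi0_lambda, df = 3)
        pi0 <- predict(fit, x = max(lambda))$y
    }
    if (pi0 <= 0) {
        warning("pi0 estimate was nonpositive; clipping to the smallest ",
                "achievable positive value 1/n")
        pi0 <- 1 / n
    }
    pi0 <- min(pi0, 1)

    r <- rank(pvalues, ties.method = "max")
    qv <- pmin(pi0 * n * pvalues / r, 1)
    o <- order(pvalues, decreasing = TRUE)
    qv[o] <- cummin(qv[o])
    list(qvalues = qv, pi0 = pi0)
}

#' Write pairwise screening results to a TSV file
#'
#' @param x a `"pairwise_results"` data frame.
#' @param path output file path.
#' @return `x`, invisibly.
#' @export
write_pairwise_results <- function(x, path) {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(x)
}
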