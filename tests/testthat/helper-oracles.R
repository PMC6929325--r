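# Independent brute-force oracles, deliberately implemented in plain R
# over the vector space (not the multinomial state space the package
# enumerates), so they share no code path with the implementation.

# All 2^m binary vectors of length m, one per row.
all_binary_vectors <- function(m) {
    as.matrix(expand.grid(rep(list(0:1), m)))
}

# Bernoulli product weight of each row of `vecs` at occurrence
# probability p.
bernoulli_weights <- function(vecs, p) {
    apply(vecs, 1, function(v) prod(ifelse(v == 1, p, 1 - p)))
}

# Per-pair centered statistic with the pair's own plug-in estimates
# (0 for an empty union: the coefficient falls back to its expectation).
pair_statistic <- function(v1, v2) {
    m <- length(v1)
    n1 <- sum(v1 * v2)
    u <- sum(v1) + sum(v2) - n1
    if (u == 0) return(0)
    pi <- sum(v1) / m
    pj <- sum(v2) / m
    n1 / u - pi * pj / (pi + pj - pi * pj)
}

# Exact p-value (estimated-probability region) by exhaustive enumeration
# of all 2^m x 2^m weighted vector pairs; weights use the OBSERVED pair's
# plug-in estimates, the region statistic each candidate pair's own.
brute_force_exact_pvalue <- function(y1, y2, guard = 1e-12) {
    m <- length(y1)
    obs <- centered_jaccard(y1, y2)
    vecs <- all_binary_vectors(m)
    w1 <- bernoulli_weights(vecs, obs$p_hat1)
    w2 <- bernoulli_weights(vecs, obs$p_hat2)
    total <- 0
    for (a in seq_len(nrow(vecs))) {
        for (b in seq_len(nrow(vecs))) {
            st <- abs(pair_statistic(vecs[a, ], vecs[b, ]))
            if (st >= abs(obs$centered) - guard)
                total <- total + w1[a] * w2[b]
        }
    }
    total
}

# Known-probability analogue: weights from the known p1, p2 and the
# region statistic centered at the fixed expectation.
brute_force_known_pvalue <- function(y1, y2, p1, p2, guard = 1e-12) {
    m <- length(y1)
    e0 <- expected_jaccard(p1, p2)
    obs <- abs(jaccard_coefficient(y1, y2, p1, p2) - e0)
    vecs <- all_binary_vectors(m)
    w1 <- bernoulli_weights(vecs, p1)
    w2 <- bernoulli_weights(vecs, p2)
    total <- 0
    for (a in seq_len(nrow(vecs))) {
        for (b in seq_len(nrow(vecs))) {
            n1 <- sum(vecs[a, ] * vecs[b, ])
            u <- sum(vecs[a, ]) + sum(vecs[b, ]) - n1
            st <- if (u == 0) 0 else abs(n1 / u - e0)
            if (st >= obs - guard) total <- total + w1[a] * w2[b]
        }
    }
    total
}

# Expectation of the refined coefficient by exhaustive weighted
# enumeration (the empty-union pair contributes the fallback value).
brute_force_expected_T <- function(m, p1, p2) {
    vecs <- all_binary_vectors(m)
    w1 <- bernoulli_weights(vecs, p1)
    w2 <- bernoulli_weights(vecs, p2)
    fallback <- p1 * p2 / (p1 + p2 - p1 * p2)
    total <- 0
    for (a in seq_len(nrow(vecs))) {
        for (b in seq_len(nrow(vecs))) {
            n1 <- sum(vecs[a, ] * vecs[b, ])
            u <- sum(vecs[a, ]) + sum(vecs[b, ]) - n1
            Tv <- if (u == 0) fallback else n1 / u
            total <- total + w1[a] * w2[b] * Tv
        }
    }
    total
}

# Random non-degenerate Bernoulli pair (at least one 1 across the pair).
random_pair <- function(m, p1 = runif(1, 0.2, 0.8),
                        p2 = runif(1, 0.2, 0.8)) {
    repeat {
        y1 <- rbinom(m, 1, p1)
        y2 <- rbinom(m, 1, p2)
        if (sum(y1) + sum(y2) > 0) return(list(y1 = y1, y2 = y2))
    }
}

# Multinomial cell probabilities of the contingency quadruple under
# independence (kept local to the tests).
.cell_probs_for_test <- function(p1, p2) {
    c(p1 * p2, p1 * (1 - p2), (1 - p1) * p2, (1 - p1) * (1 - p2))
}

# Synthetic presence-absence matrix with labelled species rows.
synthetic_matrix <- function(n_species, m_units, p = 0.5,
                             prefix = "sp") {
    mat <- matrix(rbinom(n_species * m_units, 1, p), nrow = n_species,
                  dimnames = list(sprintf("%s%02d", prefix,
                                          seq_len(n_species)),
                                  sprintf("unit%02d", seq_len(m_units))))
    mat
}
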