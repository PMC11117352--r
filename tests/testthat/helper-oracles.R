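# Independent oracles used by unit and acceptance tests.

# Greedy clustering reference: written directly from the rule's definition
# over a precomputed identity matrix, independent of the package's
# alignment machinery.
reference_greedy <- function(ids, lengths, ident, threshold) {
  ord <- ids[order(-lengths, ids)]
  centroids <- character(0)
  assign <- character(0)
  for (id in ord) {
    hit <- NA_character_
    for (c in centroids) {
      if (ident[c, id] >= threshold) { hit <- c; break }
    }
    if (is.na(hit)) {
      centroids <- c(centroids, id)
      assign[id] <- id
    } else {
      assign[id] <- hit
    }
  }
  assign
}

# Two-parameter substitution simulation, independent of the package's
# closed-form sampler: the rate matrix (transitions at rate alpha = kappa*b,
# each transversion at rate b, scaled so alpha + 2b = 1 substitution/site
# per unit distance) is exponentiated numerically by eigendecomposition and
# end states are sampled per site.  Returns observed transition and
# transversion proportions relative to the ancestor.
simulate_k2p_divergence <- function(n_sites, d, kappa) {
  b <- 1 / (kappa + 2)
  a <- kappa * b
  # state order A, G, C, T: transitions A<->G and C<->T
  Q <- matrix(c(-(a + 2 * b), a, b, b,
                a, -(a + 2 * b), b, b,
                b, b, -(a + 2 * b), a,
                b, b, a, -(a + 2 * b)), 4, 4, byrow = TRUE)
  eg <- eigen(Q)
  P <- Re(eg$vectors %*% diag(exp(eg$values * d)) %*% solve(eg$vectors))
  P[P < 0] <- 0
  P <- P / rowSums(P)
  anc <- sample.int(4L, n_sites, replace = TRUE)
  der <- integer(n_sites)
  for (s in 1:4) {
    idx <- which(anc == s)
    if (length(idx) > 0L) {
      der[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[s, ])
    }
  }
  is_ts <- (anc == 1L & der == 2L) | (anc == 2L & der == 1L) |
    (anc == 3L & der == 4L) | (anc == 4L & der == 3L)
  is_tv <- anc != der & !is_ts
  list(P = mean(is_ts), Q = mean(is_tv))
}
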