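# Exhaustive lattice maximizer of the K = 2, M = 1, H = 2 latent class
# log-likelihood, independent of the EM path: a coarse 0.05 sweep over
# (tau, rho) followed by exhaustive refinement at 0.01 and then 0.001 around
# the coarse optimum. Returns both the 0.01-lattice and refined maxima.
oracle_pass <- function(n_p, g11, g12, g21, g22, taus) {
  p1 <- as.matrix(expand.grid(a = g11, b = g12))
  p2 <- as.matrix(expand.grid(a = g21, b = g22))
  patt_probs <- function(p) cbind((1 - p[, 1]) * (1 - p[, 2]),
                                  (1 - p[, 1]) * p[, 2],
                                  p[, 1] * (1 - p[, 2]),
                                  p[, 1] * p[, 2])
  P1 <- patt_probs(p1); P2 <- patt_probs(p2)
  best <- list(ll = -Inf)
  for (tau in taus) {
    ll <- matrix(0, nrow(P1), nrow(P2))
    for (p in 1:4) {
      if (n_p[p] > 0) ll <- ll + n_p[p] * log(outer(tau * P1[, p],
                                                    (1 - tau) * P2[, p], "+"))
    }
    idx <- arrayInd(which.max(ll), dim(ll))
    if (ll[idx] > best$ll) {
      best <- list(ll = ll[idx], tau = tau,
                   c1 = p1[idx[1], ], c2 = p2[idx[2], ])
    }
  }
  best
}

grid_oracle_k2 <- function(y) {
  stopifnot(ncol(y) == 2, nrow(y) <= 8)
  n_p <- tabulate(y[, 1] * 2 + y[, 2] + 1L, 4L)
  win <- function(v, step, half) {
    g <- seq(max(v - half, 0), min(v + half, 1), by = step)
    unique(round(g, 6))
  }
  coarse <- oracle_pass(n_p, seq(0, 1, 0.05), seq(0, 1, 0.05),
                        seq(0, 1, 0.05), seq(0, 1, 0.05), seq(0, 1, 0.05))
  mid <- oracle_pass(n_p,
                     win(coarse$c1[1], 0.01, 0.06), win(coarse$c1[2], 0.01, 0.06),
                     win(coarse$c2[1], 0.01, 0.06), win(coarse$c2[2], 0.01, 0.06),
                     win(coarse$tau, 0.01, 0.06))
  fine <- oracle_pass(n_p,
                      win(mid$c1[1], 0.001, 0.012), win(mid$c1[2], 0.001, 0.012),
                      win(mid$c2[1], 0.001, 0.012), win(mid$c2[2], 0.001, 0.012),
                      win(mid$tau, 0.001, 0.012))
  list(lattice01 = mid$ll, refined = fine$ll)
}
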