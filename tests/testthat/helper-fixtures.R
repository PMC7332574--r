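# shared fixture builders; everything is generated in code under fixed seeds

# random small fitting problem: counts drawn Poisson around a random mixture
rand_problem <- function(seed, S = 4L, I = 6L, N = 2L, scale = 50) {
  set.seed(seed)
  P <- matrix(rgamma(I * N, 2), I, N)
  P <- sweep(P, 2L, colSums(P), "/")
  Q <- matrix(runif(S * N, 0.5, 2) * scale, S, N)
  H <- matrix(rpois(S * I, Q %*% t(P)), S, I)
  list(cohort = lpm_cohort(H), comps = lpm_components(P), Q = Q)
}

# column-matched L1 distance, minimised over component permutations
perm_l1 <- function(P, Ptrue) {
  perms <- function(v) if (length(v) <= 1L) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  min(vapply(perms(seq_len(ncol(P))),
             function(pp) sum(abs(P[, pp] - Ptrue)), numeric(1L)))
}

# central finite-difference Hessian of the per-spectrum extended
# log-likelihood wrt the quantities — the independent oracle for the MVB
fd_hessian <- function(h, comps, q, step = 1e-4) {
  f <- function(qq) extended_log_likelihood(matrix(h, nrow = 1L), comps, qq)
  N <- length(q)
  Hm <- matrix(0, N, N)
  for (a in seq_len(N)) for (b in seq_len(N)) {
    ea <- eb <- numeric(N); ea[a] <- step * max(1, q[a]); eb[b] <- step * max(1, q[b])
    Hm[a, b] <- (f(q + ea + eb) - f(q + ea - eb) - f(q - ea + eb) +
                   f(q - ea - eb)) / (4 * ea[a] * eb[b])
  }
  (Hm + t(Hm)) / 2
}
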