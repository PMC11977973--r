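# Independent oracles: truncated chemical-master-equation solution by
# matrix exponentiation, and a total-variation helper.

cme_birth_death_pmf <- function(birth, death, t, x0 = 0, nmax = 60) {
  states <- 0:nmax
  n <- length(states)
  Q <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    Q[i, i + 1] <- birth                # x -> x + 1
    Q[i + 1, i] <- death * states[i + 1] # x -> x - 1
  }
  diag(Q) <- -rowSums(Q)
  p0 <- numeric(n)
  p0[x0 + 1] <- 1
  as.numeric(p0 %*% as.matrix(Matrix::expm(Matrix::Matrix(Q * t))))
}

tv_distance <- function(samples, pmf, nmax = length(pmf) - 1L) {
  emp <- tabulate(pmin(samples, nmax) + 1L, nbins = nmax + 1L) / length(samples)
  0.5 * sum(abs(emp - pmf))
}

ks_pass <- function(a, b, alpha = 0.01) {
  suppressWarnings(stats::ks.test(a, b)$p.value) > alpha
}
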