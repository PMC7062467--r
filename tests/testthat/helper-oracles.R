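# Independent oracles used by the unit and acceptance suites. These are
# deliberately naive (enumeration / brute force / direct formulas) and must
# stay independent of the package implementations they check.

# exact two-sided Wilcoxon signed-rank p by full enumeration of sign vectors
wilcoxon_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  min(1, mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-12))
}

# Friedman Q from rank sums, with the mid-rank tie correction
friedman_Q_direct <- function(m) {
  n <- nrow(m); k <- ncol(m)
  R <- t(apply(m, 1, rank))
  Rj <- colSums(R)
  Q <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  ties <- sum(apply(m, 1, function(row) {
    tb <- table(row); sum(tb^3 - tb)
  }))
  C <- 1 - ties / (n * k * (k^2 - 1))
  if (C > 0) Q / C else Q
}

# Monte-Carlo null p for the Rayleigh statistic Z = n * rbar^2
rayleigh_mc_p <- function(phases, n_resample = 1e5) {
  n <- length(phases)
  z_obs <- (sum(cos(phases))^2 + sum(sin(phases))^2) / n
  th <- matrix(runif(n_resample * n, 0, 2 * pi), n_resample, n)
  z_null <- (rowSums(cos(th))^2 + rowSums(sin(th))^2) / n
  mean(z_null >= z_obs)
}

# brute-force minimum 10-frame window mean over the first minute
baseline_brute <- function(values, fs, k = 10) {
  first <- values[seq_len(min(length(values), floor(60 * fs)))]
  mins <- Inf
  for (i in seq_len(length(first) - k + 1)) {
    mins <- min(mins, mean(first[i:(i + k - 1)]))
  }
  mins
}

# greedy matching of detected to true event times within a tolerance
match_events <- function(detected_s, true_s, tol_s) {
  used <- rep(FALSE, length(detected_s))
  hits <- 0L; err <- numeric(0)
  for (ev in true_s) {
    d <- abs(detected_s - ev); d[used] <- Inf
    if (length(d) && min(d) <= tol_s) {
      j <- which.min(d); used[j] <- TRUE; hits <- hits + 1L
      err <- c(err, detected_s[j] - ev)
    }
  }
  list(hits = hits, n_true = length(true_s), n_det = length(detected_s),
       onset_err = err)
}
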