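# Independent brute-force oracles used to cross-check the package's
# statistics, written against the definitions rather than the code paths
# they verify.

# Two-sided Fisher p by full hypergeometric enumeration (probability
# method: sum of all table probabilities not exceeding the observed one).
fisher_enum_p <- function(tab) {
  m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  pobs <- stats::dhyper(tab[1, 1], m, n2, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Two-group log-rank chi-square from the observed-minus-expected
# hypergeometric sums at each distinct event time.
logrank_enum_chisq <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  o_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == g1)
    o_e <- o_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_e^2 / v
}

# Efron partial log-likelihood for a single covariate; the maximizer is
# found by one-dimensional optimization (independent of coxph).
efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in unique(time[event == 1])) {
    D <- which(event == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    sR <- sum(exp(beta * x[R]))
    sD <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D]) -
      sum(log(sR - (seq_len(d) - 1) / d * sD))
  }
  ll
}
cox_grid_beta <- function(time, event, x) {
  stats::optimize(function(b) -efron_loglik(b, time, event, x),
                  c(-8, 8), tol = 1e-8)$minimum
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments
# (no ties assumed; the U distribution is then symmetric).
mw_enum_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(length(pooled), nx)
  us <- apply(idx, 2, function(ii) sum(r[ii]) - nx * (nx + 1) / 2)
  mu <- nx * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Disruptive-rule oracle evaluated from literal interval and group
# definitions (independent of the reference-data module).
oracle_disruptive_missense <- function(ref, pos, alt) {
  groups <- c(G = "np", A = "np", V = "np", L = "np", I = "np", P = "np",
              F = "np", M = "np", W = "np",
              S = "pu", T = "pu", C = "pu", Y = "pu", N = "pu", Q = "pu",
              K = "pos", R = "pos", H = "pos", D = "neg", E = "neg")
  in_loop <- (pos >= 163 & pos <= 195) | (pos >= 236 & pos <= 251)
  in_loop & groups[ref] != groups[alt]
}

# Hand product-limit estimate (censoring at an event time after events).
km_hand <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n)
    out[i] <- s
  }
  data.frame(time = ts, surv = out)
}
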