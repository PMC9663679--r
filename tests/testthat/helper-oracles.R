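# Independent oracles used across the suite. Each is deliberately written
# with a different algorithm than the implementation it checks.

# Brute-force tie-corrected AUC: double loop over all case-control pairs.
brute_auc <- function(cases, controls) {
  mean(outer(cases, controls, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Independent Glasgow-Blatchford scorer: scalar, band-list driven.
oracle_gbs <- function(bun, hb, sex, sbp, pulse, mel, syn, hep, card) {
  in_band <- function(x, bands) {
    for (b in bands) if (x >= b[1] && x < b[2]) return(b[3])
    0
  }
  total <- in_band(bun, list(c(6.5, 8, 2), c(8, 10, 3), c(10, 25, 4),
                             c(25, Inf, 6)))
  hb_bands <- if (sex == "male") {
    list(c(120, 130, 1), c(100, 120, 3), c(-Inf, 100, 6))
  } else {
    list(c(100, 120, 1), c(-Inf, 100, 6))
  }
  total <- total + in_band(hb, hb_bands)
  total <- total + in_band(sbp, list(c(100, 110, 1), c(90, 100, 2),
                                     c(-Inf, 90, 3)))
  total + (pulse >= 100) + mel + 2 * syn + 2 * hep + 2 * card
}

# Fisher exact p by direct hypergeometric enumeration over all tables with
# the observed margins.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  as <- max(0, k - n2):min(m, k)
  probs <- stats::dhyper(as, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Logistic regression by hand-rolled iteratively reweighted least squares.
oracle_irls <- function(x, y, tol = 1e-12, maxit = 100) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, X * w), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) break
    beta <- drop(beta_new)
  }
  drop(beta)
}

# Two-sample jackknife variance of the empirical AUC: leave-one-out within
# each sample, jackknife variance per sample, parts summed.
jackknife_auc_var <- function(cases, controls) {
  m <- length(cases)
  n <- length(controls)
  loo_case <- vapply(seq_len(m),
                     function(i) brute_auc(cases[-i], controls), 0)
  loo_ctrl <- vapply(seq_len(n),
                     function(j) brute_auc(cases, controls[-j]), 0)
  (m - 1) / m * sum((loo_case - mean(loo_case))^2) +
    (n - 1) / n * sum((loo_ctrl - mean(loo_ctrl))^2)
}

study_fixture_path <- function() {
  system.file("extdata", "cohort_reconstructed.csv", package = "gbsnga",
              mustWork = TRUE)
}
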