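# Independent oracle implementations used to cross-check the package.
# Deliberately written as plain loops over the definitions, sharing no code
# with the implementation under test.

# brute-force percentile by linear interpolation of the cumulative table on
# the phi scale
oracle_percentile_phi <- function(apertures, retained, pan, x) {
  bounds <- c(0.001, rev(apertures), apertures[1] * 2)
  masses <- c(pan, rev(retained))
  pct <- c(0, cumsum(masses)) / sum(masses) * 100
  phi <- -log2(bounds)
  for (i in seq_len(length(pct) - 1)) {
    if (x >= min(pct[i], pct[i + 1]) && x <= max(pct[i], pct[i + 1])) {
      if (pct[i + 1] == pct[i]) return(2^-((phi[i] + phi[i + 1]) / 2))
      f <- (x - pct[i]) / (pct[i + 1] - pct[i])
      return(2^-(phi[i] + f * (phi[i + 1] - phi[i])))
    }
  }
  stop("x not bracketed")
}

# hand-coded hydraulic formulas, straight from the printed definitions
oracle_hydraulics <- function(U, d, D50, ks, g = 9.8, nu = 1.76e-5,
                              mu = 1.73e-4, rho = 996, rho_s = 273,
                              theta_c = 0.035, y_ref = 0.01) {
  tau <- mu * (U / y_ref)
  V <- sqrt(tau / rho)
  list(Fr = U^2 / (g * d),
       Re = U * d / nu,
       tau = tau,
       V = V,
       w_a = tau * U,
       Re_star = V * (ks / 1000) / nu,
       tau_c = theta_c * g * (D50 / 1000) * (rho_s - rho))
}

# brute-force partial dependence: row-by-row prediction loop
oracle_partial_dependence <- function(forest, predictor, grid) {
  sapply(grid, function(v) {
    tot <- 0
    for (i in seq_len(nrow(forest$x))) {
      row <- forest$x[i, , drop = FALSE]
      row[[predictor]] <- v
      tot <- tot + predict(forest$fit, row, num.threads = 1)$predictions
    }
    tot / nrow(forest$x)
  })
}

# brute-force Gaussian kernel sum (no edge correction)
oracle_gauss_field <- function(cx, cy, px, py, w, sigma) {
  out <- numeric(length(cx))
  for (i in seq_along(cx)) {
    s <- 0
    for (j in seq_along(px)) {
      d2 <- (cx[i] - px[j])^2 + (cy[i] - py[j])^2
      s <- s + w[j] * exp(-d2 / (2 * sigma^2)) / (2 * pi * sigma^2)
    }
    out[i] <- s
  }
  out
}

# direct double-loop coding of the bandwidth MSE criterion
oracle_bw_criterion <- function(x, y, area, sigma) {
  n <- length(x)
  k <- function(d, s) exp(-d^2 / (2 * s^2)) / (2 * pi * s^2)
  pairsum <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
    pairsum <- pairsum + (k(d, sigma * sqrt(2)) - 2 * k(d, sigma))
  }
  (n / area) / (4 * pi * sigma^2) + pairsum / area
}

# random sieve stack generator for property tests
random_stack <- function() {
  sieve_stack(runif(6, 0, 50), pan = runif(1, 0, 20))
}

make_forest_table <- function(n = 60, p = 4, seed = 1, signal = TRUE) {
  set.seed(seed)
  x <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(x) <- paste0("x", seq_len(p))
  x$response <- if (signal) x$x1 + rnorm(n, 0, 0.3) else rnorm(n)
  x
}
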