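# Naive-loop oracle implementations of every evaluation metric, kept
# deliberately independent of the package's vectorized code paths.

oracle_rmse <- function(o, p) {
  s <- 0
  for (i in seq_along(o)) s <- s + (o[i] - p[i])^2
  sqrt(s / length(o))
}

oracle_mae <- function(o, p) {
  s <- 0
  for (i in seq_along(o)) s <- s + abs(o[i] - p[i])
  s / length(o)
}

oracle_nrmse <- function(o, p, mode) {
  denom <- if (mode == "range") max(o) - min(o) else mean(o)
  100 * oracle_rmse(o, p) / denom
}

oracle_pearson <- function(o, p) {
  om <- mean(o); pm <- mean(p)
  num <- 0; do2 <- 0; dp2 <- 0
  for (i in seq_along(o)) {
    num <- num + (o[i] - om) * (p[i] - pm)
    do2 <- do2 + (o[i] - om)^2
    dp2 <- dp2 + (p[i] - pm)^2
  }
  num / sqrt(do2 * dp2)
}

oracle_rae <- function(o, p) {
  om <- mean(o)
  num <- 0; den <- 0
  for (i in seq_along(o)) {
    num <- num + abs(o[i] - p[i])
    den <- den + abs(o[i] - om)
  }
  num / den
}

oracle_rrse <- function(o, p) {
  om <- mean(o)
  num <- 0; den <- 0
  for (i in seq_along(o)) {
    num <- num + (o[i] - p[i])^2
    den <- den + (o[i] - om)^2
  }
  sqrt(num / den)
}

oracle_coverage25 <- function(o, p, band = 0.25, zero_tol = 0.01) {
  hits <- 0
  for (i in seq_along(o)) {
    ok <- if (o[i] == 0) abs(p[i]) <= zero_tol
          else abs(p[i] - o[i]) <= band * o[i]
    if (ok) hits <- hits + 1
  }
  hits / length(o)
}

oracle_vif <- function(x) {
  out <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    fit <- lm(x[, j] ~ x[, -j, drop = FALSE])
    out[j] <- 1 / (1 - summary(fit)$r.squared)
  }
  out
}

# Small trait table with an exact linear response, for model capacity
# checks (no noise unless sd > 0).
linear_trait_table <- function(n, seed = 1, sd = 0) {
  withr::with_seed(seed, {
    d <- data.frame(PH = runif(n, 70, 130), PeD = runif(n, 2, 6),
                    IL1 = runif(n, 4, 12), IL2 = runif(n, 8, 18))
    d$LS <- 0.002 * d$PH - 0.03 * d$PeD + 0.01 * d$IL1 + 0.005 * d$IL2
    if (sd > 0) d$LS <- d$LS + rnorm(n, 0, sd)
    d
  })
}
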