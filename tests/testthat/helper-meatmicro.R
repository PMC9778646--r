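# shared fixtures and independent oracles

mab_limit <- function() dplyr::filter(default_limits(), analyte == "MAB")

random_params <- function(seed, ni = 9, nh = 10, no = 4, scale = 1) {
  set.seed(seed)
  mlp_parameters(
    matrix(rnorm(nh * ni, 0, scale), nh, ni),
    rnorm(nh, 0, scale),
    matrix(rnorm(no * nh, 0, scale), no, nh),
    rnorm(no, 0, scale)
  )
}

# brute-force three-way count classifier for replicate sets
oracle_replicate_set <- function(values, m, M, c) {
  n_above_M <- 0
  n_mid <- 0
  for (v in values) {
    if (v > M) n_above_M <- n_above_M + 1
    else if (v > m) n_mid <- n_mid + 1
  }
  if (n_above_M > 0) "unsatisfactory"
  else if (n_mid == 0) "satisfactory"
  else if (n_mid <= c) "acceptable"
  else "unsatisfactory"
}

# element-wise loop oracle for the goodness-of-fit formulas
oracle_metrics <- function(x_exp, x_pre, n_const) {
  n <- length(x_exp)
  ss <- 0; bias <- 0; mpe_sum <- 0; mpe_n <- 0
  for (i in seq_len(n)) {
    d <- x_pre[i] - x_exp[i]
    ss <- ss + d^2
    bias <- bias + d
    if (x_exp[i] != 0) {
      mpe_sum <- mpe_sum + abs(d) / x_exp[i]
      mpe_n <- mpe_n + 1
    }
  }
  ybar <- sum(x_exp) / n
  ss_tot <- 0
  for (i in seq_len(n)) ss_tot <- ss_tot + (x_exp[i] - ybar)^2
  resid <- numeric(n)
  for (i in seq_len(n)) resid[i] <- x_pre[i] - x_exp[i]
  rbar <- sum(resid) / n
  m2 <- sum((resid - rbar)^2) / n
  m3 <- sum((resid - rbar)^3) / n
  m4 <- sum((resid - rbar)^4) / n
  list(
    chi2 = ss / (n - n_const),
    rmse = sqrt(ss / n),
    mbe = bias / n,
    mpe = 100 * mpe_sum / mpe_n,
    r2 = 1 - ss / ss_tot,
    skew = m3 / m2^1.5,
    kurt = m4 / m2^2 - 3
  )
}

# explicit double-loop Yoon oracle
oracle_yoon <- function(W1, W2) {
  ni <- ncol(W1); no <- nrow(W2); nh <- nrow(W1)
  s <- matrix(0, ni, no)
  for (i in seq_len(ni)) {
    for (k in seq_len(no)) {
      for (j in seq_len(nh)) s[i, k] <- s[i, k] + W1[j, i] * W2[k, j]
    }
  }
  ri <- s
  for (k in seq_len(no)) ri[, k] <- 100 * s[, k] / sum(abs(s[, k]))
  ri
}

# records whose outputs come from a known 9-10-4 network (noiseless)
known_net_records <- function(seed, n = 216) {
  set.seed(seed)
  rec <- tibble::tibble(
    storage_temp = runif(n, 2, 7),
    meat_temp = runif(n, 2, 7) + runif(n, 0, 2),
    butcher = sample(c("A", "B", "C", "D"), n, replace = TRUE),
    weekday = sample(c("Monday", "Wednesday", "Friday"), n, replace = TRUE)
  )
  x <- encode_features(rec)
  for (cc in c("storage_temp", "meat_temp")) {
    x[, cc] <- (x[, cc] - min(x[, cc])) / (max(x[, cc]) - min(x[, cc]))
  }
  true <- mlp_parameters(
    matrix(rnorm(90, 0, 0.8), 10, 9), rnorm(10, 0, 0.5),
    matrix(rnorm(40, 0, 0.8), 4, 10), rnorm(4, 0, 0.5)
  )
  y <- mlp_forward(true, x)
  rec$mab <- y[, 1]; rec$lab <- y[, 2]
  rec$e_coli <- y[, 3]; rec$s_aureus <- y[, 4]
  rec
}

# strong planted butcher effects for the sign-recovery property
strong_effect_config <- function(seed) {
  analytes <- default_analyte_params()
  analytes$mab$butcher <- c(A = 0, B = -2, C = 2, D = 0)
  generator_config(analytes = analytes, seed = seed)
}
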