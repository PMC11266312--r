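# Independent brute-force oracles, deliberately naive implementations kept
# separate from the package's code paths.

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

oracle_ssr <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - y[i])^2
  s
}

oracle_bias <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - y[i])
  s / length(x)
}

oracle_hedges_g <- function(x, y) {
  n <- length(x)
  vx <- sum((x - sum(x) / n)^2) / (n - 1)
  vy <- sum((y - sum(y) / n)^2) / (n - 1)
  sp <- sqrt((vx + vy) / 2)
  abs(sum(x) / n - sum(y) / n) / sp * (1 - 3 / (4 * (2 * n - 2) - 1))
}

# competition rank (ties share the minimum rank) by pairwise counting:
# rank(i) = 1 + number of strictly better values
oracle_competition_rank <- function(values, decreasing = FALSE) {
  v <- if (decreasing) -values else values
  v[!is.finite(v)] <- Inf
  vapply(seq_along(v), function(i) 1L + sum(v < v[i]), integer(1))
}

# power of the matched-pairs t test by quadrature over the scale mixture:
# T' = (Z + ncp) / sqrt(V / df), Z ~ N(0,1) independent of V ~ chi^2_df,
# so power = E_V[ P(Z > tcrit sqrt(V/df) - ncp) + P(Z < -tcrit sqrt(V/df) - ncp) ]
# (uses only central normal / chi-square routines)
oracle_paired_power <- function(n, dz, alpha = 0.05, tails = 2) {
  df <- n - 1
  ncp <- dz * sqrt(n)
  tcrit <- qt(1 - alpha / tails, df)
  upper <- function(v) dchisq(v, df) * pnorm(tcrit * sqrt(v / df) - ncp,
                                             lower.tail = FALSE)
  pow <- integrate(upper, 0, Inf, rel.tol = 1e-10)$value
  if (tails == 2) {
    lower <- function(v) dchisq(v, df) * pnorm(-tcrit * sqrt(v / df) - ncp)
    pow <- pow + integrate(lower, 0, Inf, rel.tol = 1e-10)$value
  }
  pow
}

# random valid pressure/age input frame for algebraic property tests
random_inputs <- function(n, seed = 42) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    dap <- runif(n, 40, 110)
    pp <- runif(n, 10, 90)
    data.frame(sap = dap + pp, dap = dap, pp = pp,
               age = runif(n, 18, 80), weight = runif(n, 45, 120),
               height = runif(n, 1.5, 2.1), hr = runif(n, 45, 160))
  })
}

# evaluate one pressure-based formula straight from its canonical a,b,c,d
canonical_predict <- function(formula_id, inp) {
  cc <- canonical_coefficients(formula_id)
  cc[["a"]] + cc[["b"]] * inp$pp - cc[["c"]] * inp$dap - cc[["d"]] * inp$age
}

small_study <- function(seed = 1, beats = 10, ...) {
  simulate_study(protocol_config(beats_per_phase = beats), seed = seed, ...)
}
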