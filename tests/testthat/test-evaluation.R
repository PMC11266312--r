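test_that("pearson_r matches hand oracles and flags degenerate input", {
  x <- c(1, 2, 3)
  expect_equal(pearson_r(x, 2 * x + 1), 1.0)
  expect_equal(pearson_r(x, -x), -1.0)
  expect_equal(round(pearson_r(x, c(1, 2, 4)), 3), 0.982)
  expect_equal(pearson_r(x, c(1, 2, 4)), oracle_pearson(x, c(1, 2, 4)))
  expect_warning(r <- pearson_r(x, c(5, 5, 5)), "constant")
  expect_true(is.na(r))
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("hedges_g implements the pooled-SD corrected effect size", {
  expect_equal(hedges_g(c(1, 2, 3), c(1, 2, 3)), 0)
  # two long series engineered to exact means/SDs 123+/-28 vs 87+/-14
  n <- 4000
  z <- scale(rnorm(n))[, 1]
  x <- 123 + 28 * z
  y <- 87 + 14 * sample(z)   # breaks pairing; only moments matter here
  expect_equal(round(hedges_g(x, y), 2), 1.63)
  expect_equal(hedges_g(x, y), oracle_hedges_g(x, y))
  # scale invariance
  expect_equal(hedges_g(2 * x, 2 * y), hedges_g(x, y))
  # correction factor J relates g to uncorrected d exactly
  J <- 1 - 3 / (4 * (2 * n - 2) - 1)
  expect_equal(hedges_g(x, y), hedges_g(x, y, correction = FALSE) * J)
  expect_warning(g <- hedges_g(c(1, 1), c(2, 2)), "infinite")
  expect_true(is.infinite(g))
})

test_that("SSR and bias agree with brute-force loops to 1e-9", {
  expect_equal(sum_squared_residuals(c(2, 0, 4), c(1, 2, 1)), 14)
  x <- rnorm(1000, 80, 10); y <- x + rnorm(1000, 1, 5)
  expect_equal(sum_squared_residuals(x, x), 0)
  expect_lt(abs(sum_squared_residuals(x, y) - oracle_ssr(x, y)), 1e-9)
  expect_lt(abs(mean_bias(x, y) - oracle_bias(x, y)), 1e-12)
  expect_equal(mean_bias(y + 5, y), 5)
  perm <- sample(1000)
  expect_equal(mean_bias(x[perm], y[perm]), mean_bias(x, y))
})

test_that("Bland-Altman fields satisfy their defining identities", {
  x <- rnorm(500, 80, 10); y <- x - rnorm(500, 0.7, 6)
  ba <- bland_altman(x, y)
  expect_equal(ba$bias, mean_bias(x, y))
  expect_equal(ba$loa_low, ba$bias - 1.96 * ba$sd_diff)
  expect_equal(ba$loa_high, ba$bias + 1.96 * ba$sd_diff)
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * sd(x - y))
  expect_true(ba$loa_low <= ba$bias && ba$bias <= ba$loa_high)

  zeros <- bland_altman(x, x)
  expect_equal(unlist(zeros[c("bias", "sd_diff", "loa_low", "loa_high")]),
               c(bias = 0, sd_diff = 0, loa_low = 0, loa_high = 0))

  proj <- loa_cv_ratio(ba, 70)
  expect_equal(unname(proj["high_ml"] - proj["low_ml"]), 2 * 1.96 * ba$sd_diff)
})

test_that("constant prediction offsets shift bias and leave r untouched", {
  x <- rnorm(300, 80, 12); y <- 0.8 * x + rnorm(300, 0, 5)
  c0 <- 4.2
  expect_equal(mean_bias(x, y - c0), mean_bias(x, y) + c0)
  expect_equal(pearson_r(x, y - c0), pearson_r(x, y))
})

test_that("rank aggregation uses competition ranks over the four metrics", {
  # 12 synthetic formulae engineered so 'target' draws ranks (1, 11, 1, 2)
  n_f <- 12
  ms <- data.frame(
    formula_id = c("target", paste0("f", 1:(n_f - 1))),
    stratum = "both/both", n = 100,
    r = c(0.9, seq(0.1, 0.6, length.out = n_f - 1)),
    g = c(1.0, seq(0.01, 0.1, length.out = 10), 2.0),
    ssr = c(10, seq(20, 120, length.out = n_f - 1)),
    bias = c(0.5, 0.1, seq(1, 10, length.out = n_f - 2)),
    mean_measured = 80, sd_measured = 10, mean_predicted = 78,
    sd_predicted = 9, stringsAsFactors = FALSE)
  tab <- rank_formulae(ms)
  tgt <- tab[tab$formula_id == "target", ]
  expect_equal(c(tgt$rank_r, tgt$rank_g, tgt$rank_ssr, tgt$rank_bias),
               c(1L, 11L, 1L, 2L))
  expect_equal(tgt$total_score, 15L)
  expect_equal(tab$total_score, tab$rank_r + tab$rank_g + tab$rank_ssr + tab$rank_bias)
})

test_that("ranks match a pairwise-counting oracle and share minima on ties", {
  set.seed(31)
  for (rep in 1:5) {
    k <- 8
    ms <- data.frame(
      formula_id = paste0("f", 1:k), stratum = "both/both", n = 50,
      r = round(runif(k, -1, 1), 1), g = round(rexp(k), 1),
      ssr = round(runif(k, 10, 30)), bias = round(rnorm(k), 1),
      mean_measured = 80, sd_measured = 10, mean_predicted = 78,
      sd_predicted = 9, stringsAsFactors = FALSE)
    tab <- rank_formulae(ms)
    o <- match(ms$formula_id, tab$formula_id)
    expect_equal(tab$rank_r[o], oracle_competition_rank(abs(ms$r), TRUE))
    expect_equal(tab$rank_g[o], oracle_competition_rank(abs(ms$g)))
    expect_equal(tab$rank_ssr[o], oracle_competition_rank(ms$ssr))
    expect_equal(tab$rank_bias[o], oracle_competition_rank(abs(ms$bias)))
  }
  # identical metric rows (algebraic duplicates) share every rank
  ms2 <- data.frame(formula_id = c("a", "b", "c"), stratum = "x", n = 10,
                    r = c(0.65, 0.65, 0.3), g = c(0.8, 0.8, 0.2),
                    ssr = c(100, 100, 400), bias = c(2, 2, 9),
                    mean_measured = 1, sd_measured = 1, mean_predicted = 1,
                    sd_predicted = 1, stringsAsFactors = FALSE)
  tab2 <- rank_formulae(ms2)
  expect_equal(tab2[tab2$formula_id == "a", c("rank_r", "rank_g", "rank_ssr", "rank_bias")],
               tab2[tab2$formula_id == "b", c("rank_r", "rank_g", "rank_ssr", "rank_bias")],
               ignore_attr = TRUE)
  # c has the smallest effect size, so a and b share the minimum rank 2
  expect_equal(tab2$rank_g[tab2$formula_id == "c"], 1L)
  expect_equal(tab2$rank_g[tab2$formula_id == "a"], 2L)
})

test_that("ranking is invariant to input order and ranks NA metrics last", {
  set.seed(77)
  k <- 6
  ms <- data.frame(formula_id = paste0("f", 1:k), stratum = "s", n = 30,
                   r = runif(k), g = runif(k), ssr = runif(k, 5, 50),
                   bias = rnorm(k), mean_measured = 1, sd_measured = 1,
                   mean_predicted = 1, sd_predicted = 1,
                   stringsAsFactors = FALSE)
  ms$r[2] <- NA
  t1 <- rank_formulae(ms)
  t2 <- rank_formulae(ms[sample(k), ])
  expect_equal(t1, t2)
  expect_equal(t1$rank_r[t1$formula_id == "f2"], k)
  expect_match(t1$note[t1$formula_id == "f2"], "undefined")
})

test_that("stratified evaluation recovers the generating law and bookkeeping", {
  sim <- small_study(seed = 8, beats = 12)
  rep <- suppressWarnings(stratified_report(sim$observations, sim$participants))
  expect_length(rep$rankings, 9L)
  best_all <- rep$rankings[["both/both"]]
  full <- best_all[best_all$n == max(best_all$n), ]
  expect_true(full$formula_id[which.min(full$ssr)] %in%
                c("starr54_eq72", "starr54_eq71", "jackson55"))
  # summary row echoes the measured mean/SD of its stratum
  strat_recs <- filter_stratum(sim$observations, stratum("supine", "hot"))
  row <- rep$best[rep$best$stratum == "supine/hot", ]
  expect_equal(row$mean_measured, mean(strat_recs$sv_measured))
  expect_equal(row$sd_measured, sd(strat_recs$sv_measured))

  # single-stratum input yields exactly one table
  one <- suppressWarnings(stratified_report(strat_recs, sim$participants,
                                            strata = list(stratum())))
  expect_length(one$rankings, 1L)
})
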