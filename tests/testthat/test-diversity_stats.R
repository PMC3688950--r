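test_that("chao1 point estimates match hand evaluation", {
  # no singletons: estimate collapses to S_obs with a degenerate interval
  est0 <- chao1(c(3, 4, 12))
  expect_equal(est0$value, 3)
  expect_equal(c(est0$lower, est0$upper), c(3, 3))

  expect_equal(chao1(c(1, 1, 2, 3))$value, 4 + 2 * 1 / (2 * (1 + 1)))  # 4.5
  expect_equal(chao1(c(1, 1, 2, 3), "classic")$value, 4 + 4 / 2)       # 6.0
  # classic falls back to bias-corrected when f2 = 0
  expect_equal(chao1(c(1, 1, 3), "classic")$value,
               chao1(c(1, 1, 3), "bias_corrected")$value)
  expect_error(chao1(numeric(0)), "empty")
})

test_that("chao1 interval brackets the point estimate and floors at S_obs", {
  set.seed(5)
  for (trial in 1:25) {
    v <- sample(1:8, sample(3:12, 1), replace = TRUE)
    for (variant in c("bias_corrected", "classic")) {
      est <- chao1(v, variant)
      expect_gte(est$value, length(v))
      expect_lte(est$lower, est$value + 1e-9)
      expect_gte(est$upper, est$value - 1e-9)
      expect_gte(est$lower, length(v) - 1e-9)
    }
  }
})

test_that("chao1 agrees with vegan's estimator", {
  skip_if_not_installed("vegan")
  set.seed(6)
  for (trial in 1:10) {
    v <- sample(1:6, sample(4:15, 1), replace = TRUE)
    vegan_chao <- unname(suppressWarnings(vegan::estimateR(v))["S.chao1"])
    expect_equal(chao1(v)$value, vegan_chao)
  }
})

test_that("ace matches an independent evaluation of the formula", {
  # counts {1,1,1,5}: f1 = 3, N_rare = 8, C_ace = 5/8
  c_ace <- 1 - 3 / 8
  s_rare_over_c <- 4 / c_ace
  gamma2 <- max(0, s_rare_over_c * (5 * 4 * 1) / (8 * 7) - 1)
  expect_equal(ace(c(1, 1, 1, 5))$value,
               s_rare_over_c + (3 / c_ace) * gamma2)

  # all counts above the cutoff: no rare group, estimate is S_obs
  expect_equal(ace(c(20, 30, 40))$value, 3)

  # all singletons: C_ace = 0 triggers the chao1 fallback
  expect_warning(fb <- ace(c(1, 1, 1, 1)), "falling back")
  expect_equal(fb$value, chao1(c(1, 1, 1, 1))$value)

  skip_if_not_installed("vegan")
  set.seed(8)
  for (trial in 1:10) {
    v <- c(sample(1:9, 8, replace = TRUE), sample(11:40, 3))
    expect_equal(ace(v)$value,
                 unname(suppressWarnings(vegan::estimateR(v))["S.ACE"]))
  }
})

test_that("shannon index matches closed forms and is permutation invariant", {
  expect_equal(shannon(7)$value, 0)
  expect_equal(shannon(rep(5, 4))$value, log(4))
  expect_equal(shannon(c(2, 1, 1))$value,
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_equal(shannon(c(3, 9, 1, 5))$value, shannon(c(9, 5, 3, 1))$value)
  # uniform vectors maximize H' at fixed richness
  set.seed(9)
  for (trial in 1:10) {
    v <- sample(1:20, 6, replace = TRUE)
    expect_lte(shannon(v)$value, log(6) + 1e-12)
  }
  expect_equal(shannon(rep(2, 8), base = 2)$value, 3)
  skip_if_not_installed("vegan")
  v <- c(4, 1, 7, 2, 2)
  expect_equal(shannon(v)$value, unname(vegan::diversity(v)))
})

test_that("Good's coverage equals 1 - f1/N", {
  expect_equal(goods_coverage(c(5, 5))$value, 1)
  expect_equal(goods_coverage(c(1, 1, 1, 1))$value, 0)
  expect_equal(goods_coverage(c(1, 2, 3))$value, 1 - 1 / 6)
  set.seed(10)
  for (trial in 1:10) {
    v <- sample(1:5, 8, replace = TRUE)
    cv <- goods_coverage(v)$value
    expect_gte(cv, 0)
    expect_lte(cv, 1)
  }
})

test_that("boneh prediction has the expected limiting behavior", {
  v <- c(1, 1, 1, 2, 3, 10)
  expect_equal(boneh(v, m = 0)$value, 0)
  # saturated library (no rare tail) predicts essentially nothing new
  expect_equal(boneh(c(25, 30, 44))$value, 0)
  # non-decreasing in m and bounded by the unseen-pool size
  ms <- c(0, 5, 18, 50, 200, 1e5)
  vals <- vapply(ms, function(m) boneh(v, m)$value, numeric(1))
  expect_true(all(diff(vals) >= 0))
  s0 <- 3 * 2 / (2 * (1 + 1))  # f1 = 3, f2 = 1
  expect_true(all(vals <= s0 + 1e-9))
  expect_error(boneh(v, m = -1), "non-negative")
})

test_that("boneh matches Monte-Carlo resampling of its fitted model", {
  # fitted model: S0 unseen OTUs, each hit per clone with probability mu0
  # (vector chosen so the unseen pool S0 = f1(f1-1)/(2(f2+1)) is integral)
  v <- c(1, 1, 1, 2, 2, 10)
  m <- 18
  f1 <- 3; f2 <- 2; n <- sum(v)
  s0 <- f1 * (f1 - 1) / (2 * (f2 + 1))
  mu0 <- f1 / (n * s0)
  set.seed(123)
  reps <- 10000
  new_counts <- vapply(seq_len(reps), function(r) {
    sum(stats::rbinom(s0, m, mu0) > 0)
  }, numeric(1))
  mc <- mean(new_counts)
  se <- stats::sd(new_counts) / sqrt(reps)
  expect_gte(boneh(v, m)$value, mc - 3 * se)
  expect_lte(boneh(v, m)$value, mc + 3 * se)
})

test_that("rarefaction endpoints and closed form are exact", {
  v <- c(4, 3, 2, 1)
  rc <- rarefaction(v, depths = c(1, 5, sum(v)))
  expect_equal(rc$richness[1], 1)
  expect_equal(rc$richness[3], 4)
  expect_true(all(diff(rarefaction(v)$richness) >= -1e-12))
  expect_error(rarefaction(v, depths = 11), "depths")

  skip_if_not_installed("vegan")
  expect_equal(rarefaction(v, depths = 5)$richness,
               as.numeric(vegan::rarefy(v, 5)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("rarefaction matches Monte-Carlo subsampling within 3 SE", {
  set.seed(321)
  v <- c(9, 5, 3, 2, 1, 1)
  pool <- rep(seq_along(v), v)
  depth <- 7
  reps <- 20000
  richness <- vapply(seq_len(reps), function(r)
    length(unique(sample(pool, depth))), numeric(1))
  mc <- mean(richness)
  se <- stats::sd(richness) / sqrt(reps)
  closed <- rarefaction(v, depths = depth)$richness
  expect_lt(abs(closed - mc), 3 * se)
})

test_that("richness estimators never fall below observed richness", {
  set.seed(14)
  for (trial in 1:20) {
    v <- sample(1:12, sample(3:20, 1), replace = TRUE)
    s <- length(v)
    expect_gte(chao1(v)$value, s)
    expect_gte(suppressWarnings(ace(v))$value, s - 1e-9)
  }
})

test_that("the tidy diversity table covers each library and estimator", {
  tab <- make_otu_table(cbind(A = c(4, 1, 1, 0), B = c(0, 2, 3, 1)))
  div <- diversity_table(tab)
  expect_equal(nrow(div), 2 * 6)
  expect_setequal(unique(div$library), c("A", "B"))
  expect_equal(div$value[div$library == "A" & div$estimator == "sobs"], 3)
  expect_equal(div$value[div$library == "B" &
                           div$estimator == "goods_coverage"],
               1 - 1 / 6)
})
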