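test_that("DVH of a uniform dose is a step with exact quantiles", {
  g <- voxel_grid(c(6, 6, 6), spacing = c(2, 2, 2))
  m <- array(TRUE, g$shape)
  d <- array(42.56, g$shape)
  h <- dvh(d, m)
  expect_equal(volume_at_dose(h, 42), 100)
  expect_equal(volume_at_dose(h, 43), 0)
  expect_equal(dose_at_volume(h, 5), 42.56)
  expect_equal(dose_at_volume(h, 95), 42.56)
  expect_equal(h$cum_volume_pct[1], 100)   # V(0) = 100
  expect_error(dvh(d, array(FALSE, g$shape)), "empty")
})

test_that("DVH counting matches the ramp closed form and is monotone", {
  g <- voxel_grid(c(100, 1, 1), spacing = c(1, 1, 1))
  m <- array(TRUE, g$shape)
  d <- array(seq(0, 40, length.out = 100), g$shape)
  h <- dvh(d, m)
  expect_lt(abs(volume_at_dose(h, 20) - 50), 1.01)  # within one voxel
  expect_true(all(diff(h$cum_volume_pct) <= 0))
  expect_equal(h$cum_volume_pct[length(h$cum_volume_pct)], 0)

  # random doses: curve monotone, Dx/Vx generalized-inverse consistency
  set.seed(9)
  for (rep in 1:5) {
    dr <- array(rgamma(prod(g$shape), 8, 0.25), g$shape)
    hr <- dvh(dr, m)
    expect_true(all(diff(hr$cum_volume_pct) <= 0))
    for (x in c(2, 5, 50, 95, 98)) {
      dx <- dose_at_volume(hr, x)
      expect_gte(volume_at_dose(hr, dx), x)
      expect_lte(volume_at_dose(hr, dx + 1e-9), x)
    }
  }
})

test_that("plan metrics hit the closed forms for constructed doses", {
  ph <- coarse_phantom("medium", seed = 6)
  ss <- ph$structures
  g <- ph$grid
  rx <- prescription()
  ptv <- get_mask(ss, "PTV")

  # uniform prescription exactly inside the PTV: HI = 1, CI = 1, V110 = 0
  d <- array(0, g$shape)
  d[ptv] <- rx$total_dose_gy
  m <- plan_metrics(d, ss, rx, mu = 123)
  expect_equal(m$hi, 1)
  expect_equal(m$ci, 1)
  expect_equal(m$body_v110_pct, 0)
  expect_equal(m$ptv_v95_pct, 100)
  expect_equal(m$mu, 123)

  # 5% of PTV at 44 Gy, rest at prescription: HI = 44 / 42.56
  idx <- which(ptv)
  n5 <- ceiling(0.05 * length(idx))
  d2 <- d
  d2[idx[seq_len(n5)]] <- 44
  m2 <- plan_metrics(d2, ss, rx)
  expect_equal(m2$hi, 44 / 42.56, tolerance = 1e-9)

  # BV95 spread over twice the PTV volume with full coverage: CI = 2
  extra <- which(get_mask(ss, "Body") & !ptv)
  d3 <- d
  d3[extra[seq_len(length(idx))]] <- rx$total_dose_gy
  expect_equal(plan_metrics(d3, ss, rx)$ci, 2)
})

test_that("V95 normalization rescales the dose axis correctly", {
  g <- voxel_grid(c(5, 5, 4), spacing = c(2, 2, 2))
  m <- array(TRUE, g$shape)
  set.seed(2)
  d <- array(40 + runif(prod(g$shape), 0, 4), g$shape)
  ha <- dvh(d, m)
  expect_equal(normalize_to_v95(ha, ha)$dose_bins_gy, ha$dose_bins_gy)

  hb <- dvh(d * 1.02, m)
  hn <- normalize_to_v95(ha, hb)
  expect_equal(dose_at_volume(hn, 95), dose_at_volume(ha, 95), tolerance = 1e-12)
  expect_equal(hn$doses, ha$doses, tolerance = 1e-12)

  expect_error(normalize_to_v95(ha, dvh(array(0, g$shape), m)), "degenerate")
})

test_that("mean DVH band reproduces the t-interval closed form", {
  mk <- function(v) structure(list(structure = "PTV",
                                   dose_bins_gy = seq(0, 10, 0.5),
                                   cum_volume_pct = v,
                                   doses = NULL), class = "dvh")
  base <- 100 * (1 - seq(0, 1, length.out = 21))
  same <- lapply(1:4, function(i) mk(base))
  b <- mean_dvh_band(same, bin_width_gy = 0.5)
  expect_equal(b$mean_pct, base)
  expect_equal(b$upper_pct - b$lower_pct, rep(0, 21))

  two <- list(mk(rep(40, 21)), mk(rep(60, 21)))
  expect_equal(mean_dvh_band(two, bin_width_gy = 0.5)$mean_pct, rep(50, 21))

  set.seed(4)
  curves <- lapply(1:20, function(i) mk(pmin(pmax(base + rnorm(21, 0, 3), 0), 100)))
  b20 <- mean_dvh_band(curves, bin_width_gy = 0.5)
  vals <- vapply(curves, function(c) c$cum_volume_pct, numeric(21))
  half <- qt(0.975, 19) * apply(vals, 1, sd) / sqrt(20)
  mid <- 5:15  # away from the clamps at 0 and 100
  expect_equal((b20$upper_pct - b20$lower_pct)[mid], (2 * half)[mid],
               tolerance = 1e-9)

  expect_error(mean_dvh_band(same[1]), "two")
})

test_that("paired t-test matches the textbook formula and handles degeneracy", {
  a <- c(12.1, 13.4, 11.8, 14.2, 12.9)
  b <- c(11.5, 13.9, 11.2, 13.1, 12.4)
  res <- paired_t_test(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df = 4), tolerance = 1e-12)
  expect_equal(res$df, 4)

  same <- paired_t_test(a, a)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)

  expect_error(paired_t_test(a + 1, a), "undefined")
  expect_error(paired_t_test(a, b[1:3]), "length")
})

test_that("one-way ANOVA matches hand sums of squares and the F = t^2 identity", {
  g1 <- c(4.1, 5.2, 4.8); g2 <- c(6.3, 5.9, 6.8); g3 <- c(5.1, 4.4, 5.6)
  res <- one_way_anova(list(g1, g2, g3))
  y <- c(g1, g2, g3); gm <- mean(y)
  ssb <- 3 * ((mean(g1) - gm)^2 + (mean(g2) - gm)^2 + (mean(g3) - gm)^2)
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2) + sum((g3 - mean(g3))^2)
  f_hand <- (ssb / 2) / (ssw / 6)
  expect_equal(res$F, f_hand, tolerance = 1e-12)
  expect_equal(res$p, pf(f_hand, 2, 6, lower.tail = FALSE), tolerance = 1e-12)

  # two groups: F equals the square of the pooled-variance t statistic
  tt <- t.test(g1, g2, var.equal = TRUE)
  res2 <- one_way_anova(list(g1, g2))
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res2$p, tt$p.value, tolerance = 1e-12)

  # all groups constant and equal
  resc <- one_way_anova(list(rep(2, 3), rep(2, 4)))
  expect_equal(resc$F, 0)
  expect_equal(resc$p, 1)
  expect_true(resc$degenerate)

  expect_error(one_way_anova(list(g1)), "two groups")
  expect_error(one_way_anova(list(g1, c(1))), "at least two values")
})
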