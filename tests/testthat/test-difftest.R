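test_that("window background variance averages ranked neighbors", {
  # constant variances: background equals that constant everywhere
  expect_equal(window_background_variance(rnorm(20), rep(2.5, 20), 5),
               rep(2.5, 20))
  # a window spanning all strains gives the global mean at the center;
  # end windows are truncated
  v <- runif(9)
  bg9 <- window_background_variance(seq_len(9), v, 9)
  expect_equal(bg9[5], mean(v))
  expect_equal(bg9[1], mean(v[1:5]))
  # hand case: 5 strains ranked in order, variances 1..5, window 3
  bg <- window_background_variance(1:5, c(1, 2, 3, 4, 5), 3)
  expect_equal(bg[3], 3)
  expect_equal(bg[1], 1.5)
  expect_equal(bg[5], 4.5)
  # ranking is by means, not input order
  bg2 <- window_background_variance(c(5, 4, 3, 2, 1), c(5, 4, 3, 2, 1), 3)
  expect_equal(bg2[3], 3)
  expect_equal(bg2[5], 1.5)
  expect_warning(window_background_variance(1:4, 1:4, 7), "clamped")
})

test_that("regularized t matches its closed form on the worked case", {
  ctrl <- c(1.0, 1.2, 0.8, 1.0)
  drug <- c(2.0, 2.2, 1.8, 2.0)
  r <- regularized_t(mean(ctrl), mean(drug),
                     var(ctrl), var(drug), 4, 4,
                     bg_c = 0.04, bg_d = 0.04, conf = 15)
  expect_equal(r$var_c, (15 * 0.04 + 3 * var(ctrl)) / 17)
  expect_equal(r$var_c, 0.04, tolerance = 1e-12)
  expect_equal(r$t, 1 / sqrt(0.02), tolerance = 1e-12)
  expect_equal(r$df, 4 + 4 + 2 * 15 - 4)

  # equal means
  r0 <- regularized_t(1, 1, 0.1, 0.1, 4, 4, 0.1, 0.1, 15)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)

  # conf -> large: regularized variance approaches the background
  rInf <- regularized_t(0, 1, 0.5, 0.5, 4, 4, 0.04, 0.04, 1e8)
  expect_equal(rInf$var_c, 0.04, tolerance = 1e-6)

  # degenerate all-zero case
  rz <- regularized_t(1, 1, 0, 0, 4, 4, 0, 0, 15)
  expect_equal(rz$t, 0)
  expect_equal(rz$p, 1)
})

test_that("vectorized statistics equal the scalar oracle on random cases", {
  set.seed(99)
  n_cases <- 1000
  ctrl <- matrix(rnorm(4 * n_cases, 10, 0.5), ncol = 4)
  drug <- matrix(rnorm(4 * n_cases, 10, 0.5), ncol = 4)
  bg_c <- runif(n_cases, 0.01, 0.5)
  bg_d <- runif(n_cases, 0.01, 0.5)
  conf <- sample(c(0.5, 4, 15, 40), n_cases, replace = TRUE)

  impl <- regularized_t(rowMeans(ctrl), rowMeans(drug),
                        apply(ctrl, 1, var), apply(drug, 1, var),
                        4, 4, bg_c, bg_d, conf = conf[1])
  for (i in seq_len(n_cases)) {
    o <- oracle_reg_t(ctrl[i, ], drug[i, ], bg_c[i], bg_d[i], conf[1])
    expect_equal(impl$t[i], o$t, tolerance = 1e-9)
    expect_equal(impl$p[i], o$p, tolerance = 1e-9)
    expect_equal(impl$df[i], o$df)
  }
})

test_that("shrinkage moves t toward the background as conf grows", {
  ctrl <- c(1.0, 1.1, 0.9, 1.05)
  drug <- c(1.5, 1.6, 1.4, 1.55)
  s2 <- var(ctrl)
  t_student <- t.test(drug, ctrl, var.equal = TRUE)$statistic
  # background larger than the sample variances => |t_reg| <= |t_student|
  big <- regularized_t(mean(ctrl), mean(drug), var(ctrl), var(drug), 4, 4,
                       10 * s2, 10 * s2, conf = 15)
  expect_lt(abs(big$t), abs(t_student))
  # background smaller => |t_reg| >= |t_student|
  small <- regularized_t(mean(ctrl), mean(drug), var(ctrl), var(drug), 4, 4,
                         s2 / 10, s2 / 10, conf = 15)
  expect_gt(abs(small$t), abs(t_student))
})

test_that("BH adjustment matches the hand step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(5)
  for (rep in 1:20) {
    p <- runif(sample(3:50, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("hit calling follows the two-day consistent-direction rule", {
  mk <- function(strain, day, p_adj, delta) {
    data.frame(strain_id = strain, day = day, p_adj = p_adj,
               p_raw = p_adj, delta = delta,
               direction = ifelse(delta > 0, "increased", "decreased"))
  }
  res <- rbind(
    mk("A", 3, 0.005, 1), mk("A", 4, 0.005, 1),   # hit, increased
    mk("B", 3, 0.005, 1),                         # one day only: no hit
    mk("C", 3, 0.005, 1), mk("C", 4, 0.005, -1),  # opposite signs: no hit
    mk("D", 1, 0.5, 1), mk("D", 2, 0.5, 1),       # never significant
    mk("E", 1, 0.001, -1), mk("E", 5, 0.002, -1), mk("E", 7, 0.5, -1))
  hits <- call_hits(res, test_params(alpha = 0.01, min_days = 2))
  h <- setNames(hits$is_hit, hits$strain_id)
  expect_true(h[["A"]])
  expect_false(h[["B"]])
  expect_false(h[["C"]])
  expect_false(h[["D"]])
  expect_true(h[["E"]])
  expect_equal(hits$direction[hits$strain_id == "A"], "increased")
  expect_equal(hits$direction[hits$strain_id == "E"], "decreased")
  expect_equal(hits$days[hits$strain_id == "E"], "1,5")
  # the two hit sets are disjoint by construction
  expect_equal(sum(hits$direction == "increased" &
                     hits$direction == "decreased"), 0)
})

test_that("per-day tests on an exact-effect table find only true effects", {
  eff <- c(rep(0, 10), 1.5, -1.5)
  tab <- tiny_table(12, days = 1:2, n_rep = 4, effect = eff)
  set.seed(2)
  tab$density <- tab$density * 2^rnorm(nrow(tab), 0, 0.05)
  attr(tab, "stage") <- "raw"
  res <- test_day(log_transform(tab), 1, test_params(window = 5))
  expect_equal(nrow(res), 12)
  expect_setequal(res$strain_id[order(res$p_adj)][1:2], c("S11", "S12"))
  expect_true(all(res$p_adj >= res$p_raw, na.rm = TRUE))
  expect_equal(res$direction[res$strain_id == "S11"], "increased")
  expect_equal(res$direction[res$strain_id == "S12"], "decreased")
})
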