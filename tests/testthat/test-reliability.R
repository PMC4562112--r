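test_that("paired t-test matches the closed form and t distribution", {
  res <- paired_t_test(c(1, 2, 3), c(2, 4, 6))  # differences 1, 2, 3
  expect_equal(res$t, mean(1:3) / (sd(1:3) / sqrt(3)), tolerance = 1e-12)
  expect_equal(res$t, 3.464, tolerance = 1e-3)
  expect_equal(res$df, 2)
  expect_equal(res$p, 2 * pt(-abs(res$t), 2), tolerance = 1e-12)
  expect_equal(res$p, 0.0742, tolerance = 1e-3)
  # negating differences flips t, leaves p
  res_neg <- paired_t_test(c(2, 4, 6), c(1, 2, 3))
  expect_equal(res_neg$t, -res$t)
  expect_equal(res_neg$p, res$p)
})

test_that("paired t-test handles degenerate inputs explicitly", {
  same <- paired_t_test(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$flag, "zero_variance")
  shift <- paired_t_test(c(1, 2, 3), c(2, 3, 4))  # constant nonzero diff
  expect_equal(shift$p, 0)
  expect_equal(shift$flag, "zero_variance")
  expect_error(paired_t_test(1, 2), class = "relrbl_degenerate_error")
})

test_that("paired t-test p-values are uniform under the null", {
  set.seed(19)
  p <- replicate(2000, paired_t_test(rnorm(40), rnorm(40))$p)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.09)
})

test_that("ICC(2,1) equals the brute-force mean-squares oracle", {
  # perfect agreement on varying sites
  mat <- matrix(rep(c(1, 5, 9, 13), 3), ncol = 3)
  expect_equal(icc_inter(mat)$icc, 1)
  # random small matrices, all shapes up to 6 sites x 4 raters x 2 repeats
  set.seed(23)
  for (n in 3:6) {
    for (k in 2:4) {
      for (r in 1:2) {
        arr <- array(rnorm(n * k * r, sd = 2) +
                       rep(rnorm(n, sd = 3), k * r), dim = c(n, k, r))
        est <- icc_inter(arr)$icc
        expect_equal(est, oracle_icc21(apply(arr, c(1, 2), mean)),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("ICC(2,1) confidence interval brackets the estimate sensibly", {
  # classic 6 targets x 4 judges illustration data
  mat <- matrix(c(9, 6, 8, 7, 10, 6,
                  2, 1, 4, 1, 5, 2,
                  5, 3, 6, 2, 6, 4,
                  8, 2, 8, 6, 9, 7), nrow = 6)
  res <- icc_inter(mat)
  expect_equal(res$icc, 0.29, tolerance = 0.005)
  expect_lt(res$ci_low, res$icc)
  expect_gt(res$ci_high, res$icc)
  expect_true(res$ci_high <= 1)
  # wider design, tighter interval
  set.seed(29)
  big <- matrix(rnorm(200 * 4) + rep(rnorm(200, sd = 3), 4), ncol = 4)
  wide <- icc_inter(mat); narrow <- icc_inter(big)
  expect_lt(narrow$ci_high - narrow$ci_low, wide$ci_high - wide$ci_low)
})

test_that("ICC degenerates are flagged, not fabricated", {
  res <- icc_inter(matrix(5, 4, 3))
  expect_true(is.nan(res$icc))
  expect_equal(res$flag, "no_between_site_variance")
  expect_error(icc_inter(matrix(1:4, ncol = 1)), class = "relrbl_input_error")
})

test_that("intra-examiner one-way ICC matches its oracle and contracts", {
  # identical duplicate reads
  arr <- array(rep(c(3, 7, 11, 2), 4), dim = c(4, 2, 2))
  res <- icc_intra(arr)
  expect_equal(res$per_examiner$icc, c(1, 1))
  expect_equal(res$pooled, 1)
  # random repeats vs the one-way ANOVA oracle
  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:6, 1); r <- sample(2:3, 1)
    arr <- array(rnorm(n * 2 * r) + rep(rnorm(n, sd = 2), 2 * r),
                 dim = c(n, 2, r))
    res <- icc_intra(arr)
    for (e in 1:2) {
      expect_equal(res$per_examiner$icc[e], oracle_icc11(arr[, e, ]),
                   tolerance = 1e-10)
    }
    expect_equal(res$pooled, mean(res$per_examiner$icc), tolerance = 1e-12)
  }
  expect_error(icc_intra(array(rnorm(8), dim = c(4, 2, 1))),
               class = "relrbl_input_error")
})

test_that("ICC recovers the generating variance ratio", {
  set.seed(37)
  sigma_b <- 2; sigma_e <- 1
  target <- sigma_b^2 / (sigma_b^2 + sigma_e^2)
  est <- replicate(500, {
    mat <- matrix(rnorm(15 * 4, sd = sigma_e) + rep(rnorm(15, sd = sigma_b), 4),
                  ncol = 4)
    icc_inter(mat)$icc
  })
  mc_se <- sd(est) / sqrt(length(est))
  # single-measure ICC is slightly downward biased at n = 15; allow 4 MC SEs
  expect_lt(abs(mean(est) - target), 4 * mc_se + 0.02)
})

test_that("percent change reproduces the reported study arithmetic", {
  expect_equal(percent_change(7.0, 7.8), 11.4)
  expect_equal(percent_change(31.4, 31.6), 0.6)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(percent_change(7.0, 7.8, round = FALSE), 100 * 0.8 / 7,
               tolerance = 1e-12)
  expect_error(percent_change(0, 5), class = "relrbl_degenerate_error")
})

test_that("uniform-scaling prediction links tooth-length and bone-level inflation", {
  expect_equal(round(scaled_mean_prediction(7.0, 22.1, 24.7), 1), 7.8)
  expect_error(scaled_mean_prediction(7, 0, 1), class = "relrbl_degenerate_error")
})

make_readings <- function(n_sites = 4, n_ex = 2, n_rep = 2, angles = c(0, 30),
                          value_fun) {
  grid <- expand.grid(site = paste0("s", seq_len(n_sites)),
                      examiner = seq_len(n_ex), "repeat" = seq_len(n_rep),
                      angle = angles, metric = c("length", "rbl", "rel_rbl"),
                      stringsAsFactors = FALSE)
  grid$value <- value_fun(grid)
  grid
}

test_that("summarize_study reduces a reading table to the dual-angle summary", {
  # noise-free uniform elongation: ratios invariant, distances inflated
  base <- c(s1 = 20, s2 = 21, s3 = 22, s4 = 23)
  rd <- make_readings(value_fun = function(g) {
    scale <- ifelse(g$angle == 30, 1 / cos(pi / 6), 1)
    ifelse(g$metric == "length", base[g$site] * scale,
           ifelse(g$metric == "rbl", 7 * scale, 100 * 7 / base[g$site]))
  })
  s <- summarize_study(rd)
  expect_equal(s$n, rep(4L, 3))
  expect_equal(s$percent_change[s$metric == "length"],
               100 * (1 / cos(pi / 6) - 1), tolerance = 1e-9)
  rrow <- s[s$metric == "rel_rbl", ]
  expect_equal(rrow$percent_change, 0, tolerance = 1e-12)
  expect_equal(rrow$p_value, 1)
  expect_equal(rrow$flag, "zero_variance")
  expect_equal(s$mean_0[s$metric == "rbl"], 7)
  expect_error(summarize_study(rd[0, ]), class = "relrbl_input_error")
})

test_that("summarize_study drops unpaired sites with a message", {
  rd <- make_readings(value_fun = function(g) rnorm(nrow(g), 10))
  rd <- rd[!(rd$site == "s4" & rd$angle == 30), ]
  expect_message(s <- summarize_study(rd), "unpaired")
  expect_equal(unique(s$n), 3L)
})

test_that("reliability_report spans metrics and flags thin designs", {
  rd <- make_readings(n_sites = 6, n_ex = 3,
                      value_fun = function(g) {
                        rep(rnorm(6, sd = 3), length.out = nrow(g)) +
                          rnorm(nrow(g), sd = 0.3)
                      })
  rep_ <- reliability_report(rd)
  expect_setequal(rep_$metric, c("length", "rbl", "rel_rbl"))
  expect_true(all(rep_$icc_inter > 0.5 & rep_$icc_inter <= 1))
  expect_true(all(rep_$inter_ci_low <= rep_$icc_inter))
  # single examiner: inter-ICC skipped with a warning
  solo <- rd[rd$examiner == 1, ]
  expect_warning(reliability_report(solo[solo$metric == "rbl", ]),
                 class = "relrbl_warning")
  rs <- suppressWarnings(reliability_report(solo))
  expect_true(all(is.na(rs$icc_inter)))
  expect_true(all(is.finite(rs$icc_intra_pooled)))
})
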