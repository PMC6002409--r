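test_that("paired t matches hand computation and symmetry", {
  r0 <- paired_t(c(-1, 0, 1), c(0, 0, 0))
  expect_equal(r0$t, 0)
  expect_equal(r0$mean_diff, 0)

  r <- paired_t(c(2, 4, 6, 8), c(0, 0, 0, 0))
  expect_equal(r$mean_diff, 5)
  expect_equal(r$df, 3)
  expect_equal(r$t, 5 / (sd(c(2, 4, 6, 8)) / 2), tolerance = 1e-12)
  expect_equal(r$t, 3.873, tolerance = 1e-3)
  expect_equal(r$eta_squared, r$t^2 / (r$t^2 + 3))
  expect_true(r$ci95[1] <= r$mean_diff && r$mean_diff <= r$ci95[2])

  expect_error(paired_t(c(5, 5, 5) + 1, c(1, 1, 1)), "degenerate")
  expect_error(paired_t(1:3, 1:4), "paired")

  a <- c(203, 180, 240, 210, 195)
  b <- c(221, 190, 230, 235, 200)
  fwd <- paired_t(a, b)
  rev <- paired_t(b, a)
  expect_equal(fwd$t, -rev$t)
  expect_equal(fwd$p, rev$p)
  expect_equal(fwd$mean_diff, -rev$mean_diff)
})

test_that("OLS recovers exact fits and rejects degenerate designs", {
  fit <- suppressWarnings(linear_regression(c(3, 5, 7, 9), data.frame(x = 1:4)))
  expect_equal(fit$coefficients$estimate, c(1, 2), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)

  X <- data.frame(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10)) # collinear
  expect_error(linear_regression(c(1, 2, 3, 2, 1), X), "collinear.*b")

  expect_error(linear_regression(1:3, data.frame(a = 1:3, b = c(1, 5, 2))),
               "at least")
})

test_that("slope p values are calibrated under the null", {
  withr::with_seed(13, {
    ps <- replicate(300, {
      y <- rnorm(40)
      linear_regression(y, data.frame(x = rnorm(40)))$coefficients$p[2]
    })
  })
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.10)
  expect_gt(mean(ps), 0.42)
  expect_lt(mean(ps), 0.58)
})

test_that("pairwise correlations match hand computation", {
  d <- data.frame(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4), z = c(4, 3, 2, 1))
  ct <- correlation_matrix_fdr(d)
  expect_equal(ct$r["x", "y"], 0.8)
  expect_equal(ct$r["x", "z"], -1)
  expect_true(all(is.na(diag(ct$r))))
  expect_true(all(ct$pairs$p_fdr >= ct$pairs$p, na.rm = TRUE))
  expect_true(all(ct$pairs$p_fdr <= 1, na.rm = TRUE))
})

test_that("FDR adjustment equals the brute-force step-up oracle", {
  # independent step-up recomputation: adj p = cummin over descending ranks
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  withr::with_seed(5, {
    for (i in 1:20) {
      d <- as.data.frame(matrix(rnorm(30 * 6), 30, 6))
      ct <- correlation_matrix_fdr(d)
      expect_equal(ct$pairs$p_fdr, bh_oracle(ct$pairs$p), tolerance = 1e-12)
      # monotone non-decreasing in raw-p rank
      o <- order(ct$pairs$p)
      expect_true(all(diff(ct$pairs$p_fdr[o]) >= -1e-12))
    }
  })
})

test_that("constant variables are flagged missing, not fatal", {
  d <- data.frame(x = c(1, 2, 3, 4, 5), y = c(2, 1, 4, 3, 5), z = 7)
  expect_warning(ct <- correlation_matrix_fdr(d), "constant")
  expect_true(is.na(ct$r["x", "z"]))
  expect_false(is.na(ct$r["x", "y"]))
})

test_that("the report bundle has the published tables' shape", {
  results <- withr::with_seed(9, data.frame(
    id = sprintf("p%02d", 1:46),
    go_rt_systole = rnorm(46, 471, 40), go_rt_diastole = rnorm(46, 474, 40),
    mean_ssd_systole = rnorm(46, 243, 40),
    mean_ssd_diastole = rnorm(46, 227, 40),
    ssrt_systole = rnorm(46, 203, 30), ssrt_diastole = rnorm(46, 221, 30),
    hrv_rmssd = runif(46, 20, 60), bpm = rnorm(46, 58, 10),
    bis_total = round(rnorm(46, 62, 9)), accuracy = runif(46, 0.3, 1),
    awareness = runif(46, -0.5, 0.9), sensibility = runif(46, 1.5, 4.5),
    stringsAsFactors = FALSE
  ))
  rep <- build_reports(results)
  expect_equal(nrow(rep$table1), choose(10, 2)) # 45 variable pairs
  expect_equal(nrow(rep$fig2_means), 6)         # go RT / SSRT / SSD x phase
  expect_setequal(rep$contrasts$measure, c("go_rt", "ssrt", "ssd"))
  expect_true(all(c("sig_uncorrected", "sig_fdr") %in% names(rep$table1)))

  ex <- apply_exclusions(exclusion_fixture())
  rep2 <- build_reports(results, exclusions = ex)
  expect_equal(rep2$exclusion_flow$flow, "60 -> 52 -> 46")
})

test_that("missing upstream fields yield missing cells, not failures", {
  results <- data.frame(
    id = c("a", "b", "c", "d", "e"),
    ssrt_systole = c(200, 210, 190, 220, 205),
    ssrt_diastole = c(220, 230, 215, 240, 221),
    hrv_rmssd = NA_real_, bpm = c(55, 60, 58, 62, 57),
    stringsAsFactors = FALSE
  )
  rep <- build_reports(results)
  expect_true(all(is.na(rep$table1$r[rep$table1$var1 == "HRV" |
                                       rep$table1$var2 == "HRV"])))
  expect_true(is.na(rep$contrasts$t[rep$contrasts$measure == "go_rt"]))
})
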