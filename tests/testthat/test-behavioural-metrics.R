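records_fixture <- function() {
  # four stop-systole trials {S, F, S, F} with SSDs {200, 250, 200, 150},
  # plus a handful of go trials
  data.frame(
    index = 1:8, block = 1,
    trial_type = c(rep("stop_systole", 4), "go_systole", "go_systole",
                   "go_diastole", "go_control_s"),
    ssd_used = c(200, 250, 200, 150, NA, NA, NA, NA),
    go_rt = c(NA, 480, NA, 510, 450, 470, 500, 430),
    responded = c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stop_success = c(TRUE, FALSE, TRUE, FALSE, NA, NA, NA, NA),
    omission = c(NA, NA, NA, NA, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

test_that("condition summaries count, average and pool as specified", {
  cs <- suppressWarnings(condition_summaries(records_fixture(), id = "t"))
  expect_equal(cs$p_respond_systole, 0.5)
  expect_equal(cs$mean_ssd_systole, 200)
  expect_equal(cs$go_rt_systole, 460)     # mean of 450, 470
  expect_equal(cs$go_rt_diastole, 500)
  expect_equal(sort(cs$go_rt_pool), c(430, 450, 470, 500))
  expect_equal(cs$omissions, 0)
  expect_true(is.na(cs$p_respond_diastole)) # no stop-diastole trials

  only_go <- records_fixture()[5:8, ]
  w <- capture_warnings(cs2 <- condition_summaries(only_go))
  expect_match(w, "no stop trials", all = TRUE)
  expect_length(w, 2) # one per phase
  expect_true(is.na(cs2$p_respond_systole))
})

test_that("integration SSRT matches hand-ranked examples", {
  expect_equal(
    ssrt_integration(c(400, 450, 500, 550, 600), 0, p_respond = 0.4,
                     mean_ssd = 200),
    250
  )
  # omissions pooled in at the 1000-ms maximum before ranking
  expect_equal(
    ssrt_integration(c(500, 600, 700), 1, p_respond = 0.75, mean_ssd = 180),
    700 - 180
  )
  # boundary p = 1: top rank, flagged unreliable
  expect_warning(
    v <- ssrt_integration(c(400, 500), 0, p_respond = 1, mean_ssd = 100),
    "unreliable"
  )
  expect_equal(as.numeric(v), 400)
  expect_true(isTRUE(attr(v, "unreliable")))
  expect_warning(
    v0 <- ssrt_integration(c(400, 500), 0, p_respond = 0, mean_ssd = 100),
    "undefined"
  )
  expect_true(is.na(v0))
  expect_error(ssrt_integration(numeric(0), 0, 0.5, 100), "go RT")
})

test_that("integration SSRT equals an independently coded oracle", {
  # oracle: append omissions at 1000, quantile by explicit rank walk
  oracle <- function(go_rts, omissions, p, ssd) {
    pool <- c(go_rts, rep(1000, omissions))
    pool <- pool[order(pool)]
    k <- ceiling(length(pool) * p)
    if (k < 1) k <- 1
    if (k > length(pool)) k <- length(pool)
    pool[k] - ssd
  }
  withr::with_seed(99, {
    for (i in 1:200) {
      n <- sample(3:80, 1)
      rts <- round(runif(n, 250, 990), 1)
      om <- sample(0:4, 1)
      p <- runif(1, 0.05, 0.95)
      ssd <- runif(1, 0, 400)
      expect_identical(
        as.numeric(suppressWarnings(ssrt_integration(rts, om, p, ssd))),
        oracle(rts, om, p, ssd)
      )
    }
  })
})

test_that("the two-pass exclusion filter applies the 2-SD rules in order", {
  # identical participants: zero SD, nothing strictly exceeds it
  same <- data.frame(id = letters[1:5], go_rt_systole = 470,
                     go_rt_diastole = 470, mean_ssd_systole = 240,
                     mean_ssd_diastole = 240, inhib_success_systole = 0.5,
                     inhib_success_diastole = 0.5, stringsAsFactors = FALSE)
  ex <- apply_exclusions(same)
  expect_length(ex$retained, 5)
  expect_equal(nrow(ex$excluded), 0)

  # one waiter at group mean + ~3 SD in go RT: excluded in pass 1
  d <- data.frame(
    id = sprintf("p%02d", 1:20),
    go_rt_systole = c(seq(450, 490, length.out = 19), 700),
    go_rt_diastole = 470, mean_ssd_systole = 240, mean_ssd_diastole = 240,
    inhib_success_systole = 0.5, inhib_success_diastole = 0.5,
    stringsAsFactors = FALSE
  )
  ex <- apply_exclusions(d)
  expect_equal(ex$excluded$id, "p20")
  expect_equal(ex$excluded$pass, 1L)
  expect_match(ex$excluded$reason, "go_rt_systole")

  expect_error(apply_exclusions(same[1:2, ]), "at least 3")
})

test_that("pass-2 statistics never include pass-1 exclusions", {
  # participant B (success 0.75) is >2 SD out only once the pass-1 waiter
  # (success 0.80, go RT 900) has been removed from the statistics
  d <- data.frame(
    id = c(sprintf("n%d", 1:8), "A", "B"),
    go_rt_systole = c(rep(470, 8), 900, 470),
    go_rt_diastole = 470, mean_ssd_systole = 200, mean_ssd_diastole = 200,
    inhib_success_systole = c(rep(0.5, 8), 0.80, 0.75),
    inhib_success_diastole = 0.5,
    stringsAsFactors = FALSE
  )
  ex <- apply_exclusions(d)
  expect_setequal(ex$excluded$id, c("A", "B"))
  expect_equal(ex$excluded$pass[ex$excluded$id == "A"], 1L)
  expect_equal(ex$excluded$pass[ex$excluded$id == "B"], 2L)
  expect_equal(unname(ex$flow), c(10, 9, 8))
})
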