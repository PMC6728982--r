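test_that("2x2 extraction pools active against comparator arms", {
  tab <- fixture_table()
  tt <- extract_two_by_two(tab, "dizziness")
  expect_equal(unlist(tt[c("a", "n1", "c", "n0")]),
    c(a = 20, n1 = 100, c = 5, n0 = 100))
  expect_false(tt$absent)

  doses <- ae_table(data.frame(
    trial_id = "D", arm = c("low", "high", "placebo"), n = c(100, 100, 100),
    is_active = c(1, 1, 0), ae_term = "sedation", count = c(10, 20, 5)
  ))
  td <- extract_two_by_two(doses, "sedation")
  expect_equal(unlist(td[c("a", "n1", "c", "n0")]),
    c(a = 30, n1 = 200, c = 5, n0 = 100))

  ab <- extract_two_by_two(tab, "not-observed")
  expect_true(ab$absent)
  expect_equal(unlist(ab[c("a", "n1", "c", "n0")]),
    c(a = 0, n1 = 100, c = 0, n0 = 100))
})

test_that("the Mantel-Haenszel pooled RR follows its formula", {
  # single stratum reduces to the crude risk ratio
  expect_equal(mh_pooled_rr(data.frame(a = 20, n1 = 100, c = 5, n0 = 100)), 4)
  # invariant under stratum replication
  two <- data.frame(a = c(20, 20), n1 = 100, c = c(5, 5), n0 = 100)
  expect_equal(mh_pooled_rr(two), 4)
  # two unequal strata, evaluated by hand:
  # num = 10*100/200 + 30*200/400 = 20; den = 5*100/200 + 10*200/400 = 7.5
  strata <- data.frame(a = c(10, 30), n1 = c(100, 200),
    c = c(5, 10), n0 = c(100, 200))
  expect_equal(mh_pooled_rr(strata), 20 / 7.5)
  expect_equal(mh_pooled_rr(strata), 8 / 3)
})

test_that("MH agrees with metafor on random strata", {
  skip_if_not_installed("metafor")
  set.seed(77)
  for (i in 1:10) {
    k <- sample(2:6, 1)
    n1 <- sample(50:200, k, replace = TRUE)
    n0 <- sample(50:200, k, replace = TRUE)
    a <- rbinom(k, n1, 0.15)
    c_ <- rbinom(k, n0, 0.08)
    # keep every cell positive so metafor applies no corrections
    a <- pmax(a, 1)
    c_ <- pmax(c_, 1)
    ours <- mh_pooled_rr(data.frame(a = a, n1 = n1, c = c_, n0 = n0))
    mf <- metafor::rma.mh(ai = a, bi = n1 - a, ci = c_, di = n0 - c_,
      measure = "RR", correct = FALSE, add = 0, to = "none")
    expect_equal(ours, exp(as.numeric(mf$beta)), tolerance = 1e-10)
  }
})

test_that("MH sanity: common per-stratum RR is recovered exactly", {
  strata <- data.frame(
    a = c(10, 20, 40), n1 = c(100, 100, 200),
    c = c(5, 10, 20), n0 = c(100, 100, 200)
  )
  expect_equal(mh_pooled_rr(strata), 2, tolerance = 1e-12)
})

test_that("undefined and degenerate MH inputs are flagged", {
  expect_true(is.na(mh_pooled_rr(data.frame(a = 0, n1 = 50, c = 0, n0 = 50))))
  expect_identical(mh_pooled_rr(data.frame(a = 3, n1 = 50, c = 0, n0 = 50)), Inf)
  expect_error(
    mh_pooled_rr(data.frame(a = numeric(0), n1 = numeric(0),
      c = numeric(0), n0 = numeric(0))),
    "at least one", class = "aeselect_validation_error")
  expect_error(mh_pooled_rr(data.frame(a = 60, n1 = 50, c = 0, n0 = 50)),
    "invalid", class = "aeselect_validation_error")
})

test_that("reporting censorship keeps exactly the passing terms", {
  tab <- fixture_table()
  # a zero threshold censors nothing
  expect_identical(simulate_reporting(tab, "thr=0%")[[1]]$counts, tab$counts)
  # the worked example: >= 5% in any arm keeps dizziness and headache
  cens <- simulate_reporting(tab, "thr=5%;scope=any;diff=none")[[1]]
  expect_setequal(ae_terms(cens), c("dizziness", "headache"))
  expect_identical(cens$arms, tab$arms)
  # a 100% threshold keeps only terms with a fully affected arm
  full <- ae_table(data.frame(
    trial_id = "F", arm = rep(c("a", "p"), each = 2), n = 10,
    is_active = rep(c(1, 0), each = 2), ae_term = rep(c("total", "partial"), 2),
    count = c(10, 3, 2, 1)
  ))
  expect_identical(ae_terms(simulate_reporting(full, "thr=100%")[[1]]), "total")
})

test_that("no selection means no selective-vs-complete discrepancy, exactly", {
  cfg <- synthetic_config(n_per_arm = c(100, 100), n_terms = 40)
  res <- bias_experiment(cfg, k_trials = 5, criteria = list("thr=0%"),
    reps = 5, master_seed = 31)
  expect_equal(res$reps$max_discrepancy, rep(0, 5))
  expect_equal(res$summary$max_discrepancy, 0)
})

test_that("rare-AE visibility matches the analytic binomial tail", {
  # one latent incidence level; a term passes "thr=1%, any arm" in a
  # trial when either arm reaches ceiling(0.01 * n) affected participants
  n <- 200
  p0 <- 0.001
  rr <- 3
  cfg <- synthetic_config(n_per_arm = c(n, n), n_terms = 200,
    background_rate_law = log_uniform(p0, p0),
    elevated_fraction = 1, risk_ratio = rr)
  k <- 20
  reps <- 30
  crit <- "thr=1%;scope=any;diff=none"
  hits <- numeric(0)
  for (r in seq_len(reps)) {
    tabs <- simulate_trials(cfg, k, 600 + r)
    cens <- simulate_reporting(tabs, crit)
    reported <- lapply(cens, ae_terms)
    n_reported <- length(unique(unlist(reported)))
    hits <- c(hits, n_reported / 200)
  }
  # per arm, P(count >= 2) with 2 = smallest count making 1% of 200
  q_arm_active <- 1 - stats::pbinom(1, n, rr * p0)
  q_arm_comp <- 1 - stats::pbinom(1, n, p0)
  q_trial <- 1 - (1 - q_arm_active) * (1 - q_arm_comp)
  p_ever <- 1 - (1 - q_trial)^k
  mc_se <- sqrt(p_ever * (1 - p_ever) / (200 * reps))
  expect_lt(abs(mean(hits) - p_ever), 4 * mc_se)
})

test_that("the never-reported fraction rises with the threshold", {
  cfg <- synthetic_config(n_per_arm = c(150, 150), n_terms = 100,
    background_rate_law = log_uniform(1e-3, 0.15))
  crits <- sprintf("thr=%d%%;scope=any;diff=none", c(0, 1, 3, 5, 10))
  res <- bias_experiment(cfg, k_trials = 8, criteria = crits,
    reps = 20, master_seed = 41)
  fr <- res$summary$frac_never_reported[match(crits, res$summary$criterion)]
  expect_true(all(diff(fr) >= 0))
})

test_that("difference-rule criteria inflate the selective estimate under the null", {
  # with no true arm difference, conditioning reporting on "higher in
  # active" selects positive noise: the mean selective pooled log-RR is
  # positive
  cfg <- synthetic_config(n_per_arm = c(100, 100), n_terms = 60,
    background_rate_law = log_uniform(0.01, 0.2),
    elevated_fraction = 0, risk_ratio = 1)
  res <- bias_experiment(cfg, k_trials = 10,
    criteria = list("thr=5%;scope=active;diff=higher",
      "thr=5%;scope=active;diff=ratio>=2"),
    reps = 60, master_seed = 53)
  for (lab in unique(res$reps$criterion)) {
    x <- res$reps$mean_selective_log_rr[res$reps$criterion == lab]
    x <- x[is.finite(x)]
    tt <- stats::t.test(x, alternative = "greater")
    expect_lt(tt$p.value, 0.01)
  }
})

test_that("bias_result accessors expose tidy summaries", {
  cfg <- synthetic_config(n_per_arm = c(80, 80), n_terms = 25)
  res <- bias_experiment(cfg, 3, list("thr=0%", "thr=5%"), 3, 8)
  td <- tidy(res)
  expect_equal(nrow(td), 2)
  expect_true(all(c("mean_bias", "frac_elevated_reported",
    "frac_never_reported") %in% names(td)))
  expect_true(all(td$frac_never_reported >= 0 & td$frac_never_reported <= 1))
  gl <- glance(res)
  expect_equal(gl$reps, 3)
  expect_equal(gl$n_trials, 3)
  expect_s3_class(autoplot(res), "ggplot")
  # per-term records only define selective estimates where reported
  tm <- res$terms
  expect_true(all(is.na(tm$log_rr_selective[tm$n_trials_reporting == 0])))
})
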