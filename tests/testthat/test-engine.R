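test_that("proportions pool arms as stated", {
  tab <- fixture_table()
  expect_equal(ae_proportion(tab, "dizziness", "drug"), 0.20)
  expect_equal(ae_proportion(tab, "dizziness", "all"), 25 / 200)
  expect_error(ae_proportion(tab, "unicorn", "drug"), "unknown AE term",
    class = "aeselect_validation_error")
  expect_error(ae_proportion(tab, "dizziness", "armX"), "unknown arm",
    class = "aeselect_validation_error")

  # pooled active across two dose arms: 10/100 + 20/100 -> 30/200
  doses <- ae_table(data.frame(
    trial_id = "D", arm = rep(c("low", "high", "placebo"), each = 1),
    n = 100, is_active = c(1, 1, 0), ae_term = "sedation",
    count = c(10, 20, 5)
  ))
  expect_equal(ae_proportion(doses, "sedation", "active"), 30 / 200)
})

test_that("single-term pass/fail matches hand evaluation", {
  tab <- fixture_table()
  # 0.20 >= 0.05
  expect_true(passes_criterion(tab, "dizziness", "thr=5%;scope=any;diff=none"))
  # ratio 6/100 vs 6/100 is 1 < 2
  expect_false(passes_criterion(tab, "headache", "thr=5%;scope=active;diff=ratio>=2"))
  # active > 0 against comparator 0 passes the ratio clause
  zc <- ae_table(data.frame(
    trial_id = "Z", arm = c("a", "p"), n = 100, is_active = c(1, 0),
    ae_term = "x", count = c(12, 0)
  ))
  expect_true(passes_criterion(zc, "x", "thr=10%;scope=active;diff=ratio>=2"))
  # 0 vs 0 fails the ratio clause: make the term exist via the other arm
  both <- ae_table(data.frame(
    trial_id = "Z2", arm = rep(c("a", "p"), each = 2), n = 100,
    is_active = rep(c(1, 0), each = 2), ae_term = rep(c("x", "y"), 2),
    count = c(0, 5, 3, 5)
  ))
  # term y: active 5, comparator 5 -> ratio 1 fails; term x: active 0 vs 3
  expect_false(passes_criterion(both, "x", "thr=0%;scope=any;diff=ratio>=2"))
})

test_that("applying a criterion reports the hand-derived sets", {
  tab <- fixture_table()
  rs <- apply_criterion(tab, "thr=5%;scope=any;diff=none")
  expect_identical(rs$terms, c("dizziness", "headache"))
  expect_equal(rs$percent_reported, 50)
  expect_equal(rs$n_total_terms, 4)

  rs0 <- apply_criterion(tab, "thr=0%;scope=any;diff=none")
  expect_length(rs0$terms, 4)
  expect_equal(rs0$percent_reported, 100)

  rs2 <- apply_criterion(tab, "thr=5%;scope=active;diff=ratio>=2")
  expect_identical(rs2$terms, "dizziness")
  expect_equal(rs2$percent_reported, 25)

  td <- tidy(rs)
  expect_equal(td$n_reported, 2)
  expect_equal(td$percent_reported, 50)
})

test_that("threshold comparisons are exact at the boundary", {
  # 2/100 is exactly 2%: inclusive >= passes, strict > does not
  tab <- ae_table(data.frame(
    trial_id = "B", arm = c("a", "p"), n = 100, is_active = c(1, 0),
    ae_term = "x", count = c(2, 0)
  ))
  expect_true(passes_criterion(tab, "x", "thr=2%;scope=active"))
  expect_false(passes_criterion(tab, "x", "thr=2%;scope=active", strict = TRUE))
  # 3% of 30 is 0.9 participants; 1/30 = 3.33% passes, 0 fails (absent)
  odd <- ae_table(data.frame(
    trial_id = "B2", arm = c("a", "p"), n = 30, is_active = c(1, 0),
    ae_term = "x", count = c(1, 0)
  ))
  expect_true(passes_criterion(odd, "x", "thr=3%;scope=active"))
})

test_that("rounded-percents mode thresholds rounded table values", {
  # 15/1000 = 1.5% rounds (half-up) to 2%: passes thr=2 only when rounding
  tab <- ae_table(data.frame(
    trial_id = "R", arm = c("a", "p"), n = 1000, is_active = c(1, 0),
    ae_term = "x", count = c(15, 0)
  ))
  expect_false(passes_criterion(tab, "x", "thr=2%;scope=active"))
  expect_true(passes_criterion(tab, "x", "thr=2%;scope=active",
    rounded_percents = TRUE))
})

test_that("the heat map composes apply_criterion deterministically", {
  tab <- fixture_table()
  g1 <- build_grid(0.05, "any", "none")
  hm <- criteria_heatmap(tab, g1)
  expect_equal(nrow(hm), 1)
  expect_equal(hm$percent_reported, 50)

  # boundary thresholds: 0% reports everything stored, 100% needs a
  # fully-affected arm (none in the fixture)
  gb <- build_grid(c(0, 1), "any", "none")
  hmb <- criteria_heatmap(tab, gb)
  expect_equal(hmb$percent_reported, c(100, 0))

  # identical data in two trials gives identical columns
  df2 <- tibble::as_tibble(tab)
  df2$trial_id <- "fix-2"
  hm2 <- criteria_heatmap(list(tab, ae_table(df2)), build_grid(observed_components()))
  wide <- heatmap_matrix(hm2)
  expect_equal(wide[["fix-1"]], wide[["fix-2"]])
  expect_equal(nrow(wide), 45)
  expect_true(all(hm2$percent_reported >= 0 & hm2$percent_reported <= 100))

  # annotations are carried through to the cells
  ann <- data.frame(label = "thr=5%;scope=any;diff=none", trial_id = "fix-1")
  hma <- criteria_heatmap(tab, build_grid(observed_components()), annotations = ann)
  expect_equal(sum(hma$annotated), 1)
  expect_s3_class(autoplot(hma), "ggplot")
})

test_that("heat-map cells weakly decrease as the threshold rises", {
  set.seed(401)
  grid <- build_grid(observed_components())
  for (i in 1:20) {
    tab <- random_table(paste0("hm", i))
    hm <- criteria_heatmap(tab, grid)
    cells <- dplyr::bind_cols(grid[c("threshold", "scope", "diff", "ratio")],
      percent = hm$percent_reported)
    for (grp in split(cells, list(cells$scope, cells$diff), drop = TRUE)) {
      grp <- grp[order(grp$threshold), ]
      expect_true(all(diff(grp$percent) <= 1e-12))
    }
  }
})

test_that("monotonicity, scope nesting, and difference-rule shrinkage hold", {
  set.seed(402)
  diffs <- c("none", "higher", "ratio>=2")
  for (i in 1:30) {
    tab <- random_table(paste0("pt", i))
    for (d in diffs) {
      for (sc in c("any", "active", "all")) {
        t_lo <- apply_criterion(tab, sprintf("thr=1%%;scope=%s;diff=%s", sc, d))
        t_hi <- apply_criterion(tab, sprintf("thr=5%%;scope=%s;diff=%s", sc, d))
        expect_true(all(t_hi$terms %in% t_lo$terms))
      }
      any_terms <- apply_criterion(tab, sprintf("thr=2%%;scope=any;diff=%s", d))$terms
      for (sc in c("active", "all")) {
        sub <- apply_criterion(tab, sprintf("thr=2%%;scope=%s;diff=%s", sc, d))$terms
        expect_true(all(sub %in% any_terms))
      }
    }
    for (sc in c("any", "active", "all")) {
      none <- apply_criterion(tab, sprintf("thr=2%%;scope=%s;diff=none", sc))$terms
      for (d in c("higher", "ratio>=2")) {
        shrunk <- apply_criterion(tab, sprintf("thr=2%%;scope=%s;diff=%s", sc, d))$terms
        expect_true(all(shrunk %in% none))
      }
    }
  }
})

test_that("discrepancy checking splits terms by the stated criterion", {
  tab <- fixture_table()
  crit <- "thr=5%;scope=any;diff=none"
  # reported exactly the criterion's set: nothing to flag
  ok <- check_discrepancies(tab, c("dizziness", "headache"), crit)
  expect_length(ok$under_reported, 0)
  expect_length(ok$over_included, 0)

  # a source omitting dizziness under-reports it
  miss <- check_discrepancies(tab, "headache", crit)
  expect_identical(miss$under_reported, "dizziness")
  expect_length(miss$over_included, 0)

  # unknown reported terms are flagged, not fatal
  unk <- check_discrepancies(tab, c("headache", "insomnia"), crit)
  expect_identical(unk$under_reported, "dizziness")
  expect_identical(unk$over_included, "insomnia")
  expect_identical(unk$unknown, "insomnia")
  expect_length(intersect(unk$under_reported, unk$over_included), 0)

  # matching is case/whitespace-insensitive
  ci <- check_discrepancies(tab, c("Dizziness ", "HEADACHE"), crit)
  expect_length(ci$under_reported, 0)
  expect_length(ci$over_included, 0)

  td <- tidy(unk)
  expect_setequal(td$issue, c("under_reported", "over_included"))
})

test_that("the engine matches the brute-force oracle on random tables", {
  set.seed(403)
  grid <- build_grid(observed_components())
  for (i in 1:25) {
    tab <- random_table(paste0("or", i))
    for (cr in grid$criterion) {
      expect_identical(
        apply_criterion(tab, cr)$terms,
        oracle_reported_terms(tab, cr),
        info = sprintf("table %d, criterion %s", i, cr$label)
      )
    }
  }
})
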