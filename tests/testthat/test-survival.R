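test_that("risk rule reproduces the printed risk column", {
  expect_equal(assign_risk(1266, "PR"), "low")
  expect_equal(assign_risk(1456, "PD"), "high")
  expect_equal(assign_risk(243, "PR"), "high")
  tab <- table1_fixture()
  expect_equal(assign_risk(tab$os_days, tab$response), tab$risk)
  expect_error(assign_risk(100, "XX"), "response")
  expect_error(assign_risk(0, "PR"), "positive")
})

test_that("Kaplan-Meier estimator matches hand and brute-force values", {
  km <- km_curve(c(1, 2, 3, 4), c(TRUE, TRUE, TRUE, TRUE))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median, 2)

  kc <- km_curve(c(5, 6, 7), c(FALSE, FALSE, FALSE))
  expect_true(all(kc$surv == 1))
  expect_true(is.na(kc$median))

  # times {2, 4+, 6, 8+, 10}
  km2 <- km_curve(c(2, 4, 6, 8, 10), c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(km2$surv[km2$time == 2], 0.8)
  expect_equal(km2$surv[km2$time == 6], 0.8 * (1 - 1 / 3),
               tolerance = 1e-12)
  expect_equal(km2$surv[km2$time == 10], 0)
  expect_equal(km2$median, 10)

  # property: agrees with an independent product-limit loop
  set.seed(11)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    times <- sample(1:60, n, replace = TRUE)
    events <- runif(n) < 0.7
    if (!any(events)) events[1] <- TRUE
    km <- km_curve(times, events)
    bf <- brute_force_km(times, events)
    expect_equal(km$surv[match(bf$time, km$time)], bf$surv,
                 tolerance = 1e-12)
  }
  expect_error(km_curve(numeric(0), logical(0)), "empty")
})

test_that("marker dichotomization equals exhaustive constrained search", {
  v <- c(1:10, 101:110)
  d <- dichotomize_marker(v, min_group = 10)
  expect_gt(d$threshold, 10); expect_lt(d$threshold, 101)
  expect_equal(d$n1, 10)

  # exhaustive oracle on random instances with an independent BSS formula
  set.seed(21)
  for (i in 1:25) {
    n <- sample(25:200, 1)
    x <- round(rnorm(n, 50, sample(c(1, 10, 30), 1)), 1)
    res <- tryCatch(dichotomize_marker(x, min_group = 10),
                    error = function(e) NULL)
    s <- sort(x)
    best_bss <- -Inf; tot <- sum((x - mean(x))^2)
    for (k in 10:(n - 10)) {
      if (s[k] == s[k + 1]) next
      wss <- sum((s[1:k] - mean(s[1:k]))^2) +
             sum((s[(k + 1):n] - mean(s[(k + 1):n]))^2)
      best_bss <- max(best_bss, tot - wss)
    }
    if (is.null(res)) {
      expect_true(!is.finite(best_bss))
    } else {
      expect_equal(res$bss, best_bss, tolerance = 1e-8)
      expect_gte(min(res$n1, res$n2), 10)
    }
  }
  expect_error(dichotomize_marker(rep(1, 40)), "cut")
  expect_error(dichotomize_marker(1:10), "at least")
})

test_that("Gehan-Wilcoxon test is symmetric, calibrated, and powered", {
  t1 <- c(5, 10, 15, 20); e1 <- c(TRUE, TRUE, FALSE, TRUE)
  same <- gehan_wilcoxon_test(t1, e1, t1, e1)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)

  none <- gehan_wilcoxon_test(c(1, 2), c(FALSE, FALSE), c(3, 4),
                              c(FALSE, FALSE))
  expect_true(none$no_events)
  expect_equal(none$p, 1)

  # chi-square p close to a label-permutation p on a 20-patient example
  set.seed(31)
  ta <- rexp(10, 1 / 300); tb <- rexp(10, 1 / 80)
  ea <- rep(TRUE, 10); eb <- rep(TRUE, 10)
  res <- gehan_wilcoxon_test(ta, ea, tb, eb, permutations = 2000,
                             seed = 9)
  expect_lt(abs(res$p - res$p_perm), 0.03)

  # power: hazard ratio 5 separations detected in most seeds
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    g1 <- rexp(20, 1 / 500); g2 <- rexp(20, 5 / 500)
    r <- gehan_wilcoxon_test(g1, rep(TRUE, 20), g2, rep(TRUE, 20))
    if (r$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("Welch t-test matches its closed form", {
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  x1 <- c(1, 2, 3, 4); x2 <- c(5, 6, 7, 8)
  r <- welch_t_test(x1, x2)
  se <- sqrt(var(x1) / 4 + var(x2) / 4)
  expect_equal(r$statistic, (mean(x1) - mean(x2)) / se, tolerance = 1e-12)
  expect_lt(welch_t_test(x1, x1 + 100)$p, 1e-6)
  deg <- welch_t_test(c(2, 2), c(2, 2))
  expect_true(deg$degenerate)
})

test_that("Holm-Bonferroni step-down matches hand computation", {
  expect_equal(holm_bonferroni(c(0.01, 0.04, 0.03)),
               c(TRUE, FALSE, FALSE))
  expect_equal(holm_bonferroni(rep(1, 5)), rep(FALSE, 5))
  expect_true(holm_bonferroni(0.04))
  expect_error(holm_bonferroni(c(0.1, 1.2)), "0, 1")

  # Bonferroni subset; unadjusted superset (random p-vectors)
  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(3:12, 1))^2
    holm <- holm_bonferroni(p)
    bonf <- p <= 0.05 / length(p)
    raw <- p <= 0.05
    expect_true(all(!bonf | holm))  # bonf => holm
    expect_true(all(!holm | raw))   # holm => raw
    expect_equal(holm, p.adjust(p, "holm") <= 0.05)
  }
})

test_that("marker screen plants and protects as designed", {
  # planted TMTV-hazard link is recovered after Holm in most seeds
  hits <- 0
  for (s in 1:10) {
    d <- simulate_features(n = 60, planted = "tmtv", seed = s)
    res <- marker_screen(d$features, d$outcomes)
    row <- res[res$marker == "tmtv_ml", ]
    if (nrow(row) == 1 && isTRUE(row$os_reject)) hits <- hits + 1
  }
  expect_gte(hits, 8)

  # degenerate indicators are skipped
  d <- simulate_features(n = 40, seed = 3)
  d$features$organ_pleura <- c(TRUE, rep(FALSE, 39))
  res <- marker_screen(d$features, d$outcomes)
  expect_true("organ_pleura" %in% attr(res, "skipped"))
  expect_false("organ_pleura" %in% res$marker)
})
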