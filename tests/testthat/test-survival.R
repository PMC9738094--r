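test_that("median split sends ties low and flags degenerate inputs", {
  sp <- median_split(c(1, 2, 3, 4), ids = letters[1:4])
  expect_equal(names(sp$group[sp$group == "high"]), c("c", "d"))
  expect_false(sp$degenerate)
  expect_true(median_split(rep(2, 5))$degenerate)
  sp3 <- median_split(c(1, 2, 3))           # odd n: the median value goes low
  expect_equal(as.character(sp3$group), c("low", "low", "high"))
  expect_error(median_split(1), "at least 2")
})

test_that("KM estimator matches the hand product-limit on fixtures", {
  km0 <- km_curve(c(5, 6, 7), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  km1 <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km1$surv, c(2 / 3, 1 / 3, 0))
  # censoring at t = 2 between events at 1 and 3
  km2 <- km_curve(c(1, 2, 3), c(1, 0, 1))
  o2 <- oracle_km(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$surv[km2$n_event > 0], o2$surv)
  expect_equal(o2$surv, c(2 / 3, 0))
  expect_error(km_curve(numeric(0), numeric(0)), "empty")
  # non-increasing; with no censoring equals the empirical survival function
  set.seed(41)
  t <- rexp(40)
  km3 <- km_curve(t, rep(1, 40))
  expect_true(all(diff(km3$surv) <= 1e-12))
  expect_equal(km3$surv, 1 - ecdf(t)(km3$time))
})

test_that("log-rank matches the hand O-E table and is label-symmetric", {
  times <- c(1, 2, 3, 4)
  events <- c(1, 1, 1, 1)
  group <- c("A", "A", "B", "B")
  lr <- logrank_test(times, events, group)
  expect_equal(lr$statistic, 49 / 17, tolerance = 1e-9)   # approx 2.882
  expect_equal(lr$p, pchisq(49 / 17, 1, lower.tail = FALSE))
  expect_equal(lr$p, 0.0895, tolerance = 1e-3)
  o <- oracle_logrank(times, events, group)
  expect_equal(lr$statistic, o$statistic, tolerance = 1e-9)
  swapped <- logrank_test(times, events, rev(group))
  expect_equal(swapped$statistic, lr$statistic)
  # identical groups: statistic 0, p = 1
  lr0 <- logrank_test(c(1, 2, 1, 2), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)
  # no events anywhere: undefined
  expect_true(is.na(logrank_test(c(1, 2), c(0, 0), c("A", "B"))$p))
})

test_that("log-rank agrees with the hand oracle on random small instances", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(6:10, 1)
    times <- sample(1:20, n)
    events <- rbinom(n, 1, 0.8)
    group <- sample(rep(c("A", "B"), length.out = n))
    if (sum(events) == 0 || length(unique(group)) < 2) next
    o <- oracle_logrank(times, events, group)
    if (!is.finite(o$statistic)) next
    lr <- logrank_test(times, events, group)
    expect_equal(lr$statistic, o$statistic, tolerance = 1e-9)
  }
})

test_that("hazard ratio from O/E matches the hand fixture", {
  times <- c(1, 2, 3, 4)
  events <- c(1, 1, 1, 1)
  group <- factor(c("A", "A", "B", "B"))
  hr <- hazard_ratio(times, events, group, numerator = "A")
  expect_equal(hr$hr, 3.8, tolerance = 1e-9)   # (2/(5/6))/(2/(19/6)) = 19/5
  expect_true(hr$lower < hr$hr && hr$hr < hr$upper)
  hr1 <- hazard_ratio(c(1, 2, 1, 2), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(hr1$hr, 1, tolerance = 1e-9)
})

test_that("HR estimate and CI coverage recover a true exponential HR of 2", {
  set.seed(43)
  n_seeds <- 200
  ok_est <- logical(n_seeds)
  covered <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    n <- 300
    t1 <- rexp(n, rate = 2 / 1000)   # numerator group, HR 2
    t2 <- rexp(n, rate = 1 / 1000)
    cens <- runif(2 * n, 0, 3000)
    times <- pmin(c(t1, t2), cens)
    events <- as.integer(c(t1, t2) <= cens)
    group <- rep(c("H", "L"), each = n)
    hr <- hazard_ratio(times, events, group, numerator = "H")
    ok_est[s] <- abs(hr$hr - 2) / 2 <= 0.3
    covered[s] <- hr$lower <= 2 && 2 <= hr$upper
  }
  expect_gte(mean(ok_est), 0.95)
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("the prognostic screen flags planted hazards and counts risky genes", {
  panel <- load_default_panel()
  hz <- matrix(1, nrow(panel), 1, dimnames = list(panel$symbol, "A"))
  hz["ATM", "A"] <- 3
  flagged <- logical(20)
  for (s in seq_len(20)) {
    design <- simulation_design(
      cancer_types = "A", n_tumor = 200L, reference_types = c("A", "A"),
      panel = panel, plp_freq = 0, homdel_freq = 0, meth_beta = 0.2,
      expr_shift = 0, hazard = hz, seed = 500L + s, background_mut_rate = 0
    )
    b <- generate_cohort(design)$bundle
    scr <- suppressMessages(prognostic_screen(b$expression, b$clinical,
                                              b$samples, panel))
    row <- scr$results[scr$results$gene == "ATM", ]
    flagged[s] <- is.finite(row$p) && row$p < 0.05 && row$hr > 1
    if (s == 1) {
      expect_equal(row$direction, "risky")
      expect_gte(scr$risky_counts$n_risky[1], 1L)
    }
  }
  expect_gte(mean(flagged), 0.95)
})

test_that("hierarchical stratification recovers well-separated groups", {
  set.seed(44)
  panel <- load_default_panel()
  n <- 40
  expr <- matrix(rnorm(42 * n, 8, 0.3), 42, n,
                 dimnames = list(panel$symbol,
                                 c(sprintf("LO%02d", 1:20),
                                   sprintf("HI%02d", 1:20))))
  expr[, 21:40] <- expr[, 21:40] + 3
  st <- stratify_patients(expr, panel, k = 2)
  expect_equal(unname(st$groups[sprintf("LO%02d", 1:20)]),
               factor(rep("lower", 20), levels = c("lower", "higher")),
               ignore_attr = TRUE)
  expect_equal(as.integer(st$sizes), c(20L, 20L))
  expect_gt(st$separation, 2)
  # a duplicated sample always lands with its twin
  expr2 <- cbind(expr, DUP01 = expr[, "LO01"])
  st2 <- stratify_patients(expr2, panel, k = 2)
  expect_equal(st2$groups[["DUP01"]], st2$groups[["LO01"]])
  # one tight blob: groups still returned, separation near 1
  blob <- matrix(rnorm(42 * 30, 8, 0.3), 42, 30,
                 dimnames = list(panel$symbol, sprintf("S%02d", 1:30)))
  st3 <- stratify_patients(blob, panel, k = 2)
  expect_lt(st3$separation, 1.8)
  expect_error(stratify_patients(blob, panel, k = 31), "exceeds")
})

test_that("null cohorts give calibrated log-rank false-positive rates", {
  # 42 genes x 24 types = 1008 gene-cancer pairs under the null
  design <- null_design(n_types = 24L, n_per_type = 100L, seed = 77L,
                        n_normal = 0L)
  b <- generate_cohort(design)$bundle
  scr <- suppressMessages(prognostic_screen(b$expression, b$clinical,
                                            b$samples, b$panel))
  expect_gte(nrow(scr$results), 1000)
  frac <- mean(scr$results$p < 0.05, na.rm = TRUE)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})
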