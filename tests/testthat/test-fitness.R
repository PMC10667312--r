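test_that("growth recovery rate implements the colony-size formula", {
  a <- rep(1.8, 200); b <- rep(1.2, 200)
  expect_equal(suppressWarnings(growthRecoveryRate(b, b))$valuePct, 0)
  expect_equal(growthRecoveryRate(a, b)$valuePct, 50)
  expect_equal(growthRecoveryRate(rep(0.9, 200), b)$valuePct, -25)
  # scale invariance
  expect_equal(growthRecoveryRate(3 * a, 3 * b)$valuePct, 50)
  expect_warning(growthRecoveryRate(a[1:50], b), "200")
  expect_error(growthRecoveryRate(numeric(0), b), "nonempty")
})

test_that("doubling time is exact on pure exponentials", {
  t <- seq(0, 2880, by = 20)
  curve <- data.frame(time_min = t, od600 = 0.01 * 2^(t / 120))
  dt <- doublingTime(curve)
  expect_equal(dt$dtMin, 120, tolerance = 1e-10)
  expect_equal(dt$k, log10(2) / 120, tolerance = 1e-12)
  # window position does not matter: prepend a flat lag phase
  lag <- data.frame(time_min = seq(-400, -20, by = 20), od600 = 0.01)
  curve2 <- rbind(lag, curve)
  curve2$time_min <- curve2$time_min + 400
  expect_equal(doublingTime(curve2)$dtMin, 120, tolerance = 1e-10)
  expect_error(doublingTime(data.frame(time_min = t,
                                       od600 = rep(0.3, length(t)))),
               "growth")
  expect_error(doublingTime(curve[1:5, ]), "readings")
})

test_that("noisy logistic curves estimate DT within 5 percent usually", {
  # the max-over-windows rule picks the most extreme noisy slope, a small
  # upward bias; at 2 percent multiplicative noise about 93 percent of
  # estimates land within 5 percent of truth
  ok <- vapply(1:200, function(i) {
    gc <- simulateGrowthCurve(100, noiseSd = 0.02, seed = 6000 + i)
    abs(doublingTime(gc)$dtMin - 100) / 100 < 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.88)
  # and the median estimate is close to unbiased
  est <- vapply(1:50, function(i)
    doublingTime(simulateGrowthCurve(100, noiseSd = 0.02,
                                     seed = 6000 + i))$dtMin, numeric(1))
  expect_lt(abs(median(est) - 100) / 100, 0.03)
})

test_that("retention-recovery regression reports r, fit and band", {
  mk <- function(ret, rec) new("StrainRecord", strainId = "s",
                               structure = word("A"), events = list(),
                               retainedFraction = ret,
                               recoveryRatePct = rec,
                               colonySizesMm = numeric(0),
                               trisomyFlag = FALSE, conditionLabel = "YPD")
  ret <- seq(0.1, 0.9, length.out = 20)
  exact <- lapply(seq_along(ret), function(i) mk(ret[i], 80 - 60 * ret[i]))
  fit <- retentionRecoveryRegression(exact)
  expect_equal(fit$r, -1)
  expect_equal(fit$slope, -60)
  expect_true(all(c("lwr", "upr") %in% names(fit$band)))
  # permuted labels destroy the association
  set.seed(4)
  shuffled <- sample(80 - 60 * ret)
  perm <- lapply(seq_along(ret), function(i) mk(ret[i], shuffled[i]))
  expect_lt(abs(retentionRecoveryRegression(perm)$r), 0.6)
  expect_error(retentionRecoveryRegression(exact[1:2]), "3")
})

test_that("association scan handles contrasts, flags and monotonicity", {
  set.seed(12)
  n <- 60
  del <- cbind(seg1 = rbinom(n, 1, 0.4), seg2 = rbinom(n, 1, 0.5),
               allDel = rep(1L, n), noneDel = rep(0L, n))
  rec <- rnorm(n, 30, 8) + 25 * del[, "seg1"]
  sc <- associationScan(del, rec)
  expect_equal(sc$reason[sc$segment == "allDel"], "no contrast")
  expect_equal(sc$reason[sc$segment == "noneDel"], "no contrast")
  expect_equal(sc$segment[which.min(sc$p)], "seg1")
  expect_true(sc$pass[sc$segment == "seg1"])
  # Bonferroni monotone in alpha
  scLoose <- associationScan(del, rec, alpha = 0.2)
  expect_true(all(scLoose$pass[sc$pass]))
})

test_that("permutation and analytic p agree on a small toy", {
  set.seed(9)
  n <- 20
  del <- cbind(s1 = rbinom(n, 1, 0.5), s2 = rbinom(n, 1, 0.5))
  rec <- rnorm(n, 30, 10) + 14 * del[, "s1"]
  w <- associationScan(del, rec, method = "welch")
  p <- associationScan(del, rec, method = "permutation", nPerm = 4000,
                       seed = 1)
  expect_true(all(abs(w$p - p$p) < 0.02, na.rm = TRUE))
})

test_that("stability generations: closed form and Monte Carlo agree", {
  expect_equal(stabilityGenerations(0, 0.5)$generations, Inf)
  p <- 1 - 0.5^(1 / 160)
  expect_equal(p, 0.00432, tolerance = 2e-3)
  st <- stabilityGenerations(p, 0.5, nLineages = 10000, seed = 21)
  expect_equal(st$generations, 160, tolerance = 1e-9)
  expect_lt(abs(st$mcGenerations - 160) / 160, 0.05)
})
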