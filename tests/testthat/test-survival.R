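test_that("univariate Cox matches a brute-force partial-likelihood oracle on a toy", {
  surv <- survTable(time = c(2.1, 3.4, 1.2, 5.5, 4.3, 0.8, 6.1, 2.9, 3.8, 7.2),
                    event = c(1, 0, 1, 1, 0, 1, 1, 0, 1, 1))
  x <- c(0.3, -1.2, 0.8, -0.4, 1.5, 2.0, -0.9, 0.1, 0.6, -1.8)
  negLogPL <- function(beta) {     # Breslow form, no ties in these times
    s <- 0
    for (i in which(surv$event == 1)) {
      risk <- surv$time >= surv$time[i]
      s <- s - (beta * x[i] - log(sum(exp(beta * x[risk]))))
    }
    s
  }
  oracle <- stats::optimize(negLogPL, c(-5, 5), tol = 1e-10)$minimum
  fit <- coxUnivariate(x, surv, standardize = FALSE)
  expect_equal(fit$beta, oracle, tolerance = 1e-6)
  expect_equal(fit$hr, exp(fit$beta))
  expect_lte(fit$ci95[1], fit$hr)
  expect_gte(fit$ci95[2], fit$hr)

  expect_error(coxUnivariate(rep(1, 10), surv), "constant")
  expect_error(coxUnivariate(x, survTable(surv$time, rep(0, 10))), "events")
})

test_that("null Cox p-values are uniform and planted effects are recovered", {
  f <- withr::with_seed(20, stats::rnorm(500))
  ps <- vapply(1:50, function(sd) {
    s <- generateSurvival(f, beta = 0, censorRate = 0.3, seed = sd)
    coxUnivariate(f, s)$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  betas <- vapply(1:10, function(sd) {
    s <- generateSurvival(f, beta = 0, censorRate = 0.3, seed = 100 + sd)
    coxUnivariate(f, s)$beta
  }, numeric(1))
  expect_true(all(abs(betas) <= 0.16))

  s7 <- generateSurvival(f, beta = 0.7, censorRate = 0.3, seed = 7)
  expect_lt(abs(coxUnivariate(f, s7)$beta - 0.7), 0.15)
})

test_that("multivariate Cox prunes correlated features greedily by univariate p", {
  surv <- generateSurvival(withr::with_seed(21, stats::rnorm(120)),
                           beta = 0, censorRate = 0.2, seed = 21)
  base <- withr::with_seed(22, matrix(stats::rnorm(120 * 7), 120, 7))
  colnames(base) <- paste0("f", 1:7)
  dup <- base + withr::with_seed(23, matrix(stats::rnorm(120 * 7, 0, 0.1),
                                            120, 7))
  colnames(dup) <- paste0("f", 1:7, "_dup")
  feats <- cbind(as.data.frame(base), as.data.frame(dup))

  mv <- multivariateCox(feats, surv, pruneR = 0.7)
  expect_length(mv$retained, 7L)
  expect_equal(nrow(mv$coefficients), 7L)
  # exactly one member of each correlated pair survives
  for (i in 1:7)
    expect_equal(sum(mv$retained %in% c(paste0("f", i),
                                        paste0("f", i, "_dup"))), 1L)

  # two exact copies: one retained
  two <- data.frame(a = base[, 1], b = base[, 1])
  expect_length(multivariateCox(two, surv)$retained, 1L)

  # independent features: nothing pruned
  R <- abs(stats::cor(base)); diag(R) <- 0
  expect_lt(max(R), 0.3)
  expect_length(multivariateCox(as.data.frame(base), surv)$retained, 7L)
})

test_that("log-rank test matches hand tabulation and is symmetric", {
  a <- survTable(c(1, 2, 3), c(1, 1, 1))
  b <- survTable(c(4, 5, 6), c(1, 1, 1))
  lr <- logrankTest(a, b)
  # direct O-E/V tabulation over pooled event times
  time <- c(a$time, b$time); grp <- rep(0:1, each = 3)
  O <- 0; E <- 0; V <- 0
  for (t in sort(unique(time))) {
    atRisk <- time >= t
    d <- sum(time == t)
    n <- sum(atRisk); n1 <- sum(atRisk & grp == 1)
    O <- O + sum(time == t & grp == 1)
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(lr$chi2, (O - E)^2 / V, tolerance = 1e-9)
  expect_equal(logrankTest(b, a)$chi2, lr$chi2, tolerance = 1e-12)

  same <- survTable(c(1, 2, 3, 4), c(1, 0, 1, 1))
  eq <- logrankTest(same, same)
  expect_equal(eq$chi2, 0, tolerance = 1e-12)
  expect_equal(eq$p, 1)
})

test_that("Kaplan-Meier curve equals the product-limit computation", {
  km <- kmCurve(survTable(1:4, rep(1, 4)))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))

  allc <- kmCurve(survTable(c(2, 4, 6), c(0, 0, 0)))
  expect_true(all(allc$surv == 1))

  mixed <- survTable(c(1, 2, 2, 3, 5, 6), c(1, 1, 0, 1, 0, 1))
  km2 <- kmCurve(mixed)
  # hand product-limit: S(1)=5/6, S(2)=5/6*4/5, S(3)=...*2/3, S(6)=0
  expect_equal(km2$surv[km2$time == 1], 5 / 6, tolerance = 1e-12)
  expect_equal(km2$surv[km2$time == 2], 5 / 6 * 4 / 5, tolerance = 1e-12)
  expect_equal(km2$surv[km2$time == 3], 5 / 6 * 4 / 5 * 2 / 3,
               tolerance = 1e-12)
  expect_equal(km2$surv[km2$time == 6], 0, tolerance = 1e-12)
  expect_true(all(diff(km2$surv) <= 0))
})

test_that("concordance index counts comparable pairs like the brute-force oracle", {
  expect_equal(concordanceIndex(c(2, 3, 1), survTable(1:3, rep(1, 3))), 2 / 3)
  expect_equal(concordanceIndex(c(3, 2, 1), survTable(1:3, rep(1, 3))), 1)
  risk <- withr::with_seed(24, stats::rnorm(400))
  sv <- generateSurvival(rep(0, 400), beta = 0, censorRate = 0.2, seed = 24)
  expect_lt(abs(concordanceIndex(risk, sv) - 0.5), 0.05)
})

test_that("BH adjustment matches the tail-minimum oracle and is monotone", {
  expect_equal(bhAdjust(0.03), 0.03)
  p <- withr::with_seed(25, stats::runif(50))
  adj <- bhAdjust(p)
  ord <- order(p)
  oracle <- vapply(seq_along(p), function(i) {
    rank_i <- which(ord == i)
    min(1, min(vapply(rank_i:50, function(j)
      50 / j * p[ord[j]], numeric(1))))
  }, numeric(1))
  expect_equal(adj, oracle, tolerance = 1e-12)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[ord]) >= -1e-12))
})

test_that("optimal cutoff recovers a planted split and validates its own p", {
  grp <- rep(0:1, each = 100)
  feat <- grp + withr::with_seed(26, stats::rnorm(200, 0, 0.05))
  sv <- generateSurvival(grp * 1.5, beta = 1, censorRate = 0.2, seed = 26)
  oc <- optimalCutoff(feat, sv)
  expect_gt(oc$threshold, max(feat[grp == 0]) - 0.2)
  expect_lt(oc$threshold, min(feat[grp == 1]) + 0.2)
  expect_lt(oc$p, 1e-4)
  expect_equal(oc$nLow + oc$nHigh, 200L)
  # reported p equals the log-rank test recomputed at the returned threshold
  lo <- feat <= oc$threshold
  expect_equal(oc$p, logrankTest(sv[lo, ], sv[!lo, ])$p, tolerance = 1e-12)
  expect_gt(oc$nCandidates, 1L)

  expect_error(optimalCutoff(rep(1, 200), sv), "constant")

  # transfer mode: fixed prior threshold, no search
  tr <- optimalCutoff(feat, sv, threshold = 0.5)
  expect_equal(tr$threshold, 0.5)
  expect_equal(tr$nCandidates, 1L)
  expect_lt(tr$p, 1e-4)
})

test_that("null features stay below the BH false-discovery budget", {
  sv <- generateSurvival(rep(0, 150), beta = 0, censorRate = 0.2, seed = 30)
  feats <- withr::with_seed(31, matrix(stats::rnorm(150 * 200), 150, 200))
  ps <- apply(feats, 2, function(f) coxUnivariate(f, sv)$p)
  expect_lte(mean(bhAdjust(ps) < 0.1), 0.12)
})
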