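test_that("gene filtering drops unexpressed genes and keeps the top-variance set", {
  expr <- withr::with_seed(40, matrix(stats::rnorm(8000 * 30), 8000, 30))
  rownames(expr) <- sprintf("g%04d", 1:8000)
  kept <- filterGenes(expr, topK = 5000)
  expect_equal(nrow(kept), 5000L)
  v <- apply(expr, 1, stats::var)
  expect_gte(min(v[rownames(kept)]), max(v[setdiff(rownames(expr),
                                                   rownames(kept))]))

  # topK >= gene count: variance step is a no-op
  expect_equal(nrow(filterGenes(expr[1:100, ], topK = 1000)), 100L)

  # an all-zero gene is always dropped
  expr[1, ] <- 0
  expect_false("g0001" %in% rownames(filterGenes(expr, topK = 8000)))
})

test_that("module detection recovers planted blocks and honours the merge rule", {
  for (sd in 1:3) {
    ex <- generateExpression(nGenes = 480, nSubjects = 87,
                             moduleSizes = c(60, 60, 60), noiseSd = 0.3,
                             seed = sd)
    ms <- detectModules(ex$expression, minSize = 60)
    ari <- mclust::adjustedRandIndex(moduleAssignments(ms),
                                     ex$truth$moduleLabels)
    expect_gte(ari, 0.9)
  }

  # two blocks with latent correlation 0.9 end up in one module
  z1 <- withr::with_seed(41, stats::rnorm(80))
  z2 <- 0.9 * z1 + sqrt(1 - 0.81) * withr::with_seed(42, stats::rnorm(80))
  mkBlock <- function(z, n, seedOff) t(vapply(seq_len(n), function(i)
    z + withr::with_seed(1000 + seedOff + i, stats::rnorm(80, 0, 0.3)),
    numeric(80)))
  expr2 <- rbind(mkBlock(z1, 70, 0), mkBlock(z2, 70, 100))
  rownames(expr2) <- sprintf("g%03d", 1:140)
  ms2 <- detectModules(expr2, minSize = 60, mergeHeight = 0.25)
  mods2 <- setdiff(unique(moduleAssignments(ms2)), "grey")
  expect_length(mods2, 1L)

  # pure noise: nothing reaches the minimum module size
  noise <- withr::with_seed(43, matrix(stats::rnorm(300 * 50), 300, 50))
  rownames(noise) <- sprintf("n%03d", 1:300)
  msn <- detectModules(noise, minSize = 60)
  expect_true(all(moduleAssignments(msn) == "grey"))
})

test_that("module eigengene is the dominant principal component with fixed sign", {
  g <- withr::with_seed(44, stats::rnorm(30))
  single <- moduleEigengene(matrix(g, 1))
  expect_equal(abs(stats::cor(single, g)), 1, tolerance = 1e-12)
  expect_equal(stats::sd(single), 1, tolerance = 1e-12)

  latent <- withr::with_seed(45, stats::rnorm(60))
  load <- withr::with_seed(46, stats::runif(40, 0.5, 1.5))
  mod <- load %o% latent +
    withr::with_seed(47, matrix(stats::rnorm(40 * 60, 0, 0.05), 40))
  eg <- moduleEigengene(mod)
  expect_gte(abs(stats::cor(eg, latent)), 0.999)
  expect_gt(mean(stats::cor(eg, t(mod))), 0)   # sign convention

  # explains at least as much variance as 100 random unit projections
  Z <- t(scale(t(mod)))
  ve <- function(v) sum((Z %*% v)^2)
  egRaw <- svd(Z, nu = 0, nv = 1)$v[, 1]
  rand <- withr::with_seed(48, vapply(1:100, function(i) {
    u <- stats::rnorm(60); ve(u / sqrt(sum(u^2)))
  }, numeric(1)))
  expect_true(all(ve(egRaw) >= rand))
})

test_that("module-feature correlation finds the planted link and rejects permuted nulls", {
  fe <- withr::with_seed(49, stats::rnorm(87))
  ex <- generateExpression(nGenes = 400, nSubjects = 87,
                           moduleSizes = c(158, 100), linkedFeature = fe,
                           targetR = 0.59, seed = 49)
  ms <- detectModules(ex$expression, minSize = 60)
  tab <- moduleFeatureCorrelation(ms, fe)
  expect_gte(max(abs(tab$r)), 0.45)
  expect_lte(max(abs(tab$r)), 0.72)

  eg <- moduleEigengenes(ms)[1, ]
  self <- moduleFeatureCorrelation(ms, data.frame(self = eg))
  expect_equal(self$r[self$module == rownames(moduleEigengenes(ms))[1]], 1,
               tolerance = 1e-12)

  permuted <- vapply(1:100, function(i) {
    fp <- withr::with_seed(2000 + i, sample(fe))
    abs(stats::cor(eg, fp))
  }, numeric(1))
  expect_gte(mean(permuted < 0.3), 0.95)
})

test_that("elastic net shrinks to empty at large lambda and matches the orthonormal soft-threshold oracle", {
  n <- 100L; p <- 10L
  X0 <- withr::with_seed(50, matrix(stats::rnorm(n * p), n, p))
  Q <- qr.Q(qr(scale(X0, scale = FALSE)))
  X <- t(Q * sqrt(n))                       # genes x samples; x_j'x_j = n
  rownames(X) <- sprintf("g%02d", 1:p)
  colnames(X) <- sprintf("S%03d", 1:n)
  beta <- c(2, -1.5, 1, rep(0, 7))
  y <- as.numeric(t(X) %*% beta) + withr::with_seed(51, stats::rnorm(n, 0, 0.5))
  y <- y - mean(y)

  sig <- elasticNetSignature(X, y, topCorrGenes = p, alphaGrid = 0.95,
                             folds = 10, seed = 1)
  z <- as.numeric(X %*% y) / n              # univariate inner products
  soft <- sign(z) * pmax(abs(z) - sig@alpha * sig@lambda, 0)
  expected <- soft / (1 + sig@lambda * (1 - sig@alpha))
  co <- stats::setNames(rep(0, p), rownames(X))
  co[signatureGenes(sig)] <- signatureCoefficients(sig)
  # structural check of the soft-threshold/shrinkage form; the solver's
  # default convergence threshold leaves ~0.2% slack
  expect_equal(unname(co), expected, tolerance = 0.01)
  expect_gte(sig@r2, 0.6)

  empty <- elasticNetSignature(X, y, topCorrGenes = p, alphaGrid = 0.5,
                               lambdaGrid = c(1e4, 5e3), folds = 5, seed = 1)
  expect_length(signatureGenes(empty), 0L)

  expect_warning(elasticNetSignature(X[, 1:6], y[1:6], topCorrGenes = p,
                                     alphaGrid = 0.5, folds = 10, seed = 1),
                 "folds")
})

test_that("signatures transfer exactly on training data and flag missing genes", {
  tr <- generateCohort(nSubjects = 60, nGenes = 300,
                       moduleSizes = c(80, 60), targetR = 0.6,
                       beta = 0, seed = 52)
  sig <- elasticNetSignature(tr$expression, tr$feature, topCorrGenes = 50,
                             seed = 52)
  scores <- applySignature(tr$expression, sig)
  # reproduces the fitted values exactly: recomputed R2 equals the stored one
  r2 <- 1 - sum((tr$feature - scores)^2) /
    sum((tr$feature - mean(tr$feature))^2)
  expect_equal(r2, sig@r2, tolerance = 1e-10)
  expect_gt(stats::cor(scores, tr$feature), 0.5)
  expect_named(scores)
  drop1 <- tr$expression[setdiff(rownames(tr$expression),
                                 signatureGenes(sig)[1]), ]
  expect_error(applySignature(drop1, sig), signatureGenes(sig)[1])
})

test_that("hypergeometric enrichment equals exhaustive tail enumeration", {
  universe <- sprintf("u%02d", 1:20)
  sets <- list(hit = universe[1:5], tiny = universe[6:7])
  sig <- c(universe[1:3], universe[18:19])   # overlap 3 with 'hit'
  enr <- hypergeometricEnrichment(sig, sets, universe)
  # P(X >= 3), X ~ Hypergeom(N=20, K=5, n=5), by direct enumeration
  pHand <- sum(vapply(3:5, function(k)
    choose(5, k) * choose(15, 5 - k), numeric(1))) / choose(20, 5)
  expect_equal(enr$p[enr$set == "hit"], pHand, tolerance = 1e-12)
  expect_equal(enr$p[enr$set == "hit"], 1126 / 15504, tolerance = 1e-12)
  # zero overlap with a tiny set: p = 1 exactly (P(X >= 0) = 1)
  expect_equal(enr$overlap[enr$set == "tiny"], 0L)
  expect_equal(enr$p[enr$set == "tiny"], 1)

  full <- hypergeometricEnrichment(universe, sets, universe)
  expect_true(all(full$p == 1))

  # super-uniform null p-values under random signatures
  means <- withr::with_seed(53, vapply(1:200, function(i)
    hypergeometricEnrichment(sample(universe, 5), sets, universe)$p[1],
    numeric(1)))
  expect_gte(mean(means), 0.45)
})
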