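test_that("affinity propagation handles degenerate data, planted clusters and preference extremes", {
  xid <- matrix(1, 10, 2)
  apid <- affinityPropagation(xid, seed = 1)
  expect_equal(nrow(exemplars(apid)), 1L)

  x3 <- withr::with_seed(2, rbind(matrix(stats::rnorm(100, 0), 50),
                                  matrix(stats::rnorm(100, 10), 50),
                                  matrix(stats::rnorm(100, 20), 50)))
  ap <- affinityPropagation(x3, seed = 1)
  expect_equal(nrow(exemplars(ap)), 3L)
  lab <- clusterLabels(ap)
  planted <- rep(1:3, each = 50)
  expect_equal(length(unique(paste(lab, planted))), 3L)  # exact partition match

  xs <- withr::with_seed(3, matrix(stats::rnorm(30), 15, 2))
  apall <- affinityPropagation(xs, preference = 1e4, seed = 1)
  expect_equal(nrow(exemplars(apall)), 15L)

  expect_error(affinityPropagation(xs, damping = 0.3), "damping")
  expect_error(affinityPropagation(xs[1, , drop = FALSE]), "at least 2")
})

test_that("hull projection solves vertex, edge and grid-oracle cases", {
  corners <- rbind(c(1, 0), c(0, 1))
  ph <- projectToHull(c(0.6, 0.6), corners)
  expect_equal(ph$coefficients, c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(ph$delta, sqrt(0.02), tolerance = 1e-10)

  c3 <- withr::with_seed(4, matrix(stats::runif(3 * 8), 3, 8))
  vx <- projectToHull(c3[2, ], c3)
  expect_equal(vx$coefficients, c(0, 1, 0), tolerance = 1e-7)
  expect_lt(vx$delta, 1e-6)

  # dense simplex grid oracle, step 1e-3 (quadratic optimum: grid residual
  # can exceed the QP optimum by O(step^2 / delta))
  a1 <- rep(seq(0, 1, by = 1e-3), each = 1001)
  a2 <- rep(seq(0, 1, by = 1e-3), times = 1001)
  keep <- a1 + a2 <= 1
  W <- cbind(a1[keep], a2[keep], 1 - a1[keep] - a2[keep])
  for (sd in 1:3) {
    x <- withr::with_seed(sd, stats::rnorm(8))
    ph <- projectToHull(x, c3)
    gridDelta <- sqrt(min(rowSums((W %*% c3 -
      matrix(x, nrow(W), 8, byrow = TRUE))^2)))
    expect_lte(ph$delta, gridDelta + 1e-12)   # QP dominates every grid point
    expect_lt(gridDelta - ph$delta, 1e-5)
  }

  # duplicated corners: delta unique even if the weights are not
  dup <- rbind(c(1, 0), c(1, 0), c(0, 1))
  phd <- projectToHull(c(0.6, 0.6), dup)
  expect_equal(phd$delta, sqrt(0.02), tolerance = 1e-9)
})

test_that("corner selection recovers planted vertices and the J=1 brute-force optimum", {
  V <- rbind(c(1, 0, 0, 0.2), c(0, 1, 0, 0.5), c(0, 0, 1, 0.9))
  mix <- withr::with_seed(5, {
    W <- matrix(stats::rgamma(20 * 3, 1), 20)
    W <- W / rowSums(W)
    W %*% V
  })
  E <- rbind(V, mix)
  sel <- selectCorners(E, 3)
  expect_setequal(sel$cornerIds, 1:3)
  expect_lt(sel$marginTotal, 1e-6)

  # M = J: every exemplar is its own corner, zero margin
  selMJ <- selectCorners(V, 3)
  expect_equal(sort(selMJ$cornerIds), 1:3)
  expect_equal(selMJ$marginTotal, 0, tolerance = 1e-9)

  # J = 1 equals brute force over all single-exemplar candidates
  sel1 <- selectCorners(E, 1)
  brute <- vapply(seq_len(nrow(E)), function(c.)
    sum(sqrt(rowSums((E - matrix(E[c., ], nrow(E), ncol(E),
                                 byrow = TRUE))^2))), numeric(1))
  expect_equal(sel1$cornerIds, which.min(brute))
  expect_equal(sel1$marginTotal, min(brute), tolerance = 1e-8)

  expect_error(selectCorners(E, 30), "exceed")
  expect_error(selectCorners(E, 3, cap = 10), "cap")
})

test_that("proportion estimation is exact noise-free and the R and C++ routes agree", {
  A <- withr::with_seed(6, matrix(stats::runif(3 * 8), 3, 8))
  K <- withr::with_seed(7, {
    G <- matrix(stats::rgamma(200 * 3, 1), 200)
    G / rowSums(G)
  })
  X <- K %*% A
  Khat <- estimateProportions(X, A)
  expect_lt(max(abs(Khat - K)), 1e-6)

  expect_equal(estimateProportions(X, A[1, , drop = FALSE]),
               matrix(1, nrow(X), 1))

  # independent R-level active-set solver vs the compiled route
  Xr <- withr::with_seed(8, matrix(stats::rnorm(50 * 8), 50, 8))
  cppK <- estimateProportions(Xr, A)
  rsol <- camrad:::.simplexSolveGram(A %*% t(A), A %*% t(Xr), rowSums(Xr^2))
  expect_equal(cppK, rsol$W, tolerance = 1e-8)

  expect_warning(estimateProportions(X, rbind(A[1, ], A[1, ])),
                 "linearly dependent")
})

test_that("compartment labelling round-trips generator roles and breaks ties deterministically", {
  for (sd in 1:20) {
    ks <- generateKineticCurves(3, timepoints = 0:7, seed = sd)
    perm <- withr::with_seed(sd, sample(3))
    roles <- labelCompartments(kineticCurves(ks)[perm, ], timePoints(ks))
    expect_identical(roles, curveRoles(ks)[perm])
  }
  dup <- rbind(c(0, 1, 0.5), c(0, 1, 0.5), c(0, 0.2, 1))
  r1 <- labelCompartments(dup, 0:2)
  expect_identical(r1, labelCompartments(dup, 0:2))
  expect_identical(r1[1], "plasma_input")   # tie broken by index
  expect_identical(labelCompartments(dup[1:2, ], 0:2), c("c1", "c2"))
})

test_that("subregion assignment applies the nontrivial-proportion rule", {
  K <- rbind(c(0.995, 0.005, 0), c(1 / 3, 1 / 3, 1 / 3))
  memb <- assignSubregions(K, c("plasma_input", "fast_flow", "slow_flow"))
  expect_equal(unname(memb[1, ]), c(TRUE, FALSE, FALSE))
  expect_true(all(memb[2, ]))

  Kr <- withr::with_seed(9, {
    G <- matrix(stats::rgamma(300, 1), 100)
    G / rowSums(G)
  })
  hi <- assignSubregions(Kr, threshold = 0.5)
  expect_true(all(rowSums(hi) <= 1))                  # disjoint masks
  expect_true(all(rowSums(assignSubregions(Kr)) >= 1))  # full coverage
  expect_error(assignSubregions(Kr, threshold = 0), "threshold")
})

test_that("corner selection is invariant to exemplar order and global scaling", {
  E <- withr::with_seed(10, {
    V <- matrix(stats::runif(3 * 6), 3, 6)
    W <- matrix(stats::rgamma(12 * 3, 1), 12); W <- W / rowSums(W)
    rbind(V, W %*% V + matrix(stats::rnorm(12 * 6, 0, 0.01), 12))
  })
  sel <- selectCorners(E, 3)
  selScaled <- selectCorners(E * 7.3, 3)
  expect_identical(sel$cornerIds, selScaled$cornerIds)
  expect_equal(selScaled$marginTotal, 7.3 * sel$marginTotal,
               tolerance = 1e-6)

  perm <- withr::with_seed(11, sample(nrow(E)))
  selPerm <- selectCorners(E[perm, ], 3)
  expect_setequal(perm[selPerm$cornerIds], sel$cornerIds)

  # selected margin dominates 100 random J-subsets
  margins <- withr::with_seed(12, vapply(1:100, function(i) {
    S <- sample(nrow(E), 3)
    G <- E %*% t(E)
    sum(camrad:::.simplexSolveGram(G[S, S], G[S, ], diag(G))$delta)
  }, numeric(1)))
  expect_true(all(sel$marginTotal <= margins + 1e-9))
})

test_that("end-to-end unmixing reproduces a noise-free tumour to machine precision", {
  rec <- camRecovery(seed = 3, noiseFrac = 0, shape = c(8L, 8L, 3L))
  expect_lt(rec$relFro, 1e-6)
  expect_gte(rec$minCos, 0.999)
  expect_lt(rec$kMae, 1e-6)
  expect_true(rec$rolesAligned)
})

test_that("MDL scores every candidate and identifies the compartment count", {
  ks3 <- generateKineticCurves(3, timepoints = 0:7, seed = 2)
  tum3 <- generateMixtureImage(ks3, shape = c(8L, 8L, 3L),
                               noiseSigma = max(kineticCurves(ks3)) / 20,
                               seed = 52)
  pk3 <- pixelKineticMatrix(imageData(tum3), tumourMask(tum3))
  sel3 <- suppressWarnings(mdlSelect(pk3, candidateJ = 1:4, seed = 102))
  expect_length(sel3$scores, 4L)
  expect_equal(sel3$selectedJ, 3L)

  ks1 <- generateKineticCurves(1, timepoints = 0:7, seed = 2)
  tum1 <- generateMixtureImage(ks1, shape = c(8L, 8L, 3L),
                               noiseSigma = max(kineticCurves(ks1)) / 20,
                               seed = 52)
  pk1 <- pixelKineticMatrix(imageData(tum1), tumourMask(tum1))
  sel1 <- suppressWarnings(mdlSelect(pk1, candidateJ = 1:4, seed = 102))
  expect_equal(sel1$selectedJ, 1L)
})
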