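#' Affinity propagation clustering
#'
#' Message-passing clustering on similarity = negative squared Euclidean
#' distance.  Responsibilities and availabilities are updated with damping
#' until the exemplar set is stable for `convergenceIter` sweeps.  Exemplars
#' are actual data rows; every point is mapped to its most similar exemplar.
#' A seed-controlled jitter of relative magnitude 1e-12 is added to the
#' similarities so tie-breaking is deterministic.
#'
#' @param X numeric matrix (points x features).
#' @param preference diagonal self-similarity; the string `"median"` (default)
#'   uses the median off-diagonal similarity.  Larger values yield more
#'   exemplars.
#' @param damping message damping factor in `[0.5, 1)`.
#' @param maxIter maximum message-passing sweeps.
#' @param convergenceIter sweeps with an unchanged exemplar set required to
#'   declare convergence.
#' @param seed integer seed for the tie-breaking jitter.
#' @return an [ExemplarSet-class]; `@converged` is FALSE (with a warning)
#'   when `maxIter` was reached without a stable exemplar set.
#' @export
affinityPropagation <- function(X, preference = "median", damping = 0.9,
                                maxIter = 1000L, convergenceIter = 50L,
                                seed = 1L) {
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  n <- nrow(X)
  if (n < 2L) stop("affinity propagation needs at least 2 points")
  if (damping < 0.5 || damping >= 1) stop("damping must lie in [0.5, 1)")
  S <- -as.matrix(stats::dist(X))^2
  off <- S[row(S) != col(S)]
  if (max(abs(off)) == 0)            # all points identical: one exemplar
    return(methods::new("ExemplarSet", exemplars = X[1, , drop = FALSE],
                        exemplarIds = 1L, labels = rep(1L, n),
                        converged = TRUE))
  pref <- if (identical(preference, "median")) stats::median(off)
          else as.numeric(preference)
  diag(S) <- pref
  scale <- max(abs(S), 1e-300)
  S <- S + withSeed(seed, matrix(stats::runif(n * n, -1, 1), n)) * scale * 1e-12

  R <- matrix(0, n, n); A <- matrix(0, n, n)
  lastE <- rep(FALSE, n); stable <- 0L; converged <- FALSE
  for (iter in seq_len(maxIter)) {
    # responsibilities
    AS <- A + S
    m1idx <- max.col(AS, ties.method = "first")
    m1 <- AS[cbind(seq_len(n), m1idx)]
    AS2 <- AS; AS2[cbind(seq_len(n), m1idx)] <- -Inf
    m2 <- AS2[cbind(seq_len(n), max.col(AS2, ties.method = "first"))]
    Rnew <- S - m1
    Rnew[cbind(seq_len(n), m1idx)] <- S[cbind(seq_len(n), m1idx)] - m2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0); diag(Rp) <- diag(R)
    Anew <- matrix(colSums(Rp), n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0); diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    E <- (diag(A) + diag(R)) > 0
    if (identical(E, lastE) && any(E)) stable <- stable + 1L else stable <- 0L
    lastE <- E
    if (stable >= convergenceIter) { converged <- TRUE; break }
  }
  ex <- which(lastE)
  if (!length(ex)) ex <- which.max(diag(A) + diag(R))
  if (!converged)
    warning("affinity propagation did not converge; returning current exemplars")
  labels <- apply(S[, ex, drop = FALSE], 1, which.max)
  labels[ex] <- seq_along(ex)
  methods::new("ExemplarSet", exemplars = X[ex, , drop = FALSE],
               exemplarIds = as.integer(ex), labels = as.integer(labels),
               converged = converged)
}

# Pseudo-inverse linear solve for degenerate KKT systems.
.svdSolve <- function(M, b) {
  s <- svd(M)
  pos <- s$d > max(s$d) * 1e-12
  s$v[, pos, drop = FALSE] %*%
    ((t(s$u[, pos, drop = FALSE]) %*% b) / s$d[pos])
}

# Exact simplex-constrained least squares in Gram form.
# Minimizes ||x - C' w||^2 s.t. w >= 0, sum w = 1 for many x at once, given
# GSS = C C' (k x k), CxS = C X' (k x N), xnorm2 = rowSums(X^2).
# Solved by support enumeration of the KKT system (k <= 6 so exhaustive
# enumeration is exact): the affine-constrained minimizer on the optimal
# support is the constrained optimum.
.simplexSolveGram <- function(GSS, CxS, xnorm2) {
  k <- nrow(GSS); N <- ncol(CxS)
  solveSupport <- function(S, cols) {
    ks <- length(S)
    M <- rbind(cbind(2 * GSS[S, S, drop = FALSE], 1), c(rep(1, ks), 0))
    rhs <- rbind(2 * CxS[S, cols, drop = FALSE], rep(1, length(cols)))
    sol <- tryCatch(solve(M, rhs), error = function(e) .svdSolve(M, rhs))
    W <- sol[seq_len(ks), , drop = FALSE]
    res2 <- xnorm2[cols] - 2 * colSums(CxS[S, cols, drop = FALSE] * W) +
      colSums(W * (GSS[S, S, drop = FALSE] %*% W))
    list(W = W, res2 = pmax(res2, 0))
  }
  bestW <- matrix(0, k, N); bestRes <- rep(Inf, N)
  full <- solveSupport(seq_len(k), seq_len(N))
  feas <- colSums(full$W < -1e-9) == 0
  if (any(feas)) {
    bestW[, feas] <- full$W[, feas, drop = FALSE]
    bestRes[feas] <- full$res2[feas]
  }
  pending <- which(!feas)
  if (length(pending) && k > 1L) {
    for (bits in seq_len(2^k - 2)) {       # all proper non-empty supports
      S <- which(bitwAnd(bits, 2^(seq_len(k) - 1)) > 0)
      if (!length(S) || length(S) == k) next
      sub <- solveSupport(S, pending)
      okc <- colSums(sub$W < -1e-9) == 0 & sub$res2 < bestRes[pending] - 1e-12
      if (any(okc)) {
        cols <- pending[okc]
        bestRes[cols] <- sub$res2[okc]
        bestW[, cols] <- 0
        bestW[S, cols] <- sub$W[, okc, drop = FALSE]
      }
    }
  }
  W <- t(bestW)                            # N x k
  W[W < 0] <- 0
  W <- W / rowSums(W)
  list(W = W, delta = sqrt(bestRes))
}

#' Project a time-series onto the convex hull of corner curves
#'
#' Solves the minimum-error-margin projection
#' \eqn{\delta = \min \| x - \sum_j w_j c_j \|_2} subject to
#' \eqn{w_j \ge 0, \sum_j w_j = 1}, as an exact small quadratic program
#' (support enumeration over the KKT system).
#'
#' @param x numeric length-T vector.
#' @param corners J x T matrix of corner curves.
#' @return list with `coefficients` (length-J simplex weights) and `delta`
#'   (the attained Euclidean residual, unique even when the weights are not).
#' @export
projectToHull <- function(x, corners) {
  if (is.vector(corners)) corners <- matrix(corners, nrow = 1)
  if (length(x) != ncol(corners)) stop("x and corners must share T")
  G <- corners %*% t(corners)
  Cx <- corners %*% x
  sol <- .simplexSolveGram(G, matrix(Cx, ncol = 1), sum(x^2))
  list(coefficients = as.numeric(sol$W[1, ]), delta = sol$delta[1])
}

#' Select the corner exemplars by exhaustive minimum-error-margin search
#'
#' Enumerates all `choose(M, J)` subsets of the exemplars and returns the
#' subset minimizing the summed projection residual
#' \eqn{\sum_m \delta_m} of every exemplar onto the subset's convex hull.
#' Ties are broken lexicographically by corner index.
#'
#' @param exemplarSet an [ExemplarSet-class] (or plain M x T matrix).
#' @param J number of corners to select.
#' @param cap maximum number of subsets to enumerate (default 1e5); beyond
#'   it an error asks for a lower AP preference (fewer exemplars).
#' @return list with `cornerIds` (integer length J) and `marginTotal`.
#' @export
selectCorners <- function(exemplarSet, J, cap = 1e5) {
  E <- if (is(exemplarSet, "ExemplarSet")) exemplarSet@exemplars else exemplarSet
  M <- nrow(E)
  if (J > M) stop("J cannot exceed the number of exemplars")
  if (choose(M, J) > cap)
    stop(sprintf(paste("choose(%d, %d) subsets exceed the cap (%g);",
                       "reduce the exemplar count via a lower AP preference"),
                 M, J, cap))
  G <- E %*% t(E)
  res <- .cppSelectCorners(G, as.integer(J))
  list(cornerIds = as.integer(res$cornerIds) + 1L,
       marginTotal = res$marginTotal)
}

#' Estimate per-pixel compartment proportions
#'
#' Row i of K solves the simplex-constrained least-squares projection of
#' pixel time-series i onto the hull of the compartment curves.
#'
#' @param X N x T pixel kinetic matrix (or the list from
#'   [pixelKineticMatrix()]).
#' @param A J x T compartment curve matrix.
#' @return N x J proportion matrix (rows on the unit simplex).
#' @export
estimateProportions <- function(X, A) {
  if (is.list(X)) X <- X$X
  if (is.vector(A)) A <- matrix(A, nrow = 1)
  if (ncol(X) != ncol(A)) stop("X and A must share T")
  if (qr(A)$rank < nrow(A))
    warning("compartment curves are linearly dependent; proportions may be non-unique")
  G <- A %*% t(A)
  sol <- .simplexSolveGram(G, A %*% t(X), rowSums(X^2))
  sol$W
}

#' Label three compartments as plasma input / fast flow / slow flow
#'
#' The plasma input is the curve with the earliest time-to-peak (ties broken
#' by the larger wash-out, `(peak - last) / peak`, then by row index); of
#' the remaining two, the curve with the larger initial wash-in slope
#' (first rise over the first time interval) is fast flow, the other slow
#' flow.  For J != 3, generic labels `c1..cJ` are returned.
#'
#' @param A J x T curve matrix.
#' @param timepoints acquisition times.
#' @return character vector of length J, aligned with the rows of `A`.
#' @export
labelCompartments <- function(A, timepoints) {
  J <- nrow(A)
  if (J != 3L) return(paste0("c", seq_len(J)))
  peakIdx <- apply(A, 1, which.max)
  ttp <- timepoints[peakIdx]
  peak <- A[cbind(1:3, peakIdx)]
  washout <- ifelse(peak > 0, (peak - A[, ncol(A)]) / peak, 0)
  ord <- order(ttp, -washout, seq_len(3))
  plasma <- ord[1]
  rest <- setdiff(seq_len(3), plasma)
  dt <- timepoints[2] - timepoints[1]
  washin <- (A[rest, 2] - A[rest, 1]) / dt
  fast <- rest[order(-washin, rest)[1]]
  slow <- setdiff(rest, fast)
  roles <- character(3)
  roles[c(plasma, fast, slow)] <- .ROLE_SET
  roles
}

#' Assign pixels to compartment subregions by nontrivial proportion
#'
#' A pixel belongs to subregion j iff its proportion `K[i, j]` is at least
#' `threshold` (default 1e-2).  Pixels with several nontrivial proportions
#' are mixture pixels and belong to several subregions.
#'
#' @param K N x J proportion matrix.
#' @param roles length-J compartment labels (column names of the result).
#' @param threshold nontrivial-proportion threshold in (0, 1).
#' @return N x J logical membership matrix with `roles` as column names.
#' @export
assignSubregions <- function(K, roles = colnames(K), threshold = 1e-2) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  memb <- K >= threshold
  colnames(memb) <- roles %||% paste0("c", seq_len(ncol(K)))
  memb
}

# Coordinate-descent corner polish over the pixels themselves: each corner
# in turn is replaced by whichever high-proportion candidate pixel lowers
# the total projection margin of ALL pixels onto the corner hull.  On
# noise-free mixtures with occupied corners the total margin is zero only
# at the true vertices, so the polish lands on them exactly.
.refineCornersOverPixels <- function(X, cornerPixelIds, nCandidates = 15L,
                                     maxSweeps = 5L) {
  ids <- cornerPixelIds
  J <- length(ids)
  total <- function(idset) {
    A <- pmax(X[idset, , drop = FALSE], 0)
    sum(.cppSimplexProject(A, X)$delta)
  }
  best <- total(ids)
  for (sweep in seq_len(maxSweeps)) {
    improved <- FALSE
    K <- .cppSimplexProject(pmax(X[ids, , drop = FALSE], 0), X)$K
    for (j in seq_len(J)) {
      cands <- utils::head(order(K[, j], decreasing = TRUE), nCandidates)
      cands <- setdiff(unique(c(ids[j], cands)), ids[-j])
      for (cand in cands) {
        if (cand == ids[j]) next
        trial <- ids; trial[j] <- cand
        tot <- total(trial)
        if (tot < best - 1e-12) {
          best <- tot; ids <- trial; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  list(cornerPixelIds = ids, totalMargin = best)
}

# Alternate least-squares refinement of curves and proportions (Gaussian
# EM); returns the refined fit.  A tiny ridge guards rank-deficient K.
.emRefit <- function(X, A, K, maxIter = 30L, tol = 1e-8) {
  rss <- sum((X - K %*% A)^2)
  for (i in seq_len(maxIter)) {
    A <- pmax(solve(t(K) %*% K + diag(1e-10, ncol(K)), t(K) %*% X), 0)
    K <- estimateProportions(X, A)
    rssNew <- sum((X - K %*% A)^2)
    if (rss - rssNew < tol) break
    rss <- rssNew
  }
  list(A = A, K = K, rss = rss)
}

#' Minimum-description-length selection of the compartment count
#'
#' Affinity propagation is run once on the pixel time-series; for each
#' candidate J the minimum-margin corner subset is selected, the curves and
#' proportions are refined by alternating least squares (so the scored RSS
#' is the maximized-likelihood fit, not the raw corner-exemplar fit), and
#' the description length is scored.  The smallest-scoring J wins (ties to
#' the smaller J).
#'
#' Two penalty forms are available.  The default, `"perpixel"`,
#' `(N T / 2) log(RSS / (N T)) + (J T / 2) log(N T) + (N (J - 1) / 2) log(T)`,
#' prices each pixel's J - 1 proportion parameters by the T observations
#' that support them.  `"global"`,
#' `(N T / 2) log(RSS / (N T)) + (J T + N (J - 1)) / 2 * log(N T)`, prices
#' every parameter by the full sample size; it is retained as an option but
#' over-penalizes the proportions and in practice collapses to J = 1.
#'
#' @param X N x T pixel kinetic matrix (or [pixelKineticMatrix()] list).
#' @param candidateJ integer candidates, subset of 1..6.
#' @param penalty `"perpixel"` (default) or `"global"`; see Details.
#' @param refit logical, refine each candidate fit by alternating least
#'   squares before scoring (default TRUE).
#' @param preference,damping,seed affinity-propagation controls.
#' @param cap subset-enumeration cap passed to [selectCorners()].
#' @return list with `candidateJ`, `scores`, `selectedJ`, `exemplarSet`.
#' @export
mdlSelect <- function(X, candidateJ = 1:4, penalty = c("perpixel", "global"),
                      refit = TRUE, preference = "median", damping = 0.9,
                      seed = 1L, cap = 1e5) {
  if (is.list(X)) X <- X$X
  if (!all(candidateJ %in% 1:6)) stop("candidateJ must be within 1..6")
  penalty <- match.arg(penalty)
  N <- nrow(X); Tn <- ncol(X)
  ex <- affinityPropagation(X, preference = preference, damping = damping,
                            seed = seed)
  scores <- vapply(candidateJ, function(J) {
    sel <- selectCorners(ex, J, cap = cap)
    A <- pmax(ex@exemplars[sel$cornerIds, , drop = FALSE], 0)
    K <- estimateProportions(X, A)
    rss <- if (refit) .emRefit(X, A, K)$rss else sum((X - K %*% A)^2)
    rss <- max(rss, 1e-12)
    pen <- if (penalty == "perpixel")
      (J * Tn / 2) * log(N * Tn) + (N * (J - 1) / 2) * log(Tn)
    else
      (J * Tn + N * (J - 1)) / 2 * log(N * Tn)
    (N * Tn / 2) * log(rss / (N * Tn)) + pen
  }, numeric(1))
  selected <- candidateJ[order(scores, candidateJ)[1]]
  list(candidateJ = candidateJ, scores = scores, selectedJ = selected,
       exemplarSet = ex)
}

#' Convex-analysis-of-mixtures decomposition of tumour kinetics
#'
#' Full unmixing pipeline: affinity propagation clusters the pixel
#' time-series into exemplars; the minimum-error-margin corner subset of
#' size J is selected among them; each corner is then polished by
#' coordinate descent over the highest-proportion candidate pixels,
#' minimizing the total projection margin of every pixel (so corners are
#' actual extreme pixels, exact on noise-free mixtures); the corner pixels
#' (clipped at 0) become the compartment curves; per-pixel proportions are
#' the simplex projections onto their hull; for J = 3 the compartments are
#' labelled plasma input / fast flow / slow flow.
#'
#' @param X N x T pixel kinetic matrix, a [pixelKineticMatrix()] list, or a
#'   [SyntheticTumour-class].
#' @param J compartment count (default 3, the breast DCE-MRI convention);
#'   set `selectJ = TRUE` to choose J by MDL instead.
#' @param timepoints acquisition times (taken from the input when it
#'   carries them).
#' @param selectJ logical; run [mdlSelect()] over `candidateJ` first.
#' @param candidateJ candidates for MDL selection.
#' @param preference,damping,seed affinity-propagation controls.
#' @param refineCorners logical (default TRUE); polish the exemplar-level
#'   corners over candidate pixels by total-margin coordinate descent.
#' @param emRefine logical; additionally alternate least-squares
#'   re-estimation of curves and proportions (Gaussian-noise EM) until the
#'   RSS change is < 1e-8.  Off by default: the corner-pixel fit is
#'   deterministic and attains the same optimum under isotropic noise.
#' @param cap subset-enumeration cap.
#' @return a [CompartmentModel-class].
#' @export
camDecompose <- function(X, J = 3L, timepoints = NULL, selectJ = FALSE,
                         candidateJ = 1:4, preference = "median",
                         damping = 0.9, seed = 1L, refineCorners = TRUE,
                         emRefine = FALSE, cap = 1e5) {
  if (is(X, "SyntheticTumour")) {
    pk <- pixelKineticMatrix(X@image, X@mask, X@trueCurves@timepoints)
    X <- pk$X; timepoints <- pk$timepoints
  } else if (is.list(X)) {
    timepoints <- timepoints %||% X$timepoints
    X <- X$X
  }
  if (is.null(timepoints)) timepoints <- seq_len(ncol(X)) - 1
  ex <- affinityPropagation(X, preference = preference, damping = damping,
                            seed = seed)
  if (selectJ) {
    sel <- mdlSelect(X, candidateJ = candidateJ, preference = preference,
                     damping = damping, seed = seed, cap = cap)
    J <- sel$selectedJ
  }
  J <- as.integer(J)
  corners <- selectCorners(ex, J, cap = cap)
  cornerPixelIds <- ex@exemplarIds[corners$cornerIds]
  if (refineCorners)
    cornerPixelIds <- .refineCornersOverPixels(X, cornerPixelIds)$cornerPixelIds
  A <- pmax(X[cornerPixelIds, , drop = FALSE], 0)
  K <- estimateProportions(X, A)
  if (emRefine) {
    ref <- .emRefit(X, A, K, maxIter = 100L)
    A <- ref$A; K <- ref$K
  }
  roles <- labelCompartments(A, timepoints)
  methods::new("CompartmentModel", A = A, K = K,
               timepoints = as.numeric(timepoints),
               cornerIds = as.integer(cornerPixelIds), roles = roles,
               marginTotal = corners$marginTotal)
}
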