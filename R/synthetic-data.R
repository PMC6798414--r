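#' Generate compartment kinetic curves
#'
#' Simulates the enhancement curves of J vascular compartments on a DCE-MRI
#' time grid.  Each curve is a gamma-variate wash-in with exponential
#' wash-out, `s(t) = A (t/tp)^a exp(a (1 - t/tp))`, which is smooth,
#' nonnegative and peaks at `tp`.  For J = 3 the roles are parameterized so
#' that the plasma input peaks first and washes out fastest, the slow-flow
#' compartment has the lowest wash-in rate and plateaus late, and the
#' fast-flow compartment sits in between.
#'
#' @param J number of compartments (1 to 5).
#' @param timepoints ascending acquisition times in minutes, length >= 3.
#' @param seed integer seed; identical seeds give identical curves.
#' @return a [KineticCurveSet-class].
#' @examples
#' ks <- generateKineticCurves(J = 3, timepoints = 0:8, seed = 1)
#' curveRoles(ks)
#' @export
generateKineticCurves <- function(J = 3L, timepoints = c(0, 2.5, 7.5), seed = 1L) {
  if (!is.numeric(J) || length(J) != 1L || J < 1L || J > 5L)
    stop("J must be a single integer in 1..5")
  if (length(timepoints) < 3L || is.unsorted(timepoints, strictly = TRUE))
    stop("timepoints must be ascending with length >= 3")
  J <- as.integer(J)
  tmax <- max(timepoints)

  withSeed(seed, {
    if (J == 3L) {
      # per-role (peak time, shape, amplitude); plasma sharp and early,
      # slow-flow a late broad plateau
      tp <- c(stats::runif(1, 0.10, 0.16), stats::runif(1, 0.35, 0.45),
              stats::runif(1, 0.90, 1.00)) * tmax
      a  <- c(stats::runif(1, 2.5, 3.5), stats::runif(1, 1.6, 2.2),
              stats::runif(1, 0.8, 1.2))
      amp <- c(stats::runif(1, 0.9, 1.1), stats::runif(1, 0.75, 0.95),
               stats::runif(1, 0.55, 0.75))
      roles <- .ROLE_SET
    } else {
      tp <- sort(stats::runif(J, 0.12, 0.95)) * tmax
      # enforce distinct, well-separated peak times
      if (J > 1L) tp <- (seq_len(J) - 0.5) / J * tmax * stats::runif(1, 0.9, 1.0)
      a <- stats::runif(J, 1.0, 3.0)
      amp <- stats::runif(J, 0.6, 1.1)
      roles <- paste0("c", seq_len(J))
    }
    curves <- t(vapply(seq_len(J), function(j) {
      s <- ifelse(timepoints <= 0, 0,
                  amp[j] * (timepoints / tp[j])^a[j] *
                    exp(a[j] * (1 - timepoints / tp[j])))
      pmax(s, 0)
    }, numeric(length(timepoints))))
    methods::new("KineticCurveSet", timepoints = as.numeric(timepoints),
                 curves = curves, roles = roles)
  })
}

#' Spherical mask helper
#'
#' @param shape integer length-3 grid size.
#' @param centre voxel centre (1-based, defaults to the grid midpoint).
#' @param radius radius in voxels.
#' @return logical array of `shape`.
#' @export
sphereMask <- function(shape, centre = (shape + 1) / 2, radius = min(shape) / 3) {
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                   z = seq_len(shape[3]))
  d2 <- (g$x - centre[1])^2 + (g$y - centre[2])^2 + (g$z - centre[3])^2
  array(d2 <= radius^2, dim = shape)
}

# 3-voxel moving-average smoothing of per-voxel values within a mask,
# applied axis by axis; out-of-mask neighbours are ignored.
.smoothInMask <- function(vals, mask, idx) {
  shape <- dim(mask)
  vol <- array(NA_real_, dim = shape)
  vol[idx] <- vals
  for (axis in 1:3) {
    acc <- vol
    cnt <- array(as.double(!is.na(vol)), dim = shape)
    acc[is.na(acc)] <- 0
    for (s in c(-1L, 1L)) {
      shifted <- array(0, dim = shape)
      present <- array(0, dim = shape)
      n <- shape[axis]
      src <- if (s == 1L) 1:(n - 1) else 2:n
      dst <- if (s == 1L) 2:n else 1:(n - 1)
      ix <- rep(list(quote(expr = )), 3)
      ixd <- ix
      ix[[axis]] <- src
      ixd[[axis]] <- dst
      vsrc <- do.call(`[`, c(list(vol), ix))
      shifted <- do.call(`[<-`, c(list(shifted), ixd, list(ifelse(is.na(vsrc), 0, vsrc))))
      present <- do.call(`[<-`, c(list(present), ixd, list(as.double(!is.na(vsrc)))))
      acc <- acc + shifted
      cnt <- cnt + present
    }
    sm <- acc / pmax(cnt, 1)
    sm[is.na(vol)] <- NA_real_
    vol <- sm
  }
  vol[idx]
}

#' Simulate a 4-D DCE-MRI tumour as a convex mixture of compartment curves
#'
#' Forward model: each in-mask voxel's time-series is
#' \eqn{x(i) = \sum_j K_j(i) a_j(t) + \epsilon}, with \eqn{K} drawn from a
#' Dirichlet distribution, optionally smoothed spatially (3-voxel moving
#' average, then row renormalization) so subregions are contiguous, and a
#' fraction of voxels forced to pure single-compartment proportions so the
#' mixing simplex has occupied corners — the geometric assumption corner
#' identification relies on.  Out-of-mask voxels contain only noise.
#'
#' @param curves a [KineticCurveSet-class].
#' @param shape integer length-3 voxel grid size.
#' @param dirichletAlpha length-J positive Dirichlet concentration.
#' @param cornerFraction fraction in `[0, 0.5]` of in-mask voxels forced to
#'   pure proportions (split evenly across compartments).
#' @param noiseSigma SD of additive Gaussian noise (signal units).
#' @param seed integer seed.
#' @param mask optional logical array; default: every voxel is tumour.
#' @param smooth logical, spatially smooth the proportion maps (default TRUE).
#' @return a [SyntheticTumour-class].
#' @export
generateMixtureImage <- function(curves, shape = c(10L, 10L, 4L),
                                 dirichletAlpha = NULL, cornerFraction = 0.05,
                                 noiseSigma = 0, seed = 1L, mask = NULL,
                                 smooth = TRUE) {
  stopifnot(is(curves, "KineticCurveSet"))
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  if (cornerFraction < 0 || cornerFraction > 0.5)
    stop("cornerFraction must lie in [0, 0.5]")
  J <- nrow(curves@curves)
  Tn <- length(curves@timepoints)
  if (is.null(dirichletAlpha)) dirichletAlpha <- rep(1, J)
  if (length(dirichletAlpha) != J || any(dirichletAlpha <= 0))
    stop("dirichletAlpha must be J positive reals")
  if (is.null(mask)) mask <- array(TRUE, dim = shape)
  shape <- dim(mask)
  idx <- which(mask)
  N <- length(idx)
  if (N < J) stop("mask must contain at least J voxels")

  withSeed(seed, {
    if (smooth) {
      # Spatially correlated Dirichlet field via a Gaussian copula: white
      # noise smoothed by a 3-voxel moving average, standardized, mapped
      # through the gamma quantile function and normalized.  Rows keep the
      # full Dirichlet(alpha) marginal spread (a well-grounded simplex with
      # naturally occurring near-pure pixels) while the proportion maps stay
      # spatially contiguous; smoothing the proportions directly would
      # shrink their variance ~27-fold and empty the simplex interior.
      Z <- vapply(seq_len(J), function(j)
        .smoothInMask(stats::rnorm(N), mask, idx), numeric(N))
      Z <- scale(Z)
      U <- pmin(pmax(stats::pnorm(Z), 1e-12), 1 - 1e-12)
      G <- vapply(seq_len(J), function(j)
        stats::qgamma(U[, j], shape = dirichletAlpha[j]), numeric(N))
      K <- G / rowSums(G)
    } else {
      # iid Dirichlet via normalized gammas
      G <- matrix(stats::rgamma(N * J, shape = rep(dirichletAlpha, each = N)),
                  nrow = N)
      K <- G / rowSums(G)
    }
    if (cornerFraction > 0) {
      per <- max(1L, ceiling(cornerFraction * N / J))
      taken <- integer(0)
      for (j in seq_len(J)) {
        ord <- order(K[, j], decreasing = TRUE)
        ord <- setdiff(ord, taken)[seq_len(per)]
        K[ord, ] <- 0
        K[ord, j] <- 1
        taken <- c(taken, ord)
      }
    }
    signal <- K %*% curves@curves           # N x T
    flat <- matrix(0, nrow = prod(shape), ncol = Tn)
    flat[idx, ] <- signal
    if (noiseSigma > 0)
      flat <- flat + matrix(stats::rnorm(length(flat), sd = noiseSigma),
                            nrow = nrow(flat))
    img <- array(flat, dim = c(shape, Tn))
    methods::new("SyntheticTumour", image = img, mask = mask, trueK = K,
                 trueCurves = curves, noiseSigma = as.numeric(noiseSigma),
                 seed = as.integer(seed))
  })
}

#' Extract the in-mask pixel kinetic matrix from a 4-D image
#'
#' @param image 4-D array (x, y, z, t).
#' @param mask logical array matching the spatial dimensions.
#' @param timepoints acquisition times (minutes); defaults to 0-based index.
#' @return list with `X` (N x T matrix), `pixelIndex` (voxel linear indices)
#'   and `timepoints`.
#' @export
pixelKineticMatrix <- function(image, mask, timepoints = NULL) {
  d <- dim(image)
  if (length(d) != 4L) stop("image must be 4-D (x, y, z, t)")
  if (!identical(d[1:3], dim(mask))) stop("mask shape mismatch")
  Tn <- d[4]
  if (Tn < 3L) stop("need at least 3 timepoints")
  idx <- which(mask)
  flat <- matrix(image, ncol = Tn)
  X <- flat[idx, , drop = FALSE]
  if (!all(is.finite(X))) stop("non-finite values inside the mask")
  list(X = X, pixelIndex = idx,
       timepoints = timepoints %||% seq_len(Tn) - 1)
}

#' Simulate proportional-hazards survival linked to a feature
#'
#' Event times are exponential with hazard `exp(beta * feature) /
#' baselineScale`; censoring is independent uniform on `(0, c)` with `c`
#' solved numerically so the expected censoring fraction equals
#' `censorRate`.
#'
#' @param feature numeric subject-level covariate.
#' @param beta log-hazard per unit of `feature`.
#' @param baselineScale baseline mean survival in years.
#' @param censorRate target censoring fraction in `[0, 1)`.
#' @param seed integer seed.
#' @return data.frame with columns `subject`, `time` (years), `event` (0/1).
#' @export
generateSurvival <- function(feature, beta = 0, baselineScale = 5,
                             censorRate = 0.3, seed = 1L) {
  if (length(feature) < 1L) stop("feature vector must be non-empty")
  if (censorRate < 0 || censorRate >= 1) stop("censorRate must lie in [0, 1)")
  n <- length(feature)
  lambda <- exp(beta * feature) / baselineScale
  withSeed(seed, {
    t_event <- stats::rexp(n, rate = lambda)
    if (censorRate == 0) {
      time <- t_event; event <- rep(1L, n)
    } else {
      # P(C < T | lambda_i) for C ~ U(0, c): (1 - exp(-lambda c)) / (lambda c)
      pc <- function(cc) mean((1 - exp(-lambda * cc)) / (lambda * cc)) - censorRate
      cmax <- stats::uniroot(pc, lower = 1e-6, upper = 1e6, tol = 1e-10)$root
      cens <- stats::runif(n, 0, cmax)
      event <- as.integer(t_event <= cens)
      time <- pmin(t_event, cens)
    }
    data.frame(subject = paste0("S", seq_len(n)), time = time, event = event,
               stringsAsFactors = FALSE)
  })
}

#' Simulate block-modular gene expression with one feature-linked module
#'
#' Each planted module has a latent eigengene; member genes are
#' `loading * latent + noise`.  Exactly one designated module's latent is
#' built as `targetR * z(feature) + sqrt(1 - targetR^2) * z`, so its
#' eigengene correlates with the imaging feature at `targetR` in
#' expectation.  Genes outside the planted modules are independent noise.
#'
#' @param nGenes total gene count.
#' @param nSubjects sample count (>= 3).
#' @param moduleSizes integer module sizes; sum must not exceed `nGenes`.
#' @param linkedFeature numeric length-`nSubjects` imaging feature linked to
#'   the first module (optional; NULL plants no link).
#' @param targetR target Pearson correlation, |targetR| < 1 (default 0.59).
#' @param noiseSd SD of gene-level noise relative to loadings near 1.
#' @param seed integer seed.
#' @return list with `expression` (genes x samples matrix), and `truth`
#'   (module labels, linked module id, targetR, seed).
#' @export
generateExpression <- function(nGenes = 1000L, nSubjects = 87L,
                               moduleSizes = c(158L, 100L, 60L),
                               linkedFeature = NULL, targetR = 0.59,
                               noiseSd = 0.3, seed = 1L) {
  if (nSubjects < 3L) stop("nSubjects must be >= 3")
  if (sum(moduleSizes) > nGenes) stop("module sizes exceed nGenes")
  if (abs(targetR) >= 1) stop("|targetR| must be < 1")
  if (!is.null(linkedFeature) && length(linkedFeature) != nSubjects)
    stop("linkedFeature must have one value per subject")
  nMod <- length(moduleSizes)
  withSeed(seed, {
    latents <- matrix(stats::rnorm(nMod * nSubjects), nrow = nMod)
    if (!is.null(linkedFeature) && nMod >= 1L) {
      zf <- as.numeric(scale(linkedFeature))
      z <- stats::rnorm(nSubjects)
      z <- as.numeric(scale(stats::residuals(stats::lm(z ~ zf))))
      latents[1, ] <- targetR * zf + sqrt(1 - targetR^2) * z
    }
    labels <- rep("grey", nGenes)
    expr <- matrix(stats::rnorm(nGenes * nSubjects), nrow = nGenes)
    g0 <- 0L
    for (m in seq_len(nMod)) {
      rows <- g0 + seq_len(moduleSizes[m])
      loading <- stats::runif(moduleSizes[m], 0.8, 1.2)
      expr[rows, ] <- loading %o% latents[m, ] +
        matrix(stats::rnorm(moduleSizes[m] * nSubjects, sd = noiseSd),
               nrow = moduleSizes[m])
      labels[rows] <- paste0("M", m)
      g0 <- g0 + moduleSizes[m]
    }
    rownames(expr) <- sprintf("gene%04d", seq_len(nGenes))
    colnames(expr) <- sprintf("S%03d", seq_len(nSubjects))
    names(labels) <- rownames(expr)
    list(expression = expr,
         truth = list(moduleLabels = labels, linkedModule = "M1",
                      latents = latents, targetR = targetR,
                      seed = as.integer(seed)))
  })
}

#' Simulate a linked imaging-genomic-survival cohort
#'
#' Bundles the generators: an imaging feature per subject, block-modular
#' expression whose first module eigengene tracks that feature, and
#' proportional-hazards survival driven by the feature.
#'
#' @param nSubjects subjects in the cohort.
#' @param nGenes,moduleSizes,targetR,noiseSd passed to [generateExpression()].
#' @param beta,baselineScale,censorRate passed to [generateSurvival()].
#' @param seed integer master seed.
#' @return list with `feature`, `expression`, `survival`, `truth`.
#' @export
generateCohort <- function(nSubjects = 87L, nGenes = 1000L,
                           moduleSizes = c(158L, 100L, 60L), targetR = 0.59,
                           noiseSd = 0.3, beta = 0, baselineScale = 5,
                           censorRate = 0.3, seed = 1L) {
  feature <- withSeed(deriveSeed(seed, 1), stats::rnorm(nSubjects))
  ex <- generateExpression(nGenes = nGenes, nSubjects = nSubjects,
                           moduleSizes = moduleSizes, linkedFeature = feature,
                           targetR = targetR, noiseSd = noiseSd,
                           seed = deriveSeed(seed, 2))
  surv <- generateSurvival(feature, beta = beta, baselineScale = baselineScale,
                           censorRate = censorRate, seed = deriveSeed(seed, 3))
  list(feature = feature, expression = ex$expression, survival = surv,
       truth = c(ex$truth, list(beta = beta, censorRate = censorRate,
                                seed = as.integer(seed))))
}
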