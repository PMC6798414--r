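#' @import methods
NULL

.ROLE_SET <- c("plasma_input", "fast_flow", "slow_flow")

#' KineticCurveSet: compartment enhancement curves
#'
#' Container for the time-series enhancement curves \eqn{a_j(t)} of J
#' vascular compartments sampled at T time points.  Rows of `curves` are
#' compartments, columns are time points (minutes).  When J = 3 the roles
#' distinguish the plasma input (rapid wash-in, deep wash-out), fast-flow
#' kinetics and slow-flow kinetics (lowest wash-in rate).
#'
#' @slot timepoints numeric, ascending acquisition times in minutes (length T >= 3).
#' @slot curves J x T matrix of nonnegative signal values.
#' @slot roles character of length J; for J = 3 a permutation of
#'   `c("plasma_input", "fast_flow", "slow_flow")`, otherwise generic labels.
#' @export
setClass("KineticCurveSet",
  representation(timepoints = "numeric", curves = "matrix", roles = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@timepoints) < 3L)
      msg <- c(msg, "need at least 3 timepoints")
    if (is.unsorted(object@timepoints, strictly = TRUE))
      msg <- c(msg, "timepoints must be strictly ascending")
    if (ncol(object@curves) != length(object@timepoints))
      msg <- c(msg, "curves must have one column per timepoint")
    if (any(object@curves < 0))
      msg <- c(msg, "curve values must be nonnegative")
    if (length(object@roles) != nrow(object@curves))
      msg <- c(msg, "one role per curve required")
    if (length(msg)) msg else TRUE
  }
)

#' SyntheticTumour: simulated 4-D DCE-MRI lesion with known mixing truth
#'
#' Forward-model simulation of a tumour whose in-mask voxel time-series are
#' convex mixtures of the compartment curves, plus additive Gaussian noise.
#'
#' @slot image numeric 4-D array, X x Y x Z x T (time last, index 1 = precontrast).
#' @slot mask logical X x Y x Z array of tumour voxels.
#' @slot trueK N x J matrix of ground-truth mixing proportions for the N
#'   in-mask voxels (row-sum 1, entries >= 0).
#' @slot trueCurves [KineticCurveSet-class] used by the forward model.
#' @slot noiseSigma numeric, SD of the additive Gaussian noise (signal units).
#' @slot seed integer seed the object was generated from.
#' @export
setClass("SyntheticTumour",
  representation(image = "array", mask = "array", trueK = "matrix",
                 trueCurves = "KineticCurveSet", noiseSigma = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@image)) != 4L)
      msg <- c(msg, "image must be a 4-D array (x, y, z, t)")
    if (!identical(dim(object@image)[1:3], dim(object@mask)))
      msg <- c(msg, "mask shape must match the spatial image shape")
    n <- sum(object@mask)
    if (nrow(object@trueK) != n)
      msg <- c(msg, "trueK must have one row per in-mask voxel")
    if (any(object@trueK < 0))
      msg <- c(msg, "trueK entries must be nonnegative")
    if (n > 0 && any(abs(rowSums(object@trueK) - 1) > 1e-9))
      msg <- c(msg, "trueK rows must sum to 1")
    if (length(msg)) msg else TRUE
  }
)

#' ExemplarSet: affinity-propagation cluster representatives
#'
#' @slot exemplars M x T matrix of representative pixel time-series (actual
#'   data rows chosen by affinity propagation).
#' @slot exemplarIds integer length-M row indices of the exemplars in the
#'   clustered data matrix.
#' @slot labels integer length-N map pixel -> exemplar row.
#' @slot converged logical, FALSE when message passing hit max_iter without
#'   a stable exemplar set.
#' @export
setClass("ExemplarSet",
  representation(exemplars = "matrix", exemplarIds = "integer",
                 labels = "integer", converged = "logical"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@exemplars) < 1L)
      msg <- c(msg, "need at least one exemplar")
    if (length(object@exemplarIds) != nrow(object@exemplars))
      msg <- c(msg, "one id per exemplar required")
    if (any(object@labels < 1L | object@labels > nrow(object@exemplars)))
      msg <- c(msg, "labels must index exemplar rows")
    if (length(msg)) msg else TRUE
  }
)

#' CompartmentModel: convex-mixture decomposition of a pixel kinetic matrix
#'
#' Result of convex analysis of mixtures: J nonnegative compartment curves
#' (rows of `A`, the corner exemplars) and the N x J simplex-constrained
#' proportion matrix `K` reconstructing each pixel time-series as
#' \eqn{x(i) = \sum_j K_j(i) a_j}.
#'
#' @slot A J x T nonnegative compartment curve matrix.
#' @slot K N x J proportion matrix; rows on the unit simplex.
#' @slot timepoints acquisition times (minutes).
#' @slot cornerIds integer pixel-row indices of the corner time-series the
#'   curves were taken from.
#' @slot roles length-J compartment labels.
#' @slot marginTotal total convex-hull fitting margin (sum of exemplar
#'   projection residuals) of the selected corner subset.
#' @export
setClass("CompartmentModel",
  representation(A = "matrix", K = "matrix", timepoints = "numeric",
                 cornerIds = "integer", roles = "character",
                 marginTotal = "numeric"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@K) != nrow(object@A))
      msg <- c(msg, "K must have one column per compartment curve")
    if (any(object@A < 0))
      msg <- c(msg, "compartment curves must be nonnegative")
    if (any(object@K < -1e-9))
      msg <- c(msg, "proportions must be nonnegative")
    if (nrow(object@K) > 0 && any(abs(rowSums(object@K) - 1) > 1e-6))
      msg <- c(msg, "proportion rows must sum to 1")
    if (length(object@roles) != nrow(object@A))
      msg <- c(msg, "one role per compartment required")
    if (length(msg)) msg else TRUE
  }
)

#' ModuleSet: gene co-expression modules and their eigengenes
#'
#' @slot assignments named character vector gene -> module label; `"grey"`
#'   marks unassigned genes.
#' @slot eigengenes modules x samples matrix of unit-variance eigengene
#'   scores (first principal component of each module).
#' @slot params list of detection parameters (power, minSize, mergeHeight).
#' @export
setClass("ModuleSet",
  representation(assignments = "character", eigengenes = "matrix",
                 params = "list"),
  validity = function(object) {
    msg <- character()
    mods <- setdiff(unique(object@assignments), "grey")
    if (length(mods) && is.null(rownames(object@eigengenes)))
      msg <- c(msg, "eigengene rows must be named by module")
    if (length(mods) && !all(mods %in% rownames(object@eigengenes)))
      msg <- c(msg, "every module needs an eigengene row")
    if (length(msg)) msg else TRUE
  }
)

#' GeneSignature: elastic-net multigene signature for an imaging feature
#'
#' @slot genes character, genes with nonzero coefficients.
#' @slot coefficients named numeric, the nonzero coefficients.
#' @slot intercept numeric.
#' @slot alpha numeric in `[0, 1]`, the selected L1/L2 mixing parameter.
#' @slot lambda numeric > 0, the selected penalty strength.
#' @slot r2 numeric, in-sample R-squared of the fitted model.
#' @slot threshold numeric, stratification threshold carried for transfer
#'   (NA when not set).
#' @export
setClass("GeneSignature",
  representation(genes = "character", coefficients = "numeric",
                 intercept = "numeric", alpha = "numeric", lambda = "numeric",
                 r2 = "numeric", threshold = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@genes) != length(object@coefficients))
      msg <- c(msg, "one coefficient per signature gene required")
    if (any(object@coefficients == 0))
      msg <- c(msg, "signature coefficients are nonzero by definition")
    if (object@alpha < 0 || object@alpha > 1)
      msg <- c(msg, "alpha must lie in [0, 1]")
    if (object@lambda < 0)
      msg <- c(msg, "lambda must be positive")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "KineticCurveSet", function(object) {
  cat("KineticCurveSet:", nrow(object@curves), "compartment curve(s),",
      length(object@timepoints), "timepoints\n")
  cat("  roles:", paste(object@roles, collapse = ", "), "\n")
})

setMethod("show", "SyntheticTumour", function(object) {
  d <- dim(object@image)
  cat(sprintf("SyntheticTumour: %dx%dx%d grid, %d timepoints, %d tumour voxels\n",
              d[1], d[2], d[3], d[4], sum(object@mask)))
  cat(sprintf("  J = %d compartments, noise sigma = %g, seed = %d\n",
              ncol(object@trueK), object@noiseSigma, object@seed))
})

setMethod("show", "ExemplarSet", function(object) {
  cat(sprintf("ExemplarSet: %d exemplars over %d pixels%s\n",
              nrow(object@exemplars), length(object@labels),
              if (object@converged) "" else " (not converged)"))
})

setMethod("show", "CompartmentModel", function(object) {
  cat(sprintf("CompartmentModel: J = %d compartments, %d pixels, %d timepoints\n",
              nrow(object@A), nrow(object@K), ncol(object@A)))
  cat("  roles:", paste(object@roles, collapse = ", "),
      sprintf("| corner margin = %.4g\n", object@marginTotal))
})

setMethod("show", "ModuleSet", function(object) {
  mods <- setdiff(unique(object@assignments), "grey")
  cat(sprintf("ModuleSet: %d modules over %d genes (%d unassigned)\n",
              length(mods), length(object@assignments),
              sum(object@assignments == "grey")))
})

setMethod("show", "GeneSignature", function(object) {
  cat(sprintf("GeneSignature: %d genes, alpha = %.2f, lambda = %.4g, R2 = %.3f\n",
              length(object@genes), object@alpha, object@lambda, object@r2))
})
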