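#' Fuzzy C-means clustering
#'
#' Standard FCM alternating optimization: memberships
#' `u_ik = 1 / sum_l (d_ik / d_il)^(2/(m-1))` and centroids as
#' membership^m-weighted means, iterated until the objective
#' `sum_ik u_ik^m d_ik^2` changes by less than `tol`.  A data point that
#' coincides with a centroid receives full membership there (no division by
#' zero).
#'
#' @param data numeric matrix (points x features) or vector.
#' @param c number of clusters (>= 1).
#' @param m fuzzifier, > 1.
#' @param tol convergence tolerance on the objective change.
#' @param maxIter iteration cap.
#' @param seed integer seed for centroid initialization.
#' @return list with `memberships` (rows sum to 1), `centroids`,
#'   `objectiveTrace` (non-increasing), `nIter`.
#' @export
fcmCluster <- function(data, c = 2L, m = 2, tol = 1e-6, maxIter = 300L,
                       seed = 1L) {
  if (is.vector(data)) data <- matrix(data, ncol = 1)
  n <- nrow(data)
  if (c < 1L) stop("c must be >= 1")
  if (m <= 1) stop("fuzzifier m must be > 1")
  if (n < c) stop("need at least c data points")
  if (c == 1L) {
    cen <- matrix(colMeans(data), nrow = 1)
    d2 <- rowSums((data - matrix(cen, n, ncol(data), byrow = TRUE))^2)
    return(list(memberships = matrix(1, n, 1), centroids = cen,
                objectiveTrace = sum(d2), nIter = 0L))
  }
  centroids <- withSeed(seed, data[sample.int(n, c), , drop = FALSE])
  # ensure distinct starting centroids when duplicates were drawn
  if (anyDuplicated(centroids)) {
    u <- unique(data)
    k <- min(nrow(u), c)
    centroids[seq_len(k), ] <- u[seq_len(k), , drop = FALSE]
  }
  exp_ <- -2 / (m - 1)
  obj <- Inf
  trace <- numeric(0)
  U <- matrix(0, n, c)
  for (iter in seq_len(maxIter)) {
    d2 <- vapply(seq_len(c), function(k)
      rowSums((data - matrix(centroids[k, ], n, ncol(data), byrow = TRUE))^2),
      numeric(n))
    d2 <- pmax(d2, 0)
    zero <- d2 < 1e-300
    pw <- d2^(exp_ / 2)            # d^(-2/(m-1))
    U <- pw / rowSums(pw)
    hit <- rowSums(zero) > 0
    if (any(hit)) {
      U[hit, ] <- 0
      U[cbind(which(hit), max.col(-d2[hit, , drop = FALSE]))] <- 1
    }
    Um <- U^m
    newObj <- sum(Um * d2)
    centroids <- (t(Um) %*% data) / colSums(Um)
    trace <- c(trace, newObj)
    if (is.finite(obj) && abs(obj - newObj) < tol) {
      obj <- newObj
      break
    }
    obj <- newObj
  }
  list(memberships = U, centroids = centroids, objectiveTrace = trace,
       nIter = length(trace))
}

# 26-connected component of `mask` containing voxel `seedIdx` (linear index).
.connectedComponent <- function(mask, seedIdx) {
  shape <- dim(mask)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  comp <- array(FALSE, dim = shape)
  frontier <- seedIdx
  comp[seedIdx] <- TRUE
  toCoord <- function(idx) {
    idx0 <- idx - 1L
    cbind(idx0 %% shape[1] + 1L,
          (idx0 %/% shape[1]) %% shape[2] + 1L,
          idx0 %/% (shape[1] * shape[2]) + 1L)
  }
  while (length(frontier)) {
    co <- toCoord(frontier)
    nb <- do.call(rbind, lapply(seq_len(nrow(offsets)), function(o)
      sweep(co, 2, offsets[o, ], `+`)))
    keep <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
            nb[, 2] >= 1 & nb[, 2] <= shape[2] &
            nb[, 3] >= 1 & nb[, 3] <= shape[3]
    nb <- nb[keep, , drop = FALSE]
    nbIdx <- unique(nb[, 1] + (nb[, 2] - 1L) * shape[1] +
                    (nb[, 3] - 1L) * shape[1] * shape[2])
    nbIdx <- nbIdx[mask[nbIdx] & !comp[nbIdx]]
    comp[nbIdx] <- TRUE
    frontier <- nbIdx
  }
  comp
}

#' Extract a tumour mask from an enhancement volume by fuzzy C-means
#'
#' Clusters voxel enhancement into `c` fuzzy clusters (default 2:
#' lesion vs background), hard-assigns voxels to their highest-membership
#' cluster, takes the cluster with the highest centroid as tumour, and
#' returns the 26-connected component containing the seed point.
#'
#' @param enhancementVolume 3-D array, typically early postcontrast minus
#'   precontrast.
#' @param seedPoint integer length-3 voxel coordinate (1-based) inside the
#'   lesion.
#' @param c number of FCM clusters.
#' @param minSize minimum component size in voxels.
#' @param seed RNG seed for FCM initialization.
#' @return logical array, the tumour mask.
#' @export
extractTumourMask <- function(enhancementVolume, seedPoint, c = 2L,
                              minSize = 10L, seed = 1L) {
  shape <- dim(enhancementVolume)
  if (length(shape) != 3L) stop("enhancementVolume must be 3-D")
  seedPoint <- as.integer(seedPoint)
  if (length(seedPoint) != 3L || any(seedPoint < 1L) || any(seedPoint > shape))
    stop("seedPoint must be a voxel coordinate inside the volume")
  v <- as.numeric(enhancementVolume)
  if (stats::sd(v) < 1e-12)
    stop("seed-outside-lesion: volume has no contrast to segment")
  fit <- fcmCluster(v, c = c, m = 2, seed = seed)
  hard <- max.col(fit$memberships)
  tumourCluster <- which.max(fit$centroids[, 1])
  lesion <- array(hard == tumourCluster, dim = shape)
  seedIdx <- seedPoint[1] + (seedPoint[2] - 1L) * shape[1] +
    (seedPoint[3] - 1L) * shape[1] * shape[2]
  if (!lesion[seedIdx])
    stop("seed-outside-lesion: seed voxel falls in the background cluster")
  comp <- .connectedComponent(lesion, seedIdx)
  if (sum(comp) < minSize)
    stop(sprintf("connected component at seed has %d voxels (< minSize %d)",
                 sum(comp), minSize))
  comp
}
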