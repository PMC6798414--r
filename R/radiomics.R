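#' Build the S-0 / S-1 / S-2 image series
#'
#' S-0 is the precontrast volume; S-1 and S-2 are the subtractions of the
#' precontrast from the early (~2.5 min) and late (~7.5 min) postcontrast
#' volumes.  Subtractions may be negative.
#'
#' @param pre,postEarly,postLate co-registered 3-D volumes of equal shape.
#' @return list with elements `S0`, `S1`, `S2`.
#' @export
buildSeries <- function(pre, postEarly, postLate) {
  if (!identical(dim(pre), dim(postEarly)) ||
      !identical(dim(pre), dim(postLate)))
    stop("volumes must share the same shape")
  list(S0 = pre, S1 = postEarly - pre, S2 = postLate - pre)
}

#' Histogram features: skewness, kurtosis, median
#'
#' Sample skewness `m3 / m2^1.5` and Pearson kurtosis `m4 / m2^2` (not
#' excess), with central moments `m_k = mean((x - mean(x))^k)`; the median
#' uses the mid-point convention for even counts.  A zero-variance region
#' returns skewness 0 and kurtosis 0 with a `degenerate` flag.
#'
#' @param values numeric vector of masked voxel intensities (length >= 1).
#' @return list with `skewness`, `kurtosis`, `median`, `degenerate`.
#' @export
histogramFeatures <- function(values) {
  if (length(values) < 1L) stop("need at least one voxel")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 < 1e-24)
    return(list(skewness = 0, kurtosis = 0, median = stats::median(values),
                degenerate = TRUE))
  m3 <- mean((values - m)^3)
  m4 <- mean((values - m)^4)
  list(skewness = m3 / m2^1.5, kurtosis = m4 / m2^2,
       median = stats::median(values), degenerate = FALSE)
}

# The 13 unique 3-D displacement directions of the 26-neighbourhood
# (one of each +/- pair).
.glcmOffsets3d <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- apply(g, 1, function(o) {
    nz <- o[o != 0]
    nz[1] > 0
  })
  unname(g[keep, , drop = FALSE])
}

#' Grey-level co-occurrence matrix
#'
#' Intensities are min-max quantized into `levels` bins inside the mask;
#' co-occurrences are counted for voxel pairs that are both inside the mask,
#' accumulated over all offsets, optionally symmetrized by adding the
#' transpose, and normalized to probabilities.  A constant region yields a
#' valid single-bin GLCM.
#'
#' @param image 2-D or 3-D numeric array.
#' @param mask logical array of the same shape (default: everything).
#' @param levels number of grey levels (default 32).
#' @param offsets integer matrix of displacement vectors, one per row
#'   (default: the 13 unique 3-D unit directions; for 2-D images the 4
#'   unique 2-D unit directions).
#' @param symmetric logical, add the transpose before normalizing.
#' @return list with `P` (levels x levels probability matrix), `counts`,
#'   `levels`, `offsets`, `symmetric`.
#' @export
glcm <- function(image, mask = NULL, levels = 32L, offsets = NULL,
                 symmetric = TRUE) {
  shape <- dim(image)
  if (length(shape) == 2L) shape <- c(shape, 1L)
  image <- array(image, dim = shape)
  if (is.null(mask)) mask <- array(TRUE, dim = shape)
  mask <- array(mask, dim = shape)
  if (sum(mask) < 2L) stop("need at least 2 in-mask voxels")
  if (is.null(offsets)) {
    offsets <- .glcmOffsets3d()
    if (shape[3] == 1L) offsets <- offsets[offsets[, 3] == 0, , drop = FALSE]
  }
  offsets <- matrix(as.integer(offsets), ncol = 3)
  v <- image[mask]
  lo <- min(v); hi <- max(v)
  q <- array(1L, dim = shape)
  if (hi > lo)
    q[mask] <- pmin(levels, floor((image[mask] - lo) / (hi - lo) * levels) + 1L)
  counts <- matrix(0, levels, levels)
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    sx <- seq_len(shape[1]); sy <- seq_len(shape[2]); sz <- seq_len(shape[3])
    vx <- sx[sx + o[1] >= 1 & sx + o[1] <= shape[1]]
    vy <- sy[sy + o[2] >= 1 & sy + o[2] <= shape[2]]
    vz <- sz[sz + o[3] >= 1 & sz + o[3] <= shape[3]]
    if (!length(vx) || !length(vy) || !length(vz)) next
    m1 <- mask[vx, vy, vz, drop = FALSE] &
          mask[vx + o[1], vy + o[2], vz + o[3], drop = FALSE]
    if (!any(m1)) next
    a <- q[vx, vy, vz, drop = FALSE][m1]
    b <- q[vx + o[1], vy + o[2], vz + o[3], drop = FALSE][m1]
    tab <- table(factor(a, levels = seq_len(levels)),
                 factor(b, levels = seq_len(levels)))
    counts <- counts + unclass(tab)
  }
  if (symmetric) counts <- counts + t(counts)
  dimnames(counts) <- NULL
  tot <- sum(counts)
  if (tot == 0) stop("no co-occurring in-mask voxel pairs for the offsets")
  list(P = counts / tot, counts = counts, levels = levels,
       offsets = offsets, symmetric = symmetric)
}

#' Haralick features from a GLCM
#'
#' Energy `sum p^2`, maximum probability `max p`, and correlation
#' `sum (i - mu_i)(j - mu_j) p / (sigma_i sigma_j)` using the marginal
#' means and standard deviations.  Zero marginal variance yields
#' correlation 0 with a `degenerate` flag.
#'
#' @param g a [glcm()] result (or a plain probability matrix).
#' @return list with `energy`, `maximumProbability`, `correlation`,
#'   `degenerate`.
#' @export
haralickFeatures <- function(g) {
  P <- if (is.list(g)) g$P else g
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  pi_ <- rowSums(P); pj <- colSums(P)
  mui <- sum(seq_len(L) * pi_); muj <- sum(seq_len(L) * pj)
  vi <- sum((seq_len(L) - mui)^2 * pi_); vj <- sum((seq_len(L) - muj)^2 * pj)
  corr <- if (vi * vj < 1e-24) 0 else
    sum((i - mui) * (j - muj) * P) / sqrt(vi * vj)
  list(energy = sum(P^2), maximumProbability = max(P), correlation = corr,
       degenerate = vi * vj < 1e-24)
}

#' Morphological features: volume and compactness
#'
#' Volume is voxel count times voxel volume (mm^3).  Compactness is the
#' dimensionless ratio `36 pi V^2 / A^3` (equal to 1 for a perfect sphere
#' when A is the true surface area), with A obtained by counting exposed
#' faces of boundary voxels (each face weighted by its physical area under
#' anisotropic spacing).  Face counting overestimates smooth surfaces by
#' the staircase factor (3/2 for a ball), so a digitized ball tends to
#' `36 pi / (6 pi)^3 * (4 pi / 3)^2 = 64/216` (about 0.296) rather than 1;
#' the feature is therefore comparable across regions of one analysis
#' rather than absolutely sphere-normalized.
#'
#' @param mask logical 3-D array.
#' @param voxelSpacing numeric length-3 voxel size in mm (default 1 mm iso).
#' @return list with `volume` (mm^3) and `compactness`.
#' @export
morphologyFeatures <- function(mask, voxelSpacing = c(1, 1, 1)) {
  shape <- dim(mask)
  if (length(shape) != 3L) stop("mask must be 3-D")
  n <- sum(mask)
  if (n == 0L) stop("empty mask")
  vol <- n * prod(voxelSpacing)
  faceArea <- c(voxelSpacing[2] * voxelSpacing[3],
                voxelSpacing[1] * voxelSpacing[3],
                voxelSpacing[1] * voxelSpacing[2])
  area <- 0
  for (axis in 1:3) {
    pad <- shape; pad[axis] <- pad[axis] + 2L
    m <- array(FALSE, dim = pad)
    ix <- lapply(seq_along(shape), function(a)
      if (a == axis) 1 + seq_len(shape[a]) else seq_len(shape[a]))
    m <- do.call(`[<-`, c(list(m), ix, list(mask)))
    n1 <- pad[axis]
    lo <- lapply(seq_along(pad), function(a)
      if (a == axis) 1:(n1 - 1) else seq_len(pad[a]))
    hi <- lapply(seq_along(pad), function(a)
      if (a == axis) 2:n1 else seq_len(pad[a]))
    exposed <- xor(do.call(`[`, c(list(m), lo, list(drop = FALSE))),
                   do.call(`[`, c(list(m), hi, list(drop = FALSE))))
    area <- area + sum(exposed) * faceArea[axis]
  }
  list(volume = vol, compactness = 36 * pi * vol^2 / area^3)
}

.FEATURE_NAMES <- c(
  "S0_skewness", "S0_kurtosis", "S0_median", "S0_energy",
  "S0_maximum_probability", "S0_correlation", "S0_volume", "S0_compactness",
  "S1_skewness", "S1_kurtosis", "S1_median", "S1_energy",
  "S1_maximum_probability", "S1_correlation")

#' The 14-feature radiomic table over regions
#'
#' For each supplied region mask, extracts the 14 features: histogram
#' (skewness, kurtosis, median) and Haralick (energy, maximum probability,
#' correlation) on both S-0 and S-1, plus volume and compactness of the
#' region mask on the S-0 geometry.  S-2 is carried by the series but
#' yields no features.
#'
#' @param series a [buildSeries()] result.
#' @param regions named list of logical region masks (whole tumour and/or
#'   subregions).
#' @param levels GLCM grey levels.
#' @param voxelSpacing voxel size in mm.
#' @return data.frame with one row per region and the 14 feature columns.
#' @export
featureTable <- function(series, regions, levels = 32L,
                         voxelSpacing = c(1, 1, 1)) {
  if (is.null(names(regions)) || any(!nzchar(names(regions))))
    stop("regions must be a named list of masks")
  rows <- lapply(names(regions), function(rn) {
    m <- regions[[rn]]
    out <- list(region = rn)
    for (s in c("S0", "S1")) {
      img <- series[[s]]
      h <- histogramFeatures(img[m])
      hl <- haralickFeatures(glcm(img, m, levels = levels))
      out[[paste0(s, "_skewness")]] <- h$skewness
      out[[paste0(s, "_kurtosis")]] <- h$kurtosis
      out[[paste0(s, "_median")]] <- h$median
      out[[paste0(s, "_energy")]] <- hl$energy
      out[[paste0(s, "_maximum_probability")]] <- hl$maximumProbability
      out[[paste0(s, "_correlation")]] <- hl$correlation
      if (s == "S0") {
        mo <- morphologyFeatures(m, voxelSpacing)
        out$S0_volume <- mo$volume
        out$S0_compactness <- mo$compactness
      }
    }
    as.data.frame(out[c("region", .FEATURE_NAMES)], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
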