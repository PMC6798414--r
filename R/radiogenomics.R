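#' Filter an expression matrix for module analysis
#'
#' Drops genes with nonzero expression in fewer than `minExpressedFrac` of
#' the samples, then keeps the `topK` genes with the largest variance
#' (ties broken by gene id).
#'
#' @param expr genes x samples numeric matrix with rownames.
#' @param minExpressedFrac minimum fraction of samples with nonzero
#'   expression (default 0.2).
#' @param topK number of highest-variance genes to retain (default 5000).
#' @return the filtered genes x samples matrix.
#' @export
filterGenes <- function(expr, minExpressedFrac = 0.2, topK = 5000L) {
  if (is.null(rownames(expr))) stop("expr must have gene rownames")
  frac <- rowMeans(expr != 0)
  expr <- expr[frac >= minExpressedFrac, , drop = FALSE]
  if (nrow(expr) == 0L) return(expr)
  v <- apply(expr, 1, stats::var)
  ord <- order(-v, rownames(expr))
  expr[sort(ord[seq_len(min(topK, nrow(expr)))]), , drop = FALSE]
}

#' Module eigengene: first principal component of a module
#'
#' Genes are z-scored across samples; the eigengene is the first right
#' singular vector of the standardized module submatrix, the projection
#' explaining the maximum variance.  Its sign is fixed so the mean
#' correlation with the member genes is positive, and it is scaled to unit
#' variance.
#'
#' @param exprModule genes x samples matrix (one module's genes).
#' @return numeric length-samples eigengene score vector (unit variance).
#' @export
moduleEigengene <- function(exprModule) {
  if (is.vector(exprModule)) exprModule <- matrix(exprModule, nrow = 1)
  sds <- apply(exprModule, 1, stats::sd)
  keep <- sds > 1e-12
  if (!any(keep)) stop("module has no varying genes")
  Z <- t(scale(t(exprModule[keep, , drop = FALSE])))
  v <- svd(Z, nu = 0, nv = 1)$v[, 1]
  if (mean(stats::cor(v, t(Z))) < 0) v <- -v
  as.numeric(scale(v))
}

# Average-linkage tree cut at height h; clusters smaller than minSize -> grey.
.staticCut <- function(hc, h, minSize, genes) {
  cl <- stats::cutree(hc, h = h)
  sizes <- table(cl)
  big <- as.integer(names(sizes)[sizes >= minSize])
  lab <- rep("grey", length(cl))
  for (i in seq_along(big)) lab[cl == big[i]] <- paste0("tmp", i)
  names(lab) <- genes
  lab
}

#' Detect gene co-expression modules
#'
#' Network recipe: adjacency `|pearson r|^power`, dissimilarity
#' `1 - adjacency`, average-linkage hierarchical clustering, and a static
#' tree cut at the fixed dissimilarity height `cutHeight` (default 0.99,
#' the conventional static-cut height: co-expressed blocks join the tree
#' far below it while unrelated genes agglomerate only above it); clusters
#' below `minSize` genes are discarded to grey.  Modules whose
#' eigengenes are closer than `mergeHeight` in correlation dissimilarity
#' (`1 - cor < mergeHeight`) are merged iteratively.  Genes outside any
#' retained module are labelled `"grey"`.  Final modules are named `M1,
#' M2, ...` in decreasing size order.
#'
#' @param expr genes x samples matrix with rownames.
#' @param power soft-threshold exponent for the adjacency (default 5).
#' @param minSize minimum module size in genes (default 60).
#' @param mergeHeight eigengene-dissimilarity merge threshold (default 0.25).
#' @param cutHeight static tree-cut height on the `1 - |r|^power` scale
#'   (default 0.99).
#' @return a [ModuleSet-class].
#' @export
detectModules <- function(expr, power = 5, minSize = 60L, mergeHeight = 0.25,
                          cutHeight = 0.99) {
  if (is.null(rownames(expr))) stop("expr must have gene rownames")
  genes <- rownames(expr)
  if (nrow(expr) < minSize) {
    warning("fewer genes than minSize; all genes left unassigned")
    lab <- stats::setNames(rep("grey", nrow(expr)), genes)
    return(methods::new("ModuleSet", assignments = lab,
                        eigengenes = matrix(0, 0, ncol(expr)),
                        params = list(power = power, minSize = minSize,
                                      mergeHeight = mergeHeight)))
  }
  adj <- abs(stats::cor(t(expr)))^power
  diss <- 1 - adj
  hc <- stats::hclust(stats::as.dist(diss), method = "average")
  lab <- .staticCut(hc, cutHeight, minSize, genes)
  mods <- setdiff(unique(lab), "grey")
  if (length(mods) == 0L) {
    return(methods::new("ModuleSet", assignments = lab,
                        eigengenes = matrix(0, 0, ncol(expr)),
                        params = list(power = power, minSize = minSize,
                                      mergeHeight = mergeHeight)))
  }
  eg <- function(m) moduleEigengene(expr[lab == m, , drop = FALSE])
  eigs <- do.call(rbind, lapply(mods, eg))
  rownames(eigs) <- mods
  # iterative merge of eigengene-similar modules
  while (nrow(eigs) > 1L) {
    cd <- 1 - stats::cor(t(eigs))
    diag(cd) <- Inf
    if (min(cd) >= mergeHeight) break
    ij <- which(cd == min(cd), arr.ind = TRUE)[1, ]
    a <- rownames(eigs)[ij[1]]; b <- rownames(eigs)[ij[2]]
    lab[lab == b] <- a
    mods <- setdiff(unique(lab), "grey")
    eigs <- do.call(rbind, lapply(mods, eg))
    rownames(eigs) <- mods
  }
  # relabel by decreasing size
  sizes <- sort(table(lab[lab != "grey"]), decreasing = TRUE)
  newName <- stats::setNames(paste0("M", seq_along(sizes)), names(sizes))
  lab[lab != "grey"] <- newName[lab[lab != "grey"]]
  rownames(eigs) <- newName[rownames(eigs)]
  eigs <- eigs[order(rownames(eigs)), , drop = FALSE]
  colnames(eigs) <- colnames(expr)
  methods::new("ModuleSet", assignments = lab, eigengenes = eigs,
               params = list(power = power, minSize = minSize,
                             mergeHeight = mergeHeight))
}

#' Module-feature Pearson correlation table
#'
#' @param moduleSet a [ModuleSet-class] (or a modules x samples eigengene
#'   matrix).
#' @param features data.frame/matrix of samples x features, or a single
#'   numeric vector.
#' @return data.frame with columns `module`, `feature`, `r`, `p`.
#' @export
moduleFeatureCorrelation <- function(moduleSet, features) {
  eigs <- if (is(moduleSet, "ModuleSet")) moduleSet@eigengenes else moduleSet
  if (is.vector(features)) features <- data.frame(feature = features)
  features <- as.data.frame(features)
  out <- expand.grid(module = rownames(eigs), feature = names(features),
                     stringsAsFactors = FALSE)
  rp <- t(apply(out, 1, function(row) {
    ct <- stats::cor.test(eigs[row[["module"]], ], features[[row[["feature"]]]])
    c(unname(ct$estimate), ct$p.value)
  }))
  out$r <- rp[, 1]; out$p <- rp[, 2]
  out
}

#' Elastic-net multigene signature for an imaging feature
#'
#' Preselects the `topCorrGenes` genes most correlated (absolute Pearson r)
#' with the feature, then fits an elastic net over an (alpha, lambda) grid,
#' choosing the pair with the smallest tenfold cross-validated error
#' (shared fold assignment across the alpha grid).  The signature is the
#' set of genes with nonzero coefficients.
#'
#' @param expr genes x samples matrix with rownames.
#' @param feature numeric length-samples response (the imaging feature).
#' @param topCorrGenes preselection size (default 100).
#' @param alphaGrid L1/L2 mixing grid (default 0.05 to 0.95 by 0.05).
#' @param lambdaGrid penalty grid (default 50 log-spaced points, 1e-4 to 1).
#' @param folds cross-validation folds (default 10; reduced with a warning
#'   when there are fewer samples).
#' @param seed integer seed fixing the fold assignment.
#' @return a [GeneSignature-class]; `@r2` is the in-sample R-squared.
#' @export
elasticNetSignature <- function(expr, feature, topCorrGenes = 100L,
                                alphaGrid = seq(0.05, 0.95, by = 0.05),
                                lambdaGrid = 10^seq(0, -4, length.out = 50),
                                folds = 10L, seed = 1L) {
  if (is.null(rownames(expr))) stop("expr must have gene rownames")
  n <- ncol(expr)
  if (length(feature) != n) stop("feature must have one value per sample")
  if (n < folds) {
    warning("fewer samples than folds; reducing folds")
    folds <- n
  }
  r <- abs(apply(expr, 1, stats::cor, y = feature))
  sel <- order(-r, rownames(expr))[seq_len(min(topCorrGenes, nrow(expr)))]
  x <- t(expr[sel, , drop = FALSE])
  foldid <- withSeed(seed, sample(rep_len(seq_len(folds), n)))
  best <- NULL
  for (a in alphaGrid) {
    cv <- glmnet::cv.glmnet(x, feature, alpha = a, lambda = lambdaGrid,
                            foldid = foldid, standardize = TRUE)
    i <- which.min(cv$cvm)
    if (is.null(best) || cv$cvm[i] < best$cvm) {
      best <- list(cvm = cv$cvm[i], alpha = a, lambda = cv$lambda[i], cv = cv)
    }
  }
  fit <- glmnet::glmnet(x, feature, alpha = best$alpha, lambda = lambdaGrid,
                        standardize = TRUE)
  co <- as.numeric(stats::coef(fit, s = best$lambda))
  names(co) <- c("(Intercept)", colnames(x))
  nz <- co[-1][co[-1] != 0]
  pred <- as.numeric(stats::predict(fit, newx = x, s = best$lambda))
  r2 <- 1 - sum((feature - pred)^2) / sum((feature - mean(feature))^2)
  methods::new("GeneSignature", genes = names(nz), coefficients = nz,
               intercept = unname(co[1]), alpha = best$alpha,
               lambda = best$lambda, r2 = r2, threshold = NA_real_)
}

#' Apply a gene signature to a new expression matrix
#'
#' Predicted feature scores are `intercept + sum(coef * expression)`;
#' downstream stratification delegates to [optimalCutoff()] in transfer
#' mode at the fixed training threshold.
#'
#' @param exprNew genes x samples matrix containing all signature genes.
#' @param signature a [GeneSignature-class].
#' @return numeric predicted feature scores, named by sample.
#' @export
applySignature <- function(exprNew, signature) {
  missing <- setdiff(signature@genes, rownames(exprNew))
  if (length(missing))
    stop("missing signature genes in expression matrix: ",
         paste(missing, collapse = ", "))
  sub <- exprNew[signature@genes, , drop = FALSE]
  stats::setNames(
    as.numeric(signature@intercept + crossprod(sub, signature@coefficients)),
    colnames(exprNew))
}

#' Hypergeometric gene-set enrichment of a signature
#'
#' For each gene set, the upper-tail hypergeometric probability of drawing
#' at least the observed overlap when `|signature|` genes are sampled from
#' the universe.  Benjamini-Hochberg adjustment is applied across sets.
#'
#' @param signatureGenes character vector of signature gene ids.
#' @param geneSets named list of character vectors (e.g. from [readGmt()]).
#' @param universe character vector of background gene ids (e.g. the
#'   post-filter expression genes).
#' @return data.frame with `set`, `setSize`, `overlap`, `p`, `pAdjusted`,
#'   ordered by p.
#' @export
hypergeometricEnrichment <- function(signatureGenes, geneSets, universe) {
  sig <- intersect(unique(signatureGenes), universe)
  N <- length(unique(universe))
  rows <- lapply(names(geneSets), function(nm) {
    set <- intersect(unique(geneSets[[nm]]), universe)
    k <- length(intersect(sig, set))
    p <- stats::phyper(k - 1, length(set), N - length(set), length(sig),
                       lower.tail = FALSE)
    data.frame(set = nm, setSize = length(set), overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$pAdjusted <- bhAdjust(out$p)
  out[order(out$p, out$set), , drop = FALSE]
}
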