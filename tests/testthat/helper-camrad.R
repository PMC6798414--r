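# Shared helpers for the camrad test suite.

cosSim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Best one-to-one assignment of estimated curve rows to true curve rows by
# cosine similarity (exhaustive over permutations; J <= 4 in tests).
alignCurves <- function(Ahat, Atrue) {
  J <- nrow(Atrue)
  perms <- gtoolsPerms(J)
  best <- NULL; bestScore <- -Inf
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    score <- sum(vapply(seq_len(J), function(j) cosSim(Ahat[p[j], ], Atrue[j, ]),
                        numeric(1)))
    if (score > bestScore) { bestScore <- score; best <- p }
  }
  best
}

# tiny permutation enumerator (avoids a gtools dependency)
gtoolsPerms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- gtoolsPerms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix(setdiff(seq_len(n), k)[sub], nrow(sub))) |>
      unname()
  }))
}

survTable <- function(time, event) data.frame(time = time, event = event)

# permutation-aligned recovery metrics for one synthetic tumour decomposition
camRecovery <- function(seed, noiseFrac, shape = c(10L, 10L, 4L),
                        timepoints = 0:7) {
  ks <- generateKineticCurves(3, timepoints = timepoints, seed = seed)
  mx <- max(kineticCurves(ks))
  tum <- generateMixtureImage(ks, shape = shape,
                              noiseSigma = noiseFrac * mx, seed = seed + 50)
  mod <- suppressWarnings(camDecompose(tum, J = 3, seed = seed + 100))
  A <- kineticCurves(mod); TC <- kineticCurves(ks)
  p <- alignCurves(A, TC)
  X <- pixelKineticMatrix(imageData(tum), tumourMask(tum))$X
  list(minCos = min(vapply(1:3, function(j) cosSim(A[p[j], ], TC[j, ]),
                           numeric(1))),
       kMae = mean(abs(proportions(mod)[, p] - trueProportions(tum))),
       relFro = norm(X - proportions(mod) %*% A, "F") / norm(X, "F"),
       rolesAligned = identical(curveRoles(mod)[p], curveRoles(ks)))
}
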