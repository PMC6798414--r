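#' Read and write NIfTI volumes
#'
#' Thin adapters over RNifti.  4-D series use the last dimension as time,
#' index 1 = precontrast; masks are written as byte volumes.  The affine of
#' a template image is preserved on write.
#'
#' @param path file path (`.nii` / `.nii.gz`).
#' @param image numeric array to write.
#' @param template optional RNifti image whose header/affine to reuse.
#' @return `readNiftiVolume`: a plain numeric array (attributes dropped).
#' @export
readNiftiVolume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  attr(arr, "pixdim") <- RNifti::pixdim(img)
  arr
}

#' @rdname readNiftiVolume
#' @export
writeNiftiVolume <- function(image, path, template = NULL) {
  img <- if (is.null(template)) RNifti::asNifti(image)
         else RNifti::asNifti(image, reference = template)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write tab-separated tables
#'
#' Value-exact round trip (full double precision) with the first column
#' holding row names when `rowNames = TRUE`.
#'
#' @param x data.frame or matrix.
#' @param path file path.
#' @param rowNames write/read row names in the first column.
#' @return `readTsv`: a data.frame.
#' @export
writeTsv <- function(x, path, rowNames = FALSE) {
  df <- as.data.frame(x)
  for (j in seq_along(df))    # 17 significant digits round-trip doubles
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  if (rowNames)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = TRUE, col.names = NA)
  else
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path, rowNames = FALSE) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    row.names = if (rowNames) 1 else NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a GMT gene-set file
#'
#' Tab-delimited: set name, description, then member genes.  Trailing tabs
#' and empty lines are tolerated; sets with no genes are dropped with a
#' warning.
#'
#' @param path GMT file path.
#' @return named list of character gene vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  empty <- character(0)
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) < 1L) next
    nm <- parts[1]
    genes <- if (length(parts) > 2L) unique(parts[-(1:2)]) else character(0)
    if (!length(genes)) empty <- c(empty, nm) else sets[[nm]] <- genes
  }
  if (length(empty))
    warning("dropping empty gene sets: ", paste(empty, collapse = ", "))
  sets
}

#' @rdname readGmt
#' @param sets named list of character gene vectors.
#' @param description description column (recycled).
#' @export
writeGmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a JSON provenance/report file
#'
#' @param x a list.
#' @param path output path.
#' @export
writeJsonReport <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export a synthetic tumour to standard formats
#'
#' Writes the 4-D image and mask as NIfTI, the ground-truth proportion
#' matrix as TSV, and a JSON sidecar with the truth metadata (seed, noise
#' SD, roles, timepoints; time axis = last NIfTI dimension, index 1 =
#' precontrast).
#'
#' @param tumour a [SyntheticTumour-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
writeSyntheticTumour <- function(tumour, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "image.nii.gz")
  p2 <- file.path(dir, "mask.nii.gz")
  p3 <- file.path(dir, "true_K.tsv")
  p4 <- file.path(dir, "truth.json")
  writeNiftiVolume(tumour@image, p1)
  writeNiftiVolume(array(as.integer(tumour@mask), dim = dim(tumour@mask)), p2)
  K <- as.data.frame(tumour@trueK)
  names(K) <- tumour@trueCurves@roles
  writeTsv(K, p3)
  writeJsonReport(list(seed = tumour@seed, noiseSigma = tumour@noiseSigma,
                       roles = tumour@trueCurves@roles,
                       timepoints = tumour@trueCurves@timepoints,
                       timeAxis = "last", precontrastIndex = 1),
                  p4)
  invisible(c(p1, p2, p3, p4))
}
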