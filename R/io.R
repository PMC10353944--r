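## File-format interfaces: paired single-channel TIFFs, 32-bit float map
## TIFFs, calibration CSVs, gene sets (GMT) and MatrixMarket count matrices.

#' Read a single-channel image from TIFF
#'
#' @param path TIFF file path.
#' @return numeric matrix: raw float values for 32-bit float maps, integer
#'   counts (rescaled by the bit depth) for 8/16-bit images.
#' @export
readImageTIFF <- function(path) {
  img <- tiff::readTIFF(path, info = TRUE)
  bits <- attr(img, "bits.per.sample")
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  if (!is.null(bits) && bits < 32L) img <- round(img * (2^bits - 1))
  matrix(as.numeric(img), nrow(img), ncol(img))
}

#' Write an image matrix to TIFF
#'
#' Float data are written as 32-bit float samples (suitable for efficiency
#' and force maps); integer count images are scaled to 16-bit.
#'
#' @param image numeric matrix.
#' @param path output path.
#' @param float write 32-bit float samples (default TRUE).
#' @return invisibly, the path.
#' @export
writeImageTIFF <- function(image, path, float = TRUE) {
  if (float) {
    tiff::writeTIFF(image, path, bits.per.sample = 32L, reduce = FALSE)
  } else {
    if (any(image < 0) || any(image > 65535))
      stop("integer images must lie in 0..65535")
    tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' Read a calibration curve from a two-column CSV
#'
#' Columns: force (pN), efficiency.  Monotonicity (forces strictly
#' increasing, efficiencies strictly decreasing) is enforced at load time.
#'
#' @param path CSV path.
#' @return A [CalibrationCurve-class] whose id is the file name.
#' @export
readCalibration <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L) stop("calibration CSV needs two columns: force, efficiency")
  CalibrationCurve(df[[1L]], df[[2L]], id = basename(path))
}

#' Write a calibration curve to CSV
#' @param cal a [CalibrationCurve-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeCalibration <- function(cal, path) {
  utils::write.csv(data.frame(force_pN = cal@force, efficiency = cal@efficiency),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Uses fgsea's GMT parser when available, else a minimal fallback
#' (tab-separated: name, description, genes...).
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGeneSets <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE))
    return(fgsea::gmtPathways(path))
  lines <- readLines(path)
  sets <- lapply(strsplit(lines, "\t"), function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1L)
  sets
}

#' Read a count matrix from MatrixMarket or CSV
#'
#' MTX input follows the 10x convention: \code{<stem>.mtx} plus row
#' (gene) and column (cell) name files; CSV input is genes x cells with
#' gene names in the first column.
#'
#' @param path path to a \code{.mtx} or \code{.csv} file.
#' @param genesPath,cellsPath one-name-per-line files (MTX only; defaults
#'   \code{<stem>.genes.txt} / \code{<stem>.cells.txt}).
#' @return genes x cells matrix.
#' @export
readCountsMatrix <- function(path, genesPath = NULL, cellsPath = NULL) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    if (is.null(genesPath)) genesPath <- paste0(stem, ".genes.txt")
    if (is.null(cellsPath)) cellsPath <- paste0(stem, ".cells.txt")
    rownames(m) <- readLines(genesPath)
    colnames(m) <- readLines(cellsPath)
    m
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    m
  }
}

#' Write a count matrix to MatrixMarket with name sidecars
#'
#' @param counts genes x cells matrix.
#' @param path output \code{.mtx} path.
#' @return invisibly, the path.
#' @export
writeCountsMatrix <- function(counts, path) {
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
  stem <- sub("\\.mtx$", "", path)
  writeLines(rownames(counts), paste0(stem, ".genes.txt"))
  writeLines(colnames(counts), paste0(stem, ".cells.txt"))
  invisible(path)
}
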