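## Single-cell gene-set signature scoring: CP10K log-normalization,
## cumulative signature scores, group downsampling, score comparisons and
## the promoter-accessibility / expression decile association.

#' Log-normalize counts per 10,000 transcripts
#'
#' Each cell's counts are scaled to 10,000 total transcripts and
#' natural-log transformed: \code{ln(1 + 1e4 * c / total)} — the standard
#' CP10K convention of single-cell toolkits.
#'
#' @param counts genes x cells matrix (or Matrix) of non-negative integer
#'   counts.
#' @param zeroTotal \code{"error"} (default) or \code{"drop"}: what to do
#'   with cells whose total count is zero.
#' @return list of class \code{"ExpressionMatrix"}: \code{values} (genes x
#'   cells, log-normalized), \code{normalization} metadata (method, scale
#'   factor, log base), \code{dropped} cell names.
#' @examples
#' m <- matrix(c(1L, 9999L), 2, 1, dimnames = list(c("a", "b"), "cell1"))
#' logNormalizeCP10K(m)$values["a", ]  # ln 2
#' @export
logNormalizeCP10K <- function(counts, zeroTotal = c("error", "drop")) {
  zeroTotal <- match.arg(zeroTotal)
  if (any(counts < 0)) stop("counts must be non-negative")
  totals <- Matrix::colSums(counts)
  dropped <- character()
  if (any(totals == 0)) {
    if (zeroTotal == "error")
      stop("cell(s) with zero total counts: ",
           paste(head(which(totals == 0), 5), collapse = ", "))
    dropped <- colnames(counts)[totals == 0]
    counts <- counts[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  vals <- log1p(sweep(as.matrix(counts), 2L, totals, "/") * 1e4)
  structure(list(values = vals,
                 normalization = list(method = "CP10K", scale = 1e4,
                                      log_base = exp(1)),
                 dropped = dropped),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells (%s, log base e)\n",
              nrow(x$values), ncol(x$values), x$normalization$method))
  invisible(x)
}

#' Cumulative gene-set signature score per cell
#'
#' Sums each cell's log-normalized expression over the genes of the set —
#' the cumulative adhesion/migration signature.  Genes absent from the
#' matrix are dropped and their number reported; an empty intersection is
#' an error.
#'
#' @param expr an [logNormalizeCP10K()] result, or a genes x cells numeric
#'   matrix of log-normalized values.
#' @param geneSet character vector of gene identifiers.
#' @return numeric vector of per-cell scores, with attributes
#'   \code{n_used} and \code{n_missing}.
#' @export
signatureScore <- function(expr, geneSet) {
  vals <- if (inherits(expr, "ExpressionMatrix")) expr$values else expr
  geneSet <- unique(geneSet)
  present <- intersect(geneSet, rownames(vals))
  if (!length(present))
    stop("no gene of the set is present in the expression matrix")
  score <- colSums(vals[present, , drop = FALSE])
  attr(score, "n_used") <- length(present)
  attr(score, "n_missing") <- length(geneSet) - length(present)
  score
}

#' Downsample a cell group without replacement
#'
#' Uniform seeded sampling of \code{targetN} cells — used to downsample
#' each young population to the size of its old counterpart before score
#' comparisons, so that cumulative distributions are comparable.
#'
#' @param cellIds vector of cell identifiers in the group.
#' @param targetN number of cells to keep (<= length of \code{cellIds}).
#' @param seed integer PRNG seed.
#' @return subset of \code{cellIds} (original order preserved).
#' @export
downsampleGroup <- function(cellIds, targetN, seed = 1L) {
  if (targetN > length(cellIds))
    stop("targetN exceeds the group size")
  if (targetN < 0) stop("targetN must be >= 0")
  .with_seed(seed, {
    keep <- sort(sample.int(length(cellIds), targetN))
    cellIds[keep]
  })
}

#' Compare signature scores between groups
#'
#' Two-tailed Mann-Whitney test on per-cell scores; optionally also on
#' per-animal mean scores when an animal mapping is given.
#'
#' @param scores numeric per-cell scores.
#' @param groups group label per cell (exactly two groups).
#' @param animal optional animal id per cell.
#' @return list with \code{cell_test}, group \code{means}, and
#'   \code{animal_test} (NULL without animal mapping).
#' @export
compareSignature <- function(scores, groups, animal = NULL) {
  gs <- unique(groups)
  if (length(gs) != 2L) stop("exactly two groups are required")
  cell_test <- mannWhitneyTwoTailed(scores[groups == gs[1L]],
                                    scores[groups == gs[2L]])
  animal_test <- NULL
  if (!is.null(animal)) {
    am <- aggregate(list(score = scores),
                    by = list(group = groups, animal = animal), FUN = mean)
    animal_test <- mannWhitneyTwoTailed(am$score[am$group == gs[1L]],
                                        am$score[am$group == gs[2L]])
  }
  list(cell_test = cell_test,
       means = tapply(scores, groups, mean),
       animal_test = animal_test)
}

#' Decile association between promoter accessibility and expression
#'
#' Ranks genes by promoter accessibility (stable tie order), splits them
#' into 10 equal-count bins and reports each decile's expression values and
#' summary — the promoter accessibility vs expression association plotted
#' as per-decile box plots.
#'
#' @param accessibility named numeric vector (per-gene promoter
#'   accessibility).
#' @param expression named numeric vector (per-gene mean expression);
#'   genes are matched by name to \code{accessibility}.
#' @return list with \code{assignment} (data.frame gene, accessibility,
#'   expression, decile), \code{summary} (per-decile n, median, mean) and
#'   \code{spearman} (correlation of decile index with decile median
#'   expression).
#' @export
decileAssociation <- function(accessibility, expression) {
  genes <- intersect(names(accessibility), names(expression))
  if (length(genes) < 10L) stop("at least 10 shared genes are required")
  acc <- accessibility[genes]
  expr <- expression[genes]
  ord <- order(acc)                       # stable for ties
  n <- length(genes)
  sizes <- rep(n %/% 10L, 10L)
  sizes[seq_len(n %% 10L)] <- sizes[seq_len(n %% 10L)] + 1L
  decile <- integer(n)
  decile[ord] <- rep(seq_len(10L), times = sizes)
  assignment <- data.frame(gene = genes, accessibility = as.numeric(acc),
                           expression = as.numeric(expr), decile = decile)
  med <- tapply(assignment$expression, assignment$decile, median)
  summary <- data.frame(decile = as.integer(names(med)),
                        n = as.integer(table(assignment$decile)),
                        median_expression = as.numeric(med),
                        mean_expression = as.numeric(
                          tapply(assignment$expression, assignment$decile, mean)))
  sp <- suppressWarnings(stats::cor(summary$decile, summary$median_expression,
                                    method = "spearman"))
  list(assignment = assignment, summary = summary, spearman = sp)
}
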