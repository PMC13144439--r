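# Expression matrices are plain cells x genes numeric matrices with named
# rows (cell ids), named columns (genes), and a "scale" attribute in
# {"raw", "log", "zscore"}.

expr_scale <- function(x) {
  s <- attr(x, "scale")
  if (is.null(s)) "raw" else s
}

#' Log-normalize a raw expression matrix
#'
#' Applies `log2(value + 1)` entrywise (pseudocount of 1) and updates the
#' scale tag to "log".
#'
#' @param matrix cells x genes raw matrix, values >= 0.
#' @return The log-scaled matrix.
#' @export
normalize_log <- function(matrix) {
  if (expr_scale(matrix) != "raw")
    stop("normalize_log expects a raw-scale matrix (scale tag: ",
         expr_scale(matrix), ")")
  if (any(matrix < 0)) stop("raw expression values must be non-negative")
  out <- log2(matrix + 1)
  attributes(out) <- attributes(matrix)
  attr(out, "scale") <- "log"
  out
}

#' Z-score an expression matrix per gene
#'
#' Centers and scales every gene to mean 0, SD 1 (denominator n - 1).
#' Zero-variance genes cannot be scaled and are dropped with a warning.
#'
#' @param matrix cells x genes matrix with at least 2 cells.
#' @return The z-scored matrix (possibly with fewer genes), scale tag
#'   "zscore".
#' @export
zscore <- function(matrix) {
  if (nrow(matrix) < 2) stop("z-scoring needs at least 2 cells")
  sds <- apply(matrix, 2, stats::sd)
  keep <- sds > 0
  if (!all(keep))
    warning("dropping ", sum(!keep), " zero-variance gene(s): ",
            paste(colnames(matrix)[!keep], collapse = ", "))
  out <- scale(matrix[, keep, drop = FALSE])
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "scale") <- "zscore"
  out
}

#' Apply a quantile-threshold dropout model
#'
#' Technical-noise model for single-cell counts: per gene, values strictly
#' below that gene's empirical `dropQuantile` quantile (type-7, linear
#' interpolation) are set to 0 independently with probability `dropProb`;
#' all other entries are untouched. Applied to raw values before
#' normalization.
#'
#' @param matrix cells x genes matrix.
#' @param dropProb probability in [0, 1] of zeroing an eligible entry.
#' @param dropQuantile per-gene quantile in [0, 1] defining eligibility.
#' @param seed integer seed, or NULL.
#' @return The matrix with dropouts applied (same scale tag).
#' @export
apply_dropout <- function(matrix, dropProb, dropQuantile = 0.2, seed = NULL) {
  stopifnot(dropProb >= 0, dropProb <= 1, dropQuantile >= 0, dropQuantile <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (dropProb == 0) return(matrix)
  out <- matrix
  for (g in seq_len(ncol(out))) {
    thr <- stats::quantile(out[, g], probs = dropQuantile, type = 7,
                           names = FALSE)
    eligible <- which(out[, g] < thr)
    if (length(eligible)) {
      hit <- stats::runif(length(eligible)) < dropProb
      out[eligible[hit], g] <- 0
    }
  }
  out
}

#' Write an expression matrix as TSV (cells x genes)
#'
#' First column `cell_id`, then one column per gene.
#' @param matrix cells x genes matrix with row and column names.
#' @param path output path.
#' @export
write_expression <- function(matrix, path) {
  df <- data.frame(cell_id = rownames(matrix), matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix written by [write_expression()]
#'
#' Accepts tab- or comma-separated files whose first column is the cell id.
#' @param path input path.
#' @param scale scale tag to attach ("raw", "log" or "zscore").
#' @return cells x genes numeric matrix.
#' @export
read_expression <- function(path, scale = "log") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  attr(m, "scale") <- scale
  m
}
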