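#' Construct and validate an expression matrix
#'
#' An expression matrix is a plain numeric matrix with genes in rows and
#' ordered observations (time points, or perturbation experiments taken in
#' experiment order) in columns. Row names are gene identifiers and must be
#' unique; column names label the observations. Values are expression
#' levels or log-ratios and are unitless.
#'
#' @param values numeric matrix, genes x observations.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   existing row names, or `g1..gN` when absent.
#' @param obs_ids character vector of observation labels; defaults to
#'   existing column names, or `t1..tT`.
#' @return the validated numeric matrix with dimnames set.
#' @examples
#' x <- expression_matrix(matrix(rnorm(12), 3, 4))
#' @export
expression_matrix <- function(values, gene_ids = NULL, obs_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("expression data must be a numeric matrix")
  if (is.null(gene_ids)) gene_ids <- rownames(values)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(obs_ids)) obs_ids <- colnames(values)
  if (is.null(obs_ids)) obs_ids <- paste0("t", seq_len(ncol(values)))
  if (length(gene_ids) != nrow(values))
    stopf("got %d gene ids for %d rows", length(gene_ids), nrow(values))
  if (length(obs_ids) != ncol(values))
    stopf("got %d observation ids for %d columns", length(obs_ids), ncol(values))
  dimnames(values) <- list(as.character(gene_ids), as.character(obs_ids))
  validate_expression(values)
}

#' Validate an expression matrix
#'
#' Checks that the input is a numeric matrix with at least one gene, at
#' least three ordered observations, unique gene identifiers and no missing
#' or non-finite values. Offending cells are named in the error message.
#'
#' @param x numeric matrix, genes x observations.
#' @return `x`, invisibly unchanged, with dimnames guaranteed.
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("expression data must be a numeric matrix")
  if (nrow(x) < 1L) stopf("expression matrix must have at least 1 gene row")
  if (ncol(x) < 3L)
    stopf("need at least 3 ordered observations, got %d", ncol(x))
  if (is.null(rownames(x))) rownames(x) <- paste0("g", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("t", seq_len(ncol(x)))
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup))
    stopf("duplicate gene id(s): %s", paste(unique(dup), collapse = ", "))
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad))
    stopf("missing/non-finite value at gene '%s', observation '%s'",
          rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]])
  x
}

#' Center each gene's row to mean zero
#'
#' Subtracts the row mean from every gene. Row-centering is how the
#' inference pipeline absorbs the VAR intercept: the constrained program is
#' fitted without an intercept on centered data. The removed means are kept
#' in the `"row_means"` attribute so forecasts can be mapped back to the
#' data scale.
#'
#' @param x numeric expression matrix (genes x observations).
#' @return centered matrix with identical dimnames and attribute
#'   `row_means`.
#' @examples
#' center_rows(rbind(a = c(1, 2, 3), b = c(5, 5, 5)))
#' @export
center_rows <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stopf("expression data must be a numeric matrix")
  m <- rowMeans(x)
  out <- x - m
  attr(out, "row_means") <- m
  out
}
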