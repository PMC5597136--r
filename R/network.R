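#' Construct a signed directed network
#'
#' A signed network is an edge list over a fixed gene set: each ordered
#' pair (regulator, target) carries sign +1 (activation) or -1
#' (inhibition); pairs absent from the list are non-interactions.
#' Self-loops are allowed. An optional `weight` column carries coefficient
#' magnitudes (used by [collapse_complexes()] to resolve sign conflicts).
#'
#' @param edges data.frame with columns `from`, `to`, `sign` (+1/-1) and
#'   optionally `weight`; zero-row data frames are allowed.
#' @param genes character vector of unique gene identifiers containing all
#'   edge endpoints.
#' @return an object of class `signed_network`.
#' @export
signed_network <- function(edges, genes) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stopf("gene identifiers must be unique")
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        sign = integer(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need <- c("from", "to", "sign")
  if (!all(need %in% names(edges)))
    stopf("edges must have columns: %s", paste(need, collapse = ", "))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$sign <- as.integer(edges$sign)
  if (nrow(edges)) {
    missing <- setdiff(unique(c(edges$from, edges$to)), genes)
    if (length(missing))
      stopf("edge endpoint(s) not in gene set: %s",
            paste(missing, collapse = ", "))
    if (!all(edges$sign %in% c(-1L, 1L)))
      stopf("edge signs must be +1 or -1")
    key <- paste(edges$from, edges$to, sep = "\r")
    if (anyDuplicated(key)) {
      sgn_by_pair <- tapply(edges$sign, key, function(s) length(unique(s)))
      if (any(sgn_by_pair > 1))
        stopf("conflicting duplicate edge(s): %s",
              paste(gsub("\r", " -> ", names(sgn_by_pair)[sgn_by_pair > 1]),
                    collapse = ", "))
      edges <- edges[!duplicated(key), , drop = FALSE]
    }
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(genes = genes, edges = edges), class = "signed_network")
}

#' @export
print.signed_network <- function(x, ...) {
  cat(sprintf("Signed network: %d genes, %d edges (%d activations, %d inhibitions)\n",
              length(x$genes), nrow(x$edges),
              sum(x$edges$sign > 0), sum(x$edges$sign < 0)))
  invisible(x)
}

#' Dense signed adjacency matrix of a network
#'
#' @param net a `signed_network`.
#' @return integer matrix `S` with `S[from, to]` = edge sign (0 = absent).
#'   Note the regulator indexes the row here; in the coefficient matrix of
#'   a fitted model the regulator indexes the column.
#' @export
sign_matrix <- function(net) {
  stopifnot(inherits(net, "signed_network"))
  n <- length(net$genes)
  S <- matrix(0L, n, n, dimnames = list(net$genes, net$genes))
  if (nrow(net$edges))
    S[cbind(net$edges$from, net$edges$to)] <- net$edges$sign
  S
}

#' Extract the signed edge list from a fitted coefficient matrix
#'
#' Every entry with `|A_hat[i, j]| > threshold` becomes a directed edge
#' gene_j -> gene_i carrying `sign(A_hat[i, j])`; entries at or below the
#' threshold (including exact equality) are non-edges. Self-loops are
#' included; under the stability constraint all diagonal entries are
#' non-positive, so every inferred self-loop is an inhibition.
#'
#' @param x a `var_fit` or a square numeric coefficient matrix.
#' @param gene_ids gene identifiers (taken from the fit or from dimnames
#'   when omitted).
#' @param threshold nonnegative magnitude cutoff; defaults to the fit's
#'   `edge_threshold` (1e-6 for bare matrices).
#' @return a [signed_network()] whose edges carry the coefficient
#'   magnitudes in the `weight` column.
#' @export
extract_edges <- function(x, gene_ids = NULL, threshold = NULL) {
  if (inherits(x, "var_fit")) {
    A <- x$A_hat
    if (is.null(gene_ids)) gene_ids <- x$gene_ids
    if (is.null(threshold)) threshold <- x$config$edge_threshold
  } else {
    A <- x
    if (is.null(threshold)) threshold <- 1e-6
  }
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stopf("need a square coefficient matrix")
  if (threshold < 0) stopf("threshold must be nonnegative")
  n <- nrow(A)
  if (is.null(gene_ids)) gene_ids <- rownames(A)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(n))
  idx <- which(abs(A) > threshold, arr.ind = TRUE)
  edges <- data.frame(
    from = gene_ids[idx[, "col"]],
    to = gene_ids[idx[, "row"]],
    sign = as.integer(sign(A[idx])),
    weight = abs(A[idx]),
    stringsAsFactors = FALSE)
  signed_network(edges, gene_ids)
}
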