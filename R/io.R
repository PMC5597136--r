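#' Read an expression matrix from TSV/CSV
#'
#' Expected layout: a header row of observation labels, then one row per
#' gene with the gene identifier in the first column and decimal
#' expression values in the remaining cells. Columns are taken in file
#' order as the temporal/perturbation ordering. Duplicate gene ids,
#' non-numeric cells and ragged rows are rejected with the offending
#' coordinates.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`; guessed from the file
#'   extension when omitted.
#' @return validated numeric expression matrix.
#' @export
read_expression <- function(path, dialect = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (is.null(dialect))
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  sep <- if (dialect == "csv") "," else "\t"
  nf <- tryCatch(count.fields(path, sep = sep, quote = "\""),
                 error = function(e) stopf("cannot parse %s: %s", path,
                                           conditionMessage(e)))
  if (length(nf) == 0) stopf("empty expression file: %s", path)
  if (length(unique(nf)) > 1)
    stopf("ragged rows in %s: line(s) %s have a different field count",
          path, paste(which(nf != nf[1]), collapse = ", "))
  df <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character",
                   comment.char = "")
  if (nrow(df) == 0 || ncol(df) < 2)
    stopf("expression file %s has no data cells", path)
  ids <- df[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stopf("duplicate gene id(s) in %s: %s", path, paste(dup, collapse = ", "))
  cells <- as.matrix(df[, -1, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(cells), nrow(cells), ncol(cells)))
  bad <- which(is.na(vals) & !is.na(cells), arr.ind = TRUE)
  if (nrow(bad))
    stopf("non-numeric cell in %s at gene '%s', column '%s': '%s'",
          path, ids[bad[1, 1]], colnames(cells)[bad[1, 2]],
          cells[bad[1, 1], bad[1, 2]])
  dimnames(vals) <- list(ids, colnames(cells))
  validate_expression(vals)
}

#' Write an expression matrix to TSV/CSV
#'
#' Values are written with full double precision (repr round-trip), so a
#' write-then-read cycle reproduces the matrix exactly.
#'
#' @param expr numeric expression matrix.
#' @param path output path.
#' @param dialect `"tsv"` (default) or `"csv"`; guessed from extension.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, dialect = NULL) {
  expr <- validate_expression(expr)
  if (is.null(dialect))
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  sep <- if (dialect == "csv") "," else "\t"
  out <- cbind(gene = rownames(expr),
               matrix(format(expr, digits = 17, trim = TRUE, scientific = NA),
                      nrow(expr), dimnames = dimnames(expr)))
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

# sign-token vocabulary for SIF-style edge files
.sign_tokens <- c("+" = 1L, "-" = -1L, "+1" = 1L, "-1" = -1L,
                  "activation" = 1L, "inhibition" = -1L)

#' Read a signed network from a SIF-style TSV
#'
#' One edge per line: `source <TAB> sign <TAB> target`, where the source
#' regulates the target and sign is one of `+`, `-`, `+1`, `-1`,
#' `activation`, `inhibition`. Duplicate lines with conflicting signs are
#' rejected with both line numbers; consistent duplicates are merged.
#'
#' @param path file path.
#' @param genes optional gene universe; defaults to the union of the edge
#'   endpoints (pass the expression matrix's gene set to score
#'   non-interactions over the full gene set).
#' @return a [signed_network()].
#' @export
read_network <- function(path, genes = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(signed_network(NULL, genes %||% character()))
  parts <- strsplit(lines, "[\t ]+")
  nfield <- lengths(parts)
  if (any(nfield != 3))
    stopf("line %d of %s does not have 3 fields (source sign target)",
          which(nfield != 3)[1], path)
  m <- do.call(rbind, parts)
  tok <- tolower(m[, 2])
  unknown <- !(tok %in% names(.sign_tokens))
  if (any(unknown))
    stopf("unknown sign token '%s' at line %d of %s",
          m[which(unknown)[1], 2], which(unknown)[1], path)
  edges <- data.frame(from = m[, 1], to = m[, 3],
                      sign = unname(.sign_tokens[tok]),
                      stringsAsFactors = FALSE)
  key <- paste(edges$from, edges$to, sep = "\r")
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    if (length(unique(edges$sign[idx])) > 1)
      stopf("conflicting signs for %s at lines %s of %s",
            gsub("\r", " -> ", k), paste(idx, collapse = " and "), path)
  }
  if (is.null(genes)) genes <- unique(c(edges$from, edges$to))
  signed_network(edges, genes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a signed network as a SIF-style TSV
#'
#' @param net a `signed_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "signed_network"))
  e <- net$edges
  lines <- if (nrow(e)) {
    paste(e$from, ifelse(e$sign > 0, "+", "-"), e$to, sep = "\t")
  } else character()
  writeLines(lines, path)
  invisible(path)
}

#' Write a dense coefficient/adjacency matrix with gene labels
#'
#' Writes the fitted coefficient matrix (or any square gene-labelled
#' matrix) as a TSV with gene ids on both axes, at full double precision.
#' Rows index targets and columns index regulators, matching the
#' coefficient orientation `A[target, regulator]`.
#'
#' @param x a `var_fit` or square numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(x, path) {
  A <- if (inherits(x, "var_fit")) x$A_hat else x
  if (!is.matrix(A) || nrow(A) != ncol(A)) stopf("need a square matrix")
  if (is.null(rownames(A))) {
    ids <- paste0("g", seq_len(nrow(A)))
    dimnames(A) <- list(ids, ids)
  }
  out <- cbind(gene = rownames(A),
               matrix(format(A, digits = 17, trim = TRUE, scientific = NA),
                      nrow(A), dimnames = dimnames(A)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dense gene-labelled matrix written by [write_adjacency()]
#'
#' @param path file path.
#' @return square numeric matrix with gene dimnames.
#' @export
read_adjacency <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  A <- as.matrix(df[, -1, drop = FALSE])
  rownames(A) <- df[[1]]
  storage.mode(A) <- "double"
  A
}

#' Read a gene-to-complex grouping from a two-column TSV
#'
#' @param path file path; two tab-separated columns: gene id, complex
#'   label. A header line `gene<TAB>complex` is allowed and skipped.
#' @return named character vector mapping gene id to complex label.
#' @export
read_complex_grouping <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("gene", "complex"))
  if (nrow(df) && identical(tolower(df$gene[1]), "gene"))
    df <- df[-1, , drop = FALSE]
  dup <- unique(df$gene[duplicated(df$gene)])
  if (length(dup))
    stopf("gene(s) mapped to more than one complex: %s",
          paste(dup, collapse = ", "))
  setNames(as.character(df$complex), df$gene)
}

#' Assemble a reproducible run report
#'
#' Collects everything needed to reproduce and audit a run: package
#' version, input digests, the full configuration, the fitted weights and
#' margins, an eigenvalue summary under both stability notions, the
#' budget-selection table when one was computed, and the evaluation
#' metrics when a reference network was supplied.
#'
#' @param fit a `var_fit`.
#' @param inputs named character vector of input file paths (digested with
#'   MD5), or `NULL`.
#' @param selection optional `lambda_selection`.
#' @param evaluation optional list with `counts` (a `confusion_counts`),
#'   produced for instance by [confusion()].
#' @param seed optional seed echoed into the report.
#' @return a list serializable with [write_run_report()].
#' @export
run_report <- function(fit, inputs = NULL, selection = NULL,
                       evaluation = NULL, seed = NULL) {
  stopifnot(inherits(fit, "var_fit"))
  ev <- fit$eigenvalues
  rep <- list(
    tool = list(name = "stabvar",
                version = as.character(packageVersion("stabvar"))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = if (!is.null(inputs))
      lapply(as.list(inputs), function(p)
        list(path = p, md5 = unname(tools::md5sum(p)))),
    config = unclass(fit$config),
    seed = seed,
    fit = list(objective = fit$objective,
               outer_iterations = fit$outer_iters,
               converged = fit$converged,
               l1_norm = sum(abs(fit$A_hat)),
               weights = fit$weights$v,
               delta = fit$weights$delta,
               beta = fit$weights$beta,
               margins = as.numeric(fit$margins),
               max_margin = max(fit$margins),
               max_abs_eigenvalue = max(Mod(ev)),
               max_re_eigenvalue = max(Re(ev)),
               modulus_stable = is_stable(fit$A_hat, "modulus")$stable,
               halfplane_stable = is_stable(fit$A_hat, "halfplane")$stable,
               gene_ids = fit$gene_ids))
  if (!is.null(selection))
    rep$lambda_selection <- list(table = selection$table,
                                 best_lambda = selection$best_lambda,
                                 best_msfe = selection$best_msfe,
                                 T1 = selection$T1, T2 = selection$T2,
                                 holdout_msfe = selection$holdout_msfe)
  if (!is.null(evaluation)) {
    counts <- evaluation$counts
    met <- network_metrics(counts)
    rep$evaluation <- list(
      counts = unclass(counts),
      sensitivity = met$sensitivity,
      specificity = met$specificity,
      precision = met$precision,
      rates = as.list(summary_rates(counts)))
  }
  rep
}

#' Write / read a JSON run report
#'
#' @param report list from [run_report()].
#' @param path output path.
#' @return `path` invisibly; `read_run_report` returns the parsed list.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_report
#' @export
read_run_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
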