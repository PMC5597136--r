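#' Construct confusion counts
#'
#' Container for the sign-aware confusion counts of an inferred network
#' against a reference. `tp + fp + tn + fn` must equal `n_genes^2` (every
#' ordered gene pair, self-pairs included, falls in exactly one cell).
#' The false counts split further: `false_no_interactions = fn`, and
#' `false_activations + false_inhibitions = fp` when the breakdown is
#' known.
#'
#' @param tp,fp,tn,fn nonnegative counts.
#' @param n_genes number of genes; default inferred as `sqrt(tp+fp+tn+fn)`.
#' @param false_activations,false_inhibitions optional breakdown of `fp`
#'   by inferred sign.
#' @return an object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn, n_genes = NULL,
                             false_activations = NA_integer_,
                             false_inhibitions = NA_integer_) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stopf("counts must be nonnegative")
  if (is.null(n_genes)) {
    n_genes <- sqrt(sum(counts))
    if (n_genes != round(n_genes))
      stopf("tp+fp+tn+fn = %d is not a perfect square; give n_genes",
            sum(counts))
  } else if (sum(counts) != n_genes^2) {
    stopf("tp+fp+tn+fn = %d does not equal n_genes^2 = %d",
          sum(counts), n_genes^2)
  }
  if (!is.na(false_activations) && !is.na(false_inhibitions) &&
      false_activations + false_inhibitions != fp)
    stopf("false_activations + false_inhibitions must equal fp")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn),
                 false_activations = as.integer(false_activations),
                 false_inhibitions = as.integer(false_inhibitions),
                 false_no_interactions = as.integer(fn),
                 n_genes = as.integer(n_genes)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion over %d^2 = %d ordered gene pairs:\n",
              x$n_genes, x$n_genes^2))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  if (!is.na(x$false_activations))
    cat(sprintf("  false activations %d, false inhibitions %d, false no-interactions %d\n",
                x$false_activations, x$false_inhibitions,
                x$false_no_interactions))
  invisible(x)
}

#' Sign-aware confusion of an inferred network against a reference
#'
#' Classifies every ordered gene pair (self-pairs included) exactly once:
#' an inferred edge whose reference pair carries the same sign is a true
#' positive; an inferred edge over an absent or oppositely-signed
#' reference pair is a false positive (the inferred interaction is false;
#' a sign mismatch therefore consumes the pair as FP, not FN); a
#' reference edge with no inferred edge is a false negative; and a shared
#' non-interaction is a true negative. False positives are sub-counted as
#' false activations (+) or false inhibitions (-) by the inferred sign.
#'
#' @param inferred,truth `signed_network` objects over identical gene sets
#'   (collapse complexes first if needed).
#' @return a [confusion_counts()] object.
#' @export
confusion <- function(inferred, truth) {
  stopifnot(inherits(inferred, "signed_network"),
            inherits(truth, "signed_network"))
  if (!setequal(inferred$genes, truth$genes)) {
    only_inf <- setdiff(inferred$genes, truth$genes)
    only_tru <- setdiff(truth$genes, inferred$genes)
    stopf("gene sets differ: only in inferred {%s}; only in truth {%s}",
          paste(only_inf, collapse = ", "), paste(only_tru, collapse = ", "))
  }
  genes <- truth$genes
  S_inf <- sign_matrix(inferred)[genes, genes]
  S_tru <- sign_matrix(truth)
  tp <- sum(S_tru != 0 & S_inf != 0 & S_tru == S_inf)
  fp_mask <- S_inf != 0 & (S_tru == 0 | S_tru != S_inf)
  fn <- sum(S_tru != 0 & S_inf == 0)
  tn <- sum(S_tru == 0 & S_inf == 0)
  confusion_counts(tp, sum(fp_mask), tn, fn, n_genes = length(genes),
                   false_activations = sum(fp_mask & S_inf > 0),
                   false_inhibitions = sum(fp_mask & S_inf < 0))
}

#' Sensitivity, specificity and precision from confusion counts
#'
#' `sensitivity = TP/(TP+FN)`, `specificity = TN/(TN+FP)`,
#' `precision = TP/(TP+FP)`. A metric whose denominator is zero is
#' undefined and reported as `NA` with its name listed in the `undefined`
#' field, never coerced to 0 or 1.
#'
#' @param counts a [confusion_counts()] object.
#' @return an object of class `network_metrics`: list with `sensitivity`,
#'   `specificity`, `precision`, `undefined`.
#' @examples
#' network_metrics(confusion_counts(39, 11, 5, 26))
#' @export
network_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  out <- list(sensitivity = ratio(counts$tp, counts$tp + counts$fn),
              specificity = ratio(counts$tn, counts$tn + counts$fp),
              precision = ratio(counts$tp, counts$tp + counts$fp))
  out$undefined <- names(out)[vapply(out, function(z) is.na(z[[1]]), TRUE)]
  structure(out, class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  pct <- function(z) if (is.na(z)) "undefined" else sprintf("%.1f%%", 100 * z)
  cat(sprintf("sensitivity %s, specificity %s, precision %s\n",
              pct(x$sensitivity), pct(x$specificity), pct(x$precision)))
  invisible(x)
}

#' False-identification and net-connectivity percentages
#'
#' `false_identification_pct = 100 (FP + FN) / N^2`: the share of ordered
#' pairs classified wrongly (spurious edges, wrong-sign edges and missed
#' edges together). `net_connectivity_pct = 100 (TP + FP) / N^2`: the
#' share of ordered pairs the method infers as interactions; lower values
#' mean sparser networks.
#'
#' @param counts a [confusion_counts()] object.
#' @param n_genes gene count; defaults to the count stored in `counts`.
#' @return named numeric vector with both percentages.
#' @export
summary_rates <- function(counts, n_genes = NULL) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (is.null(n_genes)) n_genes <- counts$n_genes
  if (counts$tp + counts$fp + counts$tn + counts$fn != n_genes^2)
    stopf("counts are inconsistent with %d^2 ordered pairs", n_genes)
  c(false_identification_pct = 100 * (counts$fp + counts$fn) / n_genes^2,
    net_connectivity_pct = 100 * (counts$tp + counts$fp) / n_genes^2)
}

#' Collapse genes into complexes before evaluation
#'
#' Genes acting as one regulatory unit (for example SWI4/SWI6 in the
#' budding-yeast cell cycle) are merged into a single node: every edge
#' between members of different complexes becomes a single edge between
#' the complexes, and all edges among members of the same complex are
#' dropped. The sign of a collapsed edge is the sign of the
#' largest-magnitude contributing coefficient when edge weights are
#' available; otherwise the majority sign, with exact ties resolved to +
#' and flagged with a warning.
#'
#' @param net a `signed_network` (edges may carry a `weight` column).
#' @param grouping named character vector mapping gene ids to complex
#'   labels; genes without an entry form singleton complexes labelled by
#'   their own id.
#' @return a `signed_network` over the complex labels.
#' @export
collapse_complexes <- function(net, grouping) {
  stopifnot(inherits(net, "signed_network"))
  grouping <- unlist(grouping)
  unknown <- setdiff(names(grouping), net$genes)
  if (length(unknown))
    stopf("grouping refers to unknown gene(s): %s",
          paste(unknown, collapse = ", "))
  label <- setNames(net$genes, net$genes)
  label[names(grouping)] <- as.character(grouping)
  nodes <- unique(unname(label))
  e <- net$edges
  if (nrow(e) == 0) return(signed_network(NULL, nodes))
  e$cfrom <- unname(label[e$from])
  e$cto <- unname(label[e$to])
  e <- e[e$cfrom != e$cto, , drop = FALSE]
  if (nrow(e) == 0) return(signed_network(NULL, nodes))
  has_w <- "weight" %in% names(e) && all(is.finite(e$weight))
  key <- paste(e$cfrom, e$cto, sep = "\r")
  pick <- lapply(split(seq_len(nrow(e)), key), function(idx) {
    s <- e$sign[idx]
    if (length(unique(s)) == 1L) return(s[1])
    if (has_w) {
      w <- e$weight[idx]
      top <- which(w == max(w))
      tops <- unique(s[top])
      if (length(tops) == 1L) return(tops)
      warnf("sign tie collapsing an inter-complex edge; resolved to +")
      return(1L)
    }
    tot <- sum(s)
    if (tot > 0) return(1L)
    if (tot < 0) return(-1L)
    warnf("sign tie collapsing an inter-complex edge; resolved to +")
    1L
  })
  parts <- do.call(rbind, strsplit(names(pick), "\r", fixed = TRUE))
  signed_network(data.frame(from = parts[, 1], to = parts[, 2],
                            sign = unlist(pick), stringsAsFactors = FALSE),
                 nodes)
}
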