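#' Three-way split indices for rolling forecast evaluation
#'
#' `T1 = floor(T/3)` and `T2 = floor(2T/3)`. Observations 1..T1 act as
#' initialization mass, the rolling one-step forecasts are evaluated at
#' observations T1+1..T2, and observations T2+1..T are held out for final
#' forecast evaluation.
#'
#' @param T number of ordered observations; must be at least 9 so a
#'   nontrivial evaluation window exists.
#' @return named integer vector `c(T1, T2)`.
#' @examples
#' split_indices(9)    # c(T1 = 3, T2 = 6)
#' split_indices(18)   # c(T1 = 6, T2 = 12)
#' @export
split_indices <- function(T) {
  if (!is.numeric(T) || length(T) != 1 || T < 9)
    stopf("T must be at least 9 for a nontrivial forecast window, got %s",
          paste(T, collapse = ","))
  c(T1 = as.integer(floor(T / 3)), T2 = as.integer(floor(2 * T / 3)))
}

# shared rolling-forecast engine; window = "selection" evaluates
# t in T1..T2-1 (forecasting T1+1..T2), window = "holdout" evaluates
# t in T2..T-1. Returns the mean squared forecast error and the last fit
# (for warm starting across a lambda grid).
msfe_engine <- function(expr, lambda, config, window = "selection",
                        init = NULL) {
  expr <- validate_expression(expr)
  T <- ncol(expr)
  s <- split_indices(T)
  ts <- if (window == "selection") s[["T1"]]:(s[["T2"]] - 1L) else s[["T2"]]:(T - 1L)
  cfg <- config
  cfg$lambda <- lambda
  total <- 0
  fit <- NULL
  warm <- init
  for (t in ts) {
    fit <- tryCatch(
      infer_network(expr[, seq_len(t), drop = FALSE], cfg, init = warm),
      error = function(e)
        stopf("forecast window t = %d (lambda = %g): %s", t, lambda,
              conditionMessage(e)))
    warm <- list(A = fit$A_hat, U = fit$solver$U)
    yhat <- forecast_next(fit, expr[, t])
    total <- total + sum((yhat - expr[, t + 1])^2)
  }
  # the error sum over the T2 - T1 windows is normalized by T2 - T1 - 1,
  # following the rolling-forecast criterion's convention
  list(msfe = total / (length(ts) - 1L), fit = fit)
}

#' Rolling one-step-ahead mean square forecast error
#'
#' For each `t` in `T1 .. T2-1`, fits the constrained model on
#' observations `1..t`, forecasts observation `t+1` (adding back the
#' fitted row means so forecasts live on the data scale), and returns the
#' average squared forecast error over the window,
#' `MSFE(lambda) = sum_t ||yhat_{t+1} - y_{t+1}||^2 / (T2 - T1 - 1)`.
#' Deterministic for fixed inputs.
#'
#' @param expr numeric expression matrix, at least 9 observations.
#' @param lambda nonnegative L1 budget to evaluate.
#' @param config a [solver_config()] (its `lambda` field is ignored in
#'   favour of the `lambda` argument).
#' @param window `"selection"` (default, the middle third) or `"holdout"`
#'   (the reserved final third, `t` in `T2..T-1`).
#' @return nonnegative scalar MSFE.
#' @export
msfe <- function(expr, lambda, config, window = c("selection", "holdout")) {
  window <- match.arg(window)
  msfe_engine(expr, lambda, config, window)$msfe
}

#' Select the sparsity budget by minimizing rolling forecast error
#'
#' Evaluates [msfe()] at every grid value (in increasing order, each fit
#' warm-started from the previous budget's solution) and selects the
#' minimizer; exact ties are broken towards the smallest budget, i.e. the
#' sparser model. Observations `T2+1..T` stay untouched unless
#' `holdout = TRUE`, in which case the selected budget's forecast error
#' over the held-out final third is also reported.
#'
#' @param expr numeric expression matrix, at least 9 observations.
#' @param grid nonempty vector of candidate nonnegative budgets; default
#'   `seq(0, 1, by = 0.1)`.
#' @param config a [solver_config()].
#' @param holdout also evaluate the selected budget on the final third?
#' @return an object of class `lambda_selection`: list with `table`
#'   (data.frame of lambda and msfe), `best_lambda`, `best_msfe`, `T1`,
#'   `T2`, and optionally `holdout_msfe`.
#' @export
select_lambda <- function(expr, grid = seq(0, 1, by = 0.1), config,
                          holdout = FALSE) {
  if (length(grid) == 0) stopf("the candidate grid must be nonempty")
  if (any(!is.finite(grid)) || any(grid < 0))
    stopf("all grid values must be finite and nonnegative")
  expr <- validate_expression(expr)
  grid <- sort(unique(as.numeric(grid)))
  s <- split_indices(ncol(expr))
  vals <- numeric(length(grid))
  warm <- NULL
  for (k in seq_along(grid)) {
    res <- msfe_engine(expr, grid[k], config, "selection", init = warm)
    vals[k] <- res$msfe
    warm <- list(A = res$fit$A_hat)
  }
  best <- which.min(vals)  # grid ascending, so first minimum = smallest lambda
  out <- list(table = data.frame(lambda = grid, msfe = vals),
              best_lambda = grid[best], best_msfe = vals[best],
              T1 = s[["T1"]], T2 = s[["T2"]])
  if (isTRUE(holdout))
    out$holdout_msfe <- msfe(expr, grid[best], config, window = "holdout")
  structure(out, class = "lambda_selection")
}

#' @export
print.lambda_selection <- function(x, ...) {
  cat(sprintf("Budget selection over %d candidates (T1 = %d, T2 = %d):\n",
              nrow(x$table), x$T1, x$T2))
  tab <- x$table
  tab$msfe <- signif(tab$msfe, 6)
  print(tab, row.names = FALSE)
  cat(sprintf("selected lambda = %g (MSFE %.6g)\n", x$best_lambda, x$best_msfe))
  if (!is.null(x$holdout_msfe))
    cat(sprintf("holdout MSFE = %.6g\n", x$holdout_msfe))
  invisible(x)
}
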