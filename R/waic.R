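# WAIC (widely applicable information criterion) from pointwise posterior
# log-likelihoods. Shared by every model comparison in the package.

#' Compute WAIC from a draws x observations log-likelihood matrix
#'
#' lppd = sum_n log( mean_s exp(ll_sn) ), evaluated stably via log-sum-exp;
#' p_waic = sum_n var_s(ll_sn) with the sample variance (denominator S-1);
#' waic = -2 (lppd - p_waic). Lower is better. With a single draw the
#' penalty is zero.
#'
#' @param ll numeric matrix, rows = posterior draws, columns = observations
#' @return object of class `waic_result`: list(lppd, p_waic, waic,
#'   pointwise) where `pointwise` has per-observation lppd and penalty
#' @export
waic <- function(ll) {
  ll <- as.matrix(ll)
  if (!all(is.finite(ll))) stop("pointwise log-likelihoods must be finite")
  S <- nrow(ll)
  offset <- apply(ll, 2, max)
  lppd_i <- offset + log(colMeans(exp(sweep(ll, 2, offset)))) # log-mean-exp
  p_i <- if (S > 1L) apply(ll, 2, stats::var) else rep(0, ncol(ll))
  lppd <- sum(lppd_i)
  p_waic <- sum(p_i)
  structure(list(lppd = lppd, p_waic = p_waic,
                 waic = -2 * (lppd - p_waic),
                 pointwise = data.frame(lppd = lppd_i, p_waic = p_i)),
            class = "waic_result")
}

#' @export
print.waic_result <- function(x, ...) {
  cat(sprintf("WAIC %.2f  (lppd %.2f, p_waic %.2f, n = %d)\n",
              x$waic, x$lppd, x$p_waic, nrow(x$pointwise)))
  invisible(x)
}

#' Tabulate a set of fitted models by WAIC
#'
#' @param waics named numeric vector (or named list of `waic_result`) of
#'   WAIC values, one per model structure
#' @return data.frame of class `model_comparison` with columns
#'   `model_structure`, `waic`, `delta_waic`, sorted ascending; the best
#'   row's delta is 0
#' @export
comparison_table <- function(waics) {
  if (is.list(waics)) waics <- vapply(waics, function(w) w$waic, numeric(1))
  df <- data.frame(model_structure = names(waics), waic = unname(waics),
                   stringsAsFactors = FALSE)
  df <- df[order(df$waic), ]
  df$delta_waic <- df$waic - df$waic[1L]
  rownames(df) <- NULL
  class(df) <- c("model_comparison", "data.frame")
  df
}
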