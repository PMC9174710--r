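# Connectivity indices. All are exponential distance-decay kernel sums over
# the landscape: exp(-alpha * d) with d in km and alpha the inverse mean
# dispersal distance (default 1 km^-1, from mark-recapture estimates of
# ~1 km flights).

#' Kernel parameters for distance-decay connectivity
#' @param alpha inverse mean dispersal distance (km^-1), > 0
#' @return list of class `kernel_params`
#' @export
kernel_params <- function(alpha = 1) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  structure(list(alpha = alpha), class = "kernel_params")
}

#' Coefficients of the fitted hilltop moth-abundance prediction
#'
#' Log predicted moth count on a hilltop is
#' `intercept + slope_ci * scale(ln CI) + slope_elev * elevation_m`,
#' with defaults from the fitted hilltop abundance model (-0.89, 1.27, 0.02
#' per metre of elevation). Used by the elevation-weighted index so it is
#' defined in years and sites where adult counts are missing.
#'
#' @param intercept,slope_ci,slope_elev finite reals
#' @return list of class `moth_pred_coefs`
#' @export
moth_pred_coefs <- function(intercept = -0.89, slope_ci = 1.27,
                            slope_elev = 0.02) {
  stopifnot(is.finite(intercept), is.finite(slope_ci), is.finite(slope_elev))
  structure(list(intercept = intercept, slope_ci = slope_ci,
                 slope_elev = slope_elev), class = "moth_pred_coefs")
}

#' Predict log moth count on a hilltop
#' @param scaled_log_ci z-scored log connectivity of the hilltop to patches
#' @param elevation hilltop elevation (metres)
#' @param coefs a [moth_pred_coefs()]
#' @return predicted log adult count
#' @export
predict_log_moths <- function(scaled_log_ci, elevation,
                              coefs = moth_pred_coefs()) {
  coefs$intercept + coefs$slope_ci * scaled_log_ci +
    coefs$slope_elev * elevation
}

new_connectivity_matrix <- function(kind, values, scaler = NULL,
                                    params = kernel_params(), coefs = NULL) {
  structure(list(kind = kind, values = values, scaler = scaler,
                 params = params, coefs = coefs),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("connectivity_matrix [%s]: %d x %d, alpha = %g\n", x$kind,
              nrow(x$values), ncol(x$values), x$params$alpha))
  invisible(x)
}

kernel_pp <- function(land, params) {
  k <- exp(-params$alpha * land$d_pp)
  diag(k) <- 0  # self-excluded: a patch does not contribute to itself
  k
}
kernel_ph <- function(land, params) exp(-params$alpha * land$d_ph)

check_aligned <- function(values, ids, what) {
  if (nrow(values) != length(ids))
    stop(what, ": abundance matrix has ", nrow(values),
         " rows but landscape has ", length(ids))
}

# kernel %*% A with missing source cells excluded from the sum
kernel_sum <- function(K, A) {
  A0 <- A
  A0[is.na(A0)] <- 0
  K %*% A0
}

#' Hanski-style patch connectivity index (CI)
#'
#' For patch i in year t: sum over all other patches j of
#' exp(-alpha d_ij) * A_jt, where A is log abundance. Direct patch-to-patch
#' connectivity assuming random (distance-only) dispersal.
#'
#' @param land a [landscape()]
#' @param log_abund patch x year log-abundance matrix (rows in landscape
#'   patch order); missing cells are excluded from the sums
#' @param params a [kernel_params()]
#' @return a `connectivity_matrix` of kind "CI"
#' @export
hanski_ci <- function(land, log_abund, params = kernel_params()) {
  check_aligned(log_abund, land$patches$patch_id, "hanski_ci")
  v <- kernel_sum(kernel_pp(land, params), log_abund)
  dimnames(v) <- dimnames(log_abund)
  rownames(v) <- land$patches$patch_id
  new_connectivity_matrix("CI", v, params = params)
}

#' Hilltop-to-patch connectivity (the inner stage of HCI and ECI)
#'
#' For hilltop j in year t: sum over all patches k of exp(-alpha d_jk) A_kt.
#' No self-exclusion applies (hilltops are not patches). This is also the
#' connectivity covariate of the hilltop moth-abundance model.
#'
#' @inheritParams hanski_ci
#' @return hilltop x year matrix of unscaled kernel sums
#' @export
hilltop_patch_ci <- function(land, log_abund, params = kernel_params()) {
  check_aligned(log_abund, land$patches$patch_id, "hilltop_patch_ci")
  v <- kernel_sum(t(kernel_ph(land, params)), log_abund)
  rownames(v) <- land$hilltops$hilltop_id
  v
}

resolve_inner_scaler <- function(inner, inner_scaler, log, log_offset) {
  if (identical(inner_scaler, "fit"))
    fit_scaler(as.vector(inner), log = log, log_offset = log_offset)
  else inner_scaler
}

#' Hilltop-routed connectivity index (HCI)
#'
#' Moths move natal patch -> hilltop -> oviposition patch. For patch i:
#' sum over hilltops j of exp(-alpha d_ij) * z(sum_k exp(-alpha d_jk) A_kt),
#' where z() standardizes the inner hilltop sums across all hilltop-year
#' cells jointly (or with a supplied frozen scaler).
#'
#' @inheritParams hanski_ci
#' @param inner_scaler `"fit"` to standardize the inner sums on this data,
#'   or a frozen [fit_scaler()] result (e.g. from observed data, for
#'   simulation)
#' @return a `connectivity_matrix` of kind "HCI" carrying the scaler used
#' @export
hilltop_ci <- function(land, log_abund, params = kernel_params(),
                       inner_scaler = "fit") {
  if (nrow(land$hilltops) < 1L) stop("landscape has no hilltops")
  inner <- hilltop_patch_ci(land, log_abund, params)
  sc <- resolve_inner_scaler(inner, inner_scaler, log = FALSE, log_offset = 0)
  z <- apply_scaler(inner, sc)
  v <- kernel_ph(land, params) %*% z
  colnames(v) <- colnames(log_abund)
  new_connectivity_matrix("HCI", v, scaler = sc, params = params)
}

#' Elevation-weighted hilltop connectivity index (ECI)
#'
#' As [hilltop_ci()], but each hilltop's contribution is its predicted log
#' moth count rather than its standardized kernel sum: higher hilltops
#' attract more moths. Per hilltop-year, the hilltop-to-patch kernel sum is
#' offset-logged, standardized, passed through [predict_log_moths()], then
#' kernel-summed to patches. ECI can be negative.
#'
#' @inheritParams hilltop_ci
#' @param coefs a [moth_pred_coefs()]
#' @param log_offset offset used when logging the inner kernel sums
#' @return a `connectivity_matrix` of kind "ECI"
#' @export
elevation_ci <- function(land, log_abund, params = kernel_params(),
                         coefs = moth_pred_coefs(), inner_scaler = "fit",
                         log_offset = 1) {
  if (nrow(land$hilltops) < 1L) stop("landscape has no hilltops")
  inner <- hilltop_patch_ci(land, log_abund, params)
  if (any(inner + log_offset <= 0))
    stop("inner connectivity + log_offset must be positive for ECI")
  sc <- resolve_inner_scaler(inner, inner_scaler, log = TRUE,
                             log_offset = log_offset)
  m <- predict_log_moths(apply_scaler(inner, sc),
                         land$hilltops$elevation_m, coefs)
  v <- kernel_ph(land, params) %*% m
  colnames(v) <- colnames(log_abund)
  new_connectivity_matrix("ECI", v, scaler = sc, params = params,
                          coefs = coefs)
}

#' Patch exposure to hilltop moth aggregations
#'
#' Connectivity of each patch to observed adult abundance:
#' sum over hilltops j of exp(-alpha d_ij) * ln(count_jt + offset).
#' Hilltop-years with missing counts are excluded; years with no surveyed
#' hilltop at all are missing for every patch.
#'
#' @param land a [landscape()]
#' @param moths a [moth_panel()] (rows in landscape hilltop order)
#' @param params a [kernel_params()]
#' @param log_offset offset for logging counts
#' @return a `connectivity_matrix` of kind "HILLTOP_EXPOSURE"
#' @export
hilltop_exposure <- function(land, moths, params = kernel_params(),
                             log_offset = 1) {
  check_aligned(moths$count, land$hilltops$hilltop_id, "hilltop_exposure")
  la <- log(moths$count + log_offset)
  v <- kernel_sum(kernel_ph(land, params), la)
  all_missing <- apply(is.na(la), 2, all)
  v[, all_missing] <- NA_real_
  rownames(v) <- land$patches$patch_id
  new_connectivity_matrix("HILLTOP_EXPOSURE", v, params = params)
}

#' Compute a connectivity index by kind
#'
#' Dispatch helper used by the model grid and the simulator.
#'
#' @param kind one of "CI", "HCI", "ECI"
#' @param land a [landscape()]
#' @param log_abund patch x year log-abundance matrix
#' @param params a [kernel_params()]
#' @param coefs a [moth_pred_coefs()] (ECI only)
#' @param inner_scaler `"fit"` or a frozen scaler (HCI/ECI only)
#' @param log_offset log offset (ECI only)
#' @return a `connectivity_matrix`
#' @export
connectivity_index <- function(kind, land, log_abund,
                               params = kernel_params(),
                               coefs = moth_pred_coefs(),
                               inner_scaler = "fit", log_offset = 1) {
  switch(match.arg(kind, c("CI", "HCI", "ECI")),
    CI  = hanski_ci(land, log_abund, params),
    HCI = hilltop_ci(land, log_abund, params, inner_scaler),
    ECI = elevation_ci(land, log_abund, params, coefs, inner_scaler,
                       log_offset))
}

#' Export a connectivity matrix as a long CSV (`patch_id,year,kind,value`)
#' @param cm a `connectivity_matrix`
#' @param path destination
#' @export
write_connectivity <- function(cm, path) {
  df <- expand.grid(patch_id = rownames(cm$values),
                    year = as.integer(colnames(cm$values)),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$kind <- cm$kind
  df$value <- as.vector(cm$values)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(cm)
}
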