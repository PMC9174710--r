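# Hierarchical Bayesian models of adult moth counts on hilltops, and the
# log-normal model predicting next-spring caterpillar counts from patch
# exposure to hilltop aggregations. Both feed the WAIC comparisons.

#' Model structure for the hilltop moth-abundance GLMM
#' @param connectivity include the scaled log connectivity main effect?
#' @param elevation include the hilltop elevation main effect?
#' @param interaction include connectivity x elevation (requires both mains)?
#' @return list of class `moth_glmm_spec`
#' @export
moth_glmm_spec <- function(connectivity = TRUE, elevation = TRUE,
                           interaction = FALSE) {
  if (interaction && !(connectivity && elevation))
    stop("interaction requires both main effects")
  structure(list(connectivity = connectivity, elevation = elevation,
                 interaction = interaction), class = "moth_glmm_spec")
}

#' Assemble the observation frame for the hilltop moth GLMM
#'
#' Joins surveyed hilltop-year counts with the hilltop-to-patch connectivity
#' index (offset-logged then z-scored across all hilltop-year cells) and
#' hilltop elevations. Unsurveyed hilltop-years are dropped, not imputed.
#'
#' @param moths a [moth_panel()] (hilltops in landscape order)
#' @param land a [landscape()]
#' @param census a [census_panel()] supplying patch abundances for the
#'   connectivity index
#' @param params a [kernel_params()]
#' @param log_offset offset for log abundance and the log of the index
#' @return data.frame with columns `hilltop`, `year` (integer indices),
#'   `hilltop_id`, `count`, `z_ci`, `elev`; the fitted scaler is attached as
#'   attribute `"scaler"`
#' @export
build_moth_frame <- function(moths, land, census, params = kernel_params(),
                             log_offset = 1) {
  # surveyed moth years need not span the census years (whole unsurveyed
  # years are dropped from files), so align by year value
  if (!all(moths$years %in% census$years))
    stop("moth panel has years outside the census years")
  A <- log_abundance(census, log_offset)
  ci <- hilltop_patch_ci(land, A, params)
  sc <- fit_scaler(as.vector(ci), log = TRUE, log_offset = log_offset)
  z <- apply_scaler(ci, sc)
  year_of <- match(moths$years, census$years)
  idx <- which(!is.na(moths$count), arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("no surveyed hilltop-years")
  yr <- year_of[idx[, 2L]]
  df <- data.frame(
    hilltop = idx[, 1L], year = yr,
    hilltop_id = moths$hilltop_ids[idx[, 1L]],
    count = moths$count[idx], z_ci = z[cbind(idx[, 1L], yr)],
    elev = land$hilltops$elevation_m[idx[, 1L]],
    stringsAsFactors = FALSE)
  attr(df, "scaler") <- sc
  df
}

glmm_linpred <- function(params, frame) {
  eta <- params$a0 +
    params$b_ci * frame$z_ci +
    params$b_elev * frame$elev +
    params$b_int * frame$z_ci * frame$elev
  if (!is.null(params$u_hilltop)) eta <- eta + params$u_hilltop[frame$hilltop]
  if (!is.null(params$u_year)) eta <- eta + params$u_year[frame$year]
  eta
}

#' Pointwise Poisson log-likelihood for one GLMM parameter draw
#'
#' The linear predictor is on the log scale (canonical log link), so the
#' Poisson mean is exp(a0 + b_ci z + b_elev elev + b_int z elev +
#' u_hilltop + u_year).
#'
#' @param params list with `a0`, `b_ci`, `b_elev`, `b_int` (scalars; use 0
#'   for excluded terms) and `u_hilltop`, `u_year` (vectors indexed by the
#'   frame's `hilltop` / `year` columns, or NULL)
#' @param frame a [build_moth_frame()] result
#' @return per-observation log densities
#' @export
glmm_pointwise_loglik <- function(params, frame) {
  if (any(frame$count != round(frame$count)))
    stop("moth counts must be integers")
  if (any(frame$count < 0)) stop("moth counts must be nonnegative")
  dpois(frame$count, exp(glmm_linpred(params, frame)), log = TRUE)
}

# The elevation term is constant within hilltop, so it is fitted by
# hierarchical centering (the hilltop intercepts are drawn around
# b_elev * elevation) — the same model, but without the near-perfect
# posterior correlation between b_elev and the raw intercepts that cripples
# Gibbs mixing. The observation-level predictor then carries u_h directly.
moth_glmm_jags <- function(spec) {
  terms <- "a0"
  if (spec$connectivity) terms <- c(terms, "b_ci * z[n]")
  if (spec$interaction) terms <- c(terms, "b_int * z[n] * elev[n]")
  priors <- c("a0 ~ dnorm(0, 0.01)",
    if (spec$connectivity) "b_ci ~ dnorm(0, 0.01)",
    if (spec$elevation) "b_elev ~ dnorm(0, 0.01)",
    if (spec$interaction) "b_int ~ dnorm(0, 0.01)")
  mu_h <- if (spec$elevation) "b_elev * elevh[j]" else "0"
  # a0 centres the year intercepts (hierarchical centering again, for the
  # a0 <-> mean(u) confounding); the observation predictor drops a0.
  terms <- terms[terms != "a0"]
  obs_terms <- paste(c(terms, "u_h[h[n]]", "u_y[yr[n]]"), collapse = " + ")
  paste0("model {
  for (n in 1:N) {
    y[n] ~ dpois(lambda[n])
    log(lambda[n]) <- ", obs_terms, "
  }
  ", paste(priors, collapse = "\n  "), "
  for (j in 1:H) { u_h[j] ~ dnorm(", mu_h, ", tau_h) }
  for (t in 1:T) { u_y[t] ~ dnorm(a0, tau_y) }
  sd_h ~ dt(0, ", 1 / 2.7^2, ", 3) T(0.001,)
  sd_y ~ dt(0, ", 1 / 2.7^2, ", 3) T(0.001,)
  tau_h <- pow(sd_h, -2)
  tau_y <- pow(sd_y, -2)
}")
}

#' Fit the Bayesian Poisson GLMM of moth counts on hilltops
#'
#' Counts are Poisson with a log link; fixed effects get vague Normal(0, 10)
#' priors, hilltop and year random intercepts get half-Student-t(3, 0, 2.7)
#' scale hyperpriors. Pointwise log-likelihoods for WAIC are computed from
#' the retained draws.
#'
#' @param frame a [build_moth_frame()] result
#' @param spec a [moth_glmm_spec()]
#' @param config a [sampler_config()]
#' @return object of class `glmm_fit`: list(draws, pointwise_loglik,
#'   diagnostics, spec, frame)
#' @export
fit_moth_glmm <- function(frame, spec = moth_glmm_spec(),
                          config = sampler_config()) {
  if (length(unique(frame$hilltop)) < 2L || length(unique(frame$year)) < 2L)
    stop("need data from at least 2 hilltops and 2 years")
  H <- max(frame$hilltop); T <- max(frame$year)
  data <- list(N = nrow(frame), H = H, T = T, y = as.integer(frame$count),
               h = frame$hilltop, yr = frame$year)
  if (spec$connectivity || spec$interaction) data$z <- frame$z_ci
  if (spec$interaction) data$elev <- frame$elev
  if (spec$elevation) {
    elevh <- rep(0, H)  # hilltops with no surveys keep a prior-only intercept
    elevh[frame$hilltop] <- frame$elev
    data$elevh <- elevh
  }
  monitor <- c("a0", if (spec$connectivity) "b_ci",
               if (spec$elevation) "b_elev", if (spec$interaction) "b_int",
               "u_h", "u_y", "sd_h", "sd_y")
  fit <- run_jags(moth_glmm_jags(spec), data, monitor, config)
  warn_if_unconverged(fit$diagnostics, "moth GLMM")

  d <- fit$draws
  S <- nrow(d)
  eta <- matrix(0, S, nrow(frame))
  if (spec$connectivity) eta <- eta + d[, "b_ci"] %o% frame$z_ci
  if (spec$interaction) eta <- eta + d[, "b_int"] %o% (frame$z_ci * frame$elev)
  # u_h is centred on b_elev * elevation and u_y on a0, so the draws
  # already carry those effects
  eta <- eta + draw_block(d, "u_h", H)[, frame$hilltop, drop = FALSE]
  eta <- eta + draw_block(d, "u_y", T)[, frame$year, drop = FALSE]
  ll <- dpois(matrix(frame$count, S, nrow(frame), byrow = TRUE), exp(eta),
              log = TRUE)
  structure(list(draws = d, pointwise_loglik = ll,
                 diagnostics = fit$diagnostics, spec = spec, frame = frame),
            class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("glmm_fit: %d draws, %d observations, converged: %s\n",
              nrow(x$draws), ncol(x$pointwise_loglik),
              x$diagnostics$converged))
  invisible(x)
}

#' Posterior summary of a fitted model's named parameter
#' @param fit a fit with a `draws` matrix
#' @param par parameter name (a column of the draws matrix)
#' @param probs credible interval probabilities
#' @return list(mean, sd, lower, upper)
#' @export
posterior_summary <- function(fit, par, probs = c(0.05, 0.95)) {
  v <- fit$draws[, par]
  q <- stats::quantile(v, probs)
  list(mean = mean(v), sd = stats::sd(v), lower = q[[1L]], upper = q[[2L]])
}

#' Compare the five hilltop moth-abundance model structures by WAIC
#'
#' Fits connectivity+elevation, connectivity, elevation, intercept-only, and
#' the full model with the connectivity x elevation interaction; random
#' intercepts for hilltop and year are retained in every structure. A
#' structure whose sampler errors out is annotated with an NA WAIC rather
#' than aborting the table.
#'
#' @param frame a [build_moth_frame()] result
#' @param config a [sampler_config()]
#' @return list with `table` (a [comparison_table()]) and `fits`
#' @export
compare_moth_models <- function(frame, config = sampler_config()) {
  specs <- list(
    "Connectivity+Elevation" = moth_glmm_spec(TRUE, TRUE, FALSE),
    "Connectivity" = moth_glmm_spec(TRUE, FALSE, FALSE),
    "Elevation" = moth_glmm_spec(FALSE, TRUE, FALSE),
    "Intercept only" = moth_glmm_spec(FALSE, FALSE, FALSE),
    "Connectivity+Elevation+Connectivity:Elevation" =
      moth_glmm_spec(TRUE, TRUE, TRUE))
  fits <- lapply(specs, function(sp) {
    tryCatch(fit_moth_glmm(frame, sp, config), error = function(e) e)
  })
  w <- vapply(fits, function(f) {
    if (inherits(f, "error")) NA_real_ else waic(f$pointwise_loglik)$waic
  }, numeric(1))
  tab <- comparison_table(w[!is.na(w)])
  failed <- names(w)[is.na(w)]
  if (length(failed) > 0L) {
    extra <- data.frame(model_structure = failed, waic = NA_real_,
                        delta_waic = NA_real_)
    tab <- rbind(tab, extra)
    class(tab) <- c("model_comparison", "data.frame")
  }
  list(table = tab, fits = fits)
}

# --------------------------------------------------------------------------
# Back-prediction: hilltop exposure in year t -> caterpillars in year t+1
# --------------------------------------------------------------------------

patch_model_jags <- function(include_connectivity) {
  # year intercepts centred on a0 (hierarchical centering, see the GLMM)
  paste0("model {
  for (n in 1:N) {
    y[n] ~ dnorm(mu[n], tau)
    mu[n] <- ", if (include_connectivity) "b_ci * z[n] + ", "u_p[p[n]] + u_y[yr[n]]
  }
  a0 ~ dnorm(0, 0.01)
  ", if (include_connectivity) "b_ci ~ dnorm(0, 0.01)\n  ", "for (i in 1:P) { u_p[i] ~ dnorm(0, tau_p) }
  for (t in 1:T) { u_y[t] ~ dnorm(a0, tau_y) }
  sd_p ~ dt(0, ", 1 / 2.5^2, ", 3) T(0.001,)
  sd_y ~ dt(0, ", 1 / 2.5^2, ", 3) T(0.001,)
  sigma ~ dt(0, ", 1 / 2.5^2, ", 3) T(0.001,)
  tau_p <- pow(sd_p, -2)
  tau_y <- pow(sd_y, -2)
  tau <- pow(sigma, -2)
}")
}

#' Fit the log-normal model of next-year caterpillar counts on hilltop
#' exposure
#'
#' Response: ln(mean caterpillar count in patch i, year t+1, + offset).
#' Predictor: the patch's exposure to hilltop moth aggregations in year t,
#' offset-logged and z-scored. Patch and year random intercepts; residual
#' and random-effect scales get half-Student-t(3, 0, 2.5) priors.
#'
#' @param census a [census_panel()]
#' @param exposure a `connectivity_matrix` of kind "HILLTOP_EXPOSURE" on the
#'   same patches and years
#' @param include_connectivity drop the exposure term for the intercept-only
#'   reduction used in WAIC comparison
#' @param config a [sampler_config()]
#' @param log_offset offset for the response log and the predictor log
#' @return object of class `glmm_fit` (normal likelihood); the frame and the
#'   predictor scaler are attached
#' @export
fit_hilltop_to_patch_model <- function(census, exposure,
                                       include_connectivity = TRUE,
                                       config = sampler_config(),
                                       log_offset = 1) {
  if (exposure$kind != "HILLTOP_EXPOSURE")
    stop("exposure must be a HILLTOP_EXPOSURE connectivity matrix")
  Tn <- length(census$years)
  ex <- exposure$values
  y_next <- log(census$mean_count + log_offset)
  rows <- list()
  sc <- fit_scaler(as.vector(ex), log = TRUE, log_offset = log_offset)
  for (t in seq_len(Tn - 1L)) {
    ok <- !is.na(ex[, t]) & !is.na(y_next[, t + 1L])
    if (!any(ok)) next
    rows[[length(rows) + 1L]] <- data.frame(
      patch = which(ok), year = t,
      y = y_next[ok, t + 1L], z = apply_scaler(ex[ok, t], sc))
  }
  frame <- do.call(rbind, rows)
  if (is.null(frame) || length(unique(frame$year)) < 2L)
    stop("need usable exposure/census pairs from at least 2 years")
  P <- max(frame$patch); T <- max(frame$year)
  data <- list(N = nrow(frame), P = P, T = T, y = frame$y, p = frame$patch,
               yr = frame$year)
  if (include_connectivity) data$z <- frame$z
  monitor <- c("a0", if (include_connectivity) "b_ci", "u_p", "u_y",
               "sd_p", "sd_y", "sigma")
  fit <- run_jags(patch_model_jags(include_connectivity), data, monitor,
                  config)
  warn_if_unconverged(fit$diagnostics, "hilltop-to-patch model")
  d <- fit$draws
  S <- nrow(d)
  mu <- matrix(0, S, nrow(frame))  # a0 lives inside the u_y draws
  if (include_connectivity) mu <- mu + d[, "b_ci"] %o% frame$z
  mu <- mu + draw_block(d, "u_p", P)[, frame$patch, drop = FALSE]
  mu <- mu + draw_block(d, "u_y", T)[, frame$year, drop = FALSE]
  ll <- dnorm(matrix(frame$y, S, nrow(frame), byrow = TRUE), mu,
              matrix(d[, "sigma"], S, nrow(frame)), log = TRUE)
  structure(list(draws = d, pointwise_loglik = ll,
                 diagnostics = fit$diagnostics,
                 spec = list(connectivity = include_connectivity),
                 frame = frame, scaler = sc),
            class = "glmm_fit")
}

#' WAIC comparison of the back-prediction model against its intercept-only
#' reduction
#' @inheritParams fit_hilltop_to_patch_model
#' @return list with `table` and `fits`
#' @export
compare_patch_models <- function(census, exposure,
                                 config = sampler_config(),
                                 log_offset = 1) {
  fits <- list(
    "Connectivity" = fit_hilltop_to_patch_model(census, exposure, TRUE,
                                                config, log_offset),
    "Intercept only" = fit_hilltop_to_patch_model(census, exposure, FALSE,
                                                  config, log_offset))
  w <- vapply(fits, function(f) waic(f$pointwise_loglik)$waic, numeric(1))
  list(table = comparison_table(w), fits = fits)
}
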