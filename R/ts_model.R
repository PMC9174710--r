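# Gompertz AR(2) log-linear time-series model of patch censuses: density
# dependence acts on log abundance, with climate covariates at lag one, an
# optional connectivity term, patch random intercepts, and patch-specific
# residual variances.

#' Model structure for the caterpillar time-series model
#'
#' AR(1), AR(2) terms and patch random intercepts are always present; the
#' flags control the covariates. The precipitation x temperature interaction
#' requires both mains.
#'
#' @param precip,temp,interaction,connectivity inclusion flags
#' @param connectivity_kind which index drives the connectivity covariate
#' @return list of class `ts_model_spec`
#' @export
ts_model_spec <- function(precip = TRUE, temp = TRUE, interaction = TRUE,
                          connectivity = TRUE,
                          connectivity_kind = c("CI", "HCI", "ECI")) {
  if (interaction && !(precip && temp))
    stop("interaction requires both precip and temp")
  connectivity_kind <- if (connectivity) match.arg(connectivity_kind) else NA
  structure(list(precip = precip, temp = temp, interaction = interaction,
                 connectivity = connectivity,
                 connectivity_kind = connectivity_kind),
            class = "ts_model_spec")
}

ts_spec_label <- function(spec) {
  parts <- c(if (spec$precip) "Precip", if (spec$temp) "Temp",
             if (spec$interaction) "Precip:Temp",
             if (spec$connectivity) "Connectivity")
  if (length(parts) == 0L) "AR only" else paste(parts, collapse = "+")
}

# Scaling convention per index: CI is a nonnegative kernel sum and is
# logged then z-scored (its exponential kernel makes the raw scale very
# skewed); HCI and ECI aggregate standardized inner terms, are
# sign-indefinite, and are z-scored without a log.
conn_covariate_scaler <- function(values, kind, log_offset = 1) {
  fit_scaler(as.vector(values), log = kind == "CI", log_offset = log_offset)
}

#' Build the regression frame for the time-series model
#'
#' One row per usable (patch, year): the response is offset-logged mean
#' count in year t, with lags at t-1 and t-2, z-scored climate covariates at
#' t-1 (their interaction formed from the z-scored terms), and the scaled
#' connectivity index computed from abundances at t-1. The first two census
#' years are consumed as initial conditions.
#'
#' @param census a [census_panel()]
#' @param climate a [climate_series()] covering the census years
#' @param connectivity a `connectivity_matrix` on the census patches/years
#'   (required when `spec$connectivity`), computed from the same censuses
#' @param spec a [ts_model_spec()]
#' @param scalers optional list with `precip`, `temp`, `conn` scalers to
#'   freeze; missing entries are fitted here and returned
#' @param log_offset offset for the response log
#' @param X optional patch x year log-abundance matrix overriding the
#'   offset-logged census (e.g. a generator's latent layer, for recovery
#'   studies free of observation error)
#' @return data.frame with columns `patch`, `patch_id`, `year`, `x`,
#'   `x_lag1`, `x_lag2`, `precip`, `temp`, `precip_temp`, `conn`; scalers
#'   attached as attribute `"scalers"`
#' @export
build_ts_design <- function(census, climate, connectivity = NULL,
                            spec = ts_model_spec(), scalers = list(),
                            log_offset = 1, X = NULL) {
  yrs <- census$years
  if (any(diff(yrs) != 1L)) stop("census years must be contiguous")
  if (length(yrs) < 3L) stop("AR(2) needs at least 3 census years")
  if (!all(yrs %in% climate$years))
    stop("climate series must cover all census years")
  if (is.null(X)) X <- log(census$mean_count + log_offset)
  stopifnot(all(dim(X) == dim(census$mean_count)))
  P <- length(census$patch_ids)

  ci <- match(yrs, climate$years)
  if (is.null(scalers$precip))
    scalers$precip <- fit_scaler(climate$precip[ci])
  if (is.null(scalers$temp))
    scalers$temp <- fit_scaler(climate$temp[ci])
  pz <- apply_scaler(climate$precip[ci], scalers$precip)
  tz <- apply_scaler(climate$temp[ci], scalers$temp)

  cz <- NULL
  if (spec$connectivity) {
    if (is.null(connectivity)) stop("spec includes connectivity but none given")
    if (is.null(scalers$conn))
      scalers$conn <- conn_covariate_scaler(connectivity$values,
                                            connectivity$kind, log_offset)
    cz <- apply_scaler(connectivity$values, scalers$conn)
  }

  tt <- seq(3L, length(yrs))  # response years; t-1, t-2 available
  frame <- data.frame(
    patch = rep(seq_len(P), times = length(tt)),
    patch_id = rep(census$patch_ids, times = length(tt)),
    year = rep(yrs[tt], each = P),
    x = as.vector(X[, tt]),
    x_lag1 = as.vector(X[, tt - 1L]),
    x_lag2 = as.vector(X[, tt - 2L]),
    precip = rep(pz[tt - 1L], each = P),
    temp = rep(tz[tt - 1L], each = P),
    stringsAsFactors = FALSE)
  frame$precip_temp <- frame$precip * frame$temp
  frame$conn <- if (spec$connectivity) as.vector(cz[, tt - 1L]) else 0
  keep <- stats::complete.cases(frame[, c("x", "x_lag1", "x_lag2")])
  frame <- frame[keep, ]
  attr(frame, "scalers") <- scalers
  attr(frame, "spec") <- spec
  frame
}

ts_linpred <- function(params, frame) {
  params$a0 + params$a1 * frame$x_lag1 + params$a2 * frame$x_lag2 +
    params$b_precip * frame$precip + params$b_temp * frame$temp +
    params$b_int * frame$precip_temp + params$b_conn * frame$conn +
    params$alpha_patch[frame$patch]
}

#' Pointwise normal log-likelihood for one time-series parameter draw
#'
#' @param params list with scalars `a0`, `a1`, `a2`, `b_precip`, `b_temp`,
#'   `b_int`, `b_conn` (0 for excluded terms), vector `alpha_patch`, and
#'   vector `sigma` of positive patch-specific residual sds
#' @param frame a [build_ts_design()] result
#' @return per-row log densities
#' @export
ts_pointwise_loglik <- function(params, frame) {
  sig <- params$sigma[frame$patch]
  if (any(sig <= 0)) stop("sigma must be positive")
  dnorm(frame$x, ts_linpred(params, frame), sig, log = TRUE)
}

ts_jags <- function(spec) {
  terms <- c("a0", "a1 * x1[n]", "a2 * x2[n]")
  pri <- c("a0 ~ dnorm(0, 0.01)", "a1 ~ dnorm(0, 0.01)",
           "a2 ~ dnorm(0, 0.01)")
  if (spec$precip) { terms <- c(terms, "b_precip * pr[n]")
                     pri <- c(pri, "b_precip ~ dnorm(0, 0.01)") }
  if (spec$temp) { terms <- c(terms, "b_temp * tm[n]")
                   pri <- c(pri, "b_temp ~ dnorm(0, 0.01)") }
  if (spec$interaction) { terms <- c(terms, "b_int * prtm[n]")
                          pri <- c(pri, "b_int ~ dnorm(0, 0.01)") }
  if (spec$connectivity) { terms <- c(terms, "b_conn * cn[n]")
                           pri <- c(pri, "b_conn ~ dnorm(0, 0.01)") }
  # patch intercepts centred on a0 (hierarchical centering: removes the
  # a0 <-> mean(alpha) posterior correlation that slows Gibbs mixing)
  terms <- terms[terms != "a0"]
  paste0("model {
  for (n in 1:N) {
    y[n] ~ dnorm(mu[n], tau[p[n]])
    mu[n] <- ", paste(terms, collapse = " + "), " + alpha[p[n]]
  }
  ", paste(pri, collapse = "\n  "), "
  for (i in 1:P) {
    alpha[i] ~ dnorm(a0, tau_site)
    sigma[i] ~ dt(0, 0.04, 1) T(0.001,)
    tau[i] <- pow(sigma[i], -2)
  }
  sd_site ~ dt(0, 0.04, 1) T(0.001,)
  tau_site <- pow(sd_site, -2)
}")
}

#' Fit the hierarchical AR(2) time-series model
#'
#' Fixed effects get Normal(0, 10) priors; patch-specific residual sds and
#' the patch random-intercept sd get half-Cauchy(0, 5) priors. Pointwise
#' log-likelihoods for WAIC are computed from the retained draws.
#'
#' @param frame a [build_ts_design()] result
#' @param spec a [ts_model_spec()] (defaults to the one attached to the
#'   frame)
#' @param config a [sampler_config()]
#' @return object of class `ts_fit`: list(draws, pointwise_loglik,
#'   diagnostics, spec, frame)
#' @export
fit_ts_model <- function(frame, spec = attr(frame, "spec"),
                         config = sampler_config()) {
  if (nrow(frame) == 0L) stop("empty design frame")
  P <- max(frame$patch)
  data <- list(N = nrow(frame), P = P, y = frame$x, x1 = frame$x_lag1,
               x2 = frame$x_lag2, p = frame$patch)
  if (spec$precip) data$pr <- frame$precip
  if (spec$temp) data$tm <- frame$temp
  if (spec$interaction) data$prtm <- frame$precip_temp
  if (spec$connectivity) data$cn <- frame$conn
  monitor <- c("a0", "a1", "a2", if (spec$precip) "b_precip",
               if (spec$temp) "b_temp", if (spec$interaction) "b_int",
               if (spec$connectivity) "b_conn", "alpha", "sigma", "sd_site")
  # start the scales at 1: half-Cauchy tails can otherwise initialize far
  # enough out for the first likelihood evaluation to underflow
  fit <- run_jags(ts_jags(spec), data, monitor, config,
                  inits = list(sigma = rep(1, P), sd_site = 1))
  warn_if_unconverged(fit$diagnostics, "time-series model")
  d <- fit$draws
  S <- nrow(d)
  getcol <- function(nm) if (nm %in% colnames(d)) d[, nm] else rep(0, S)
  # alpha draws are centred on a0 and carry it
  mu <- d[, "a1"] %o% frame$x_lag1 + d[, "a2"] %o% frame$x_lag2 +
    getcol("b_precip") %o% frame$precip + getcol("b_temp") %o% frame$temp +
    getcol("b_int") %o% frame$precip_temp + getcol("b_conn") %o% frame$conn +
    draw_block(d, "alpha", P)[, frame$patch, drop = FALSE]
  sig <- draw_block(d, "sigma", P)[, frame$patch, drop = FALSE]
  ll <- dnorm(matrix(frame$x, S, nrow(frame), byrow = TRUE), mu, sig,
              log = TRUE)
  structure(list(draws = d, pointwise_loglik = ll,
                 diagnostics = fit$diagnostics, spec = spec, frame = frame),
            class = "ts_fit")
}

#' @export
print.ts_fit <- function(x, ...) {
  cat(sprintf("ts_fit [%s]: %d draws, %d rows, converged: %s\n",
              ts_spec_label(x$spec), nrow(x$draws),
              ncol(x$pointwise_loglik), x$diagnostics$converged))
  invisible(x)
}

#' Posterior-mean point parameters from a fitted time-series model
#'
#' Packs posterior means into the parameter list the simulator consumes.
#' @param fit a `ts_fit`
#' @return a [ts_params()] list
#' @export
ts_posterior_means <- function(fit) {
  d <- fit$draws
  P <- max(fit$frame$patch)
  getm <- function(nm) if (nm %in% colnames(d)) mean(d[, nm]) else 0
  # alpha draws include a0 (hierarchical centering); re-centre for the
  # a0 + alpha_patch parameterization the simulator uses
  ts_params(a0 = getm("a0"), a1 = getm("a1"), a2 = getm("a2"),
            b_precip = getm("b_precip"), b_temp = getm("b_temp"),
            b_int = getm("b_int"), b_conn = getm("b_conn"),
            alpha_patch = colMeans(draw_block(d, "alpha", P)) - getm("a0"),
            sigma = colMeans(draw_block(d, "sigma", P)))
}

#' Is an AR(2) pair stationary?
#'
#' Diagnostic only: reports whether the characteristic roots of
#' 1 - a1 z - a2 z^2 lie outside the unit circle (equivalently the
#' stationarity triangle conditions on a1, a2).
#' @param a1,a2 direct and delayed density-dependence coefficients
#' @return logical
#' @export
ar2_stationary <- function(a1, a2) {
  roots <- polyroot(c(1, -a1, -a2))
  all(Mod(roots) > 1)
}

ts_grid_structures <- function() {
  list(
    list(label = "Precip+Temp+Precip:Temp+Connectivity",
         precip = TRUE, temp = TRUE, interaction = TRUE, conn = TRUE),
    list(label = "Precip+Temp+Precip:Temp",
         precip = TRUE, temp = TRUE, interaction = TRUE, conn = FALSE),
    list(label = "Precip+Temp+Connectivity",
         precip = TRUE, temp = TRUE, interaction = FALSE, conn = TRUE),
    list(label = "Precip+Temp",
         precip = TRUE, temp = TRUE, interaction = FALSE, conn = FALSE),
    list(label = "Temp+Connectivity",
         precip = FALSE, temp = TRUE, interaction = FALSE, conn = TRUE),
    list(label = "Temp",
         precip = FALSE, temp = TRUE, interaction = FALSE, conn = FALSE),
    list(label = "Precip+Connectivity",
         precip = TRUE, temp = FALSE, interaction = FALSE, conn = TRUE),
    list(label = "Precip",
         precip = TRUE, temp = FALSE, interaction = FALSE, conn = FALSE),
    list(label = "Connectivity",
         precip = FALSE, temp = FALSE, interaction = FALSE, conn = TRUE))
}

#' WAIC grid over the nine time-series model structures
#'
#' Fits every combination of the climate covariates with and without a
#' connectivity term (AR terms and random effects retained throughout).
#' Each connectivity-containing structure is fitted three times — with the
#' direct (CI), hilltop-routed (HCI) and elevation-weighted (ECI) indices —
#' and reported at its best variant, alongside the CI-ECI and HCI-ECI WAIC
#' differences.
#'
#' @param census a [census_panel()]
#' @param climate a [climate_series()]
#' @param land a [landscape()]
#' @param config a [sampler_config()]
#' @param params a [kernel_params()]
#' @param coefs a [moth_pred_coefs()]
#' @param log_offset log offset for abundances
#' @return list with `table` (columns `model_structure`, `waic`,
#'   `delta_waic`, `ci_minus_eci`, `hci_minus_eci`, sorted ascending) and
#'   `fits` (per structure/variant)
#' @export
compare_ts_models <- function(census, climate, land,
                              config = sampler_config(),
                              params = kernel_params(),
                              coefs = moth_pred_coefs(), log_offset = 1) {
  A <- log_abundance(census, log_offset)
  conns <- list(CI = hanski_ci(land, A, params),
                HCI = hilltop_ci(land, A, params),
                ECI = elevation_ci(land, A, params, coefs,
                                   log_offset = log_offset))
  fit_one <- function(st, kind) {
    sp <- ts_model_spec(st$precip, st$temp, st$interaction, st$conn,
                        if (st$conn) kind else "CI")
    frame <- build_ts_design(census, climate,
                             if (st$conn) conns[[kind]] else NULL,
                             sp, log_offset = log_offset)
    tryCatch(fit_ts_model(frame, sp, config), error = function(e) e)
  }
  rows <- list(); fits <- list()
  for (st in ts_grid_structures()) {
    if (st$conn) {
      vw <- sapply(c("CI", "HCI", "ECI"), function(k) {
        f <- fit_one(st, k)
        fits[[paste(st$label, k, sep = " / ")]] <<- f
        if (inherits(f, "error")) NA_real_ else waic(f$pointwise_loglik)$waic
      })
      rows[[st$label]] <- data.frame(
        model_structure = st$label, waic = suppressWarnings(min(vw, na.rm = TRUE)),
        ci_minus_eci = vw[["CI"]] - vw[["ECI"]],
        hci_minus_eci = vw[["HCI"]] - vw[["ECI"]])
    } else {
      f <- fit_one(st, "CI")
      fits[[st$label]] <- f
      w <- if (inherits(f, "error")) NA_real_ else waic(f$pointwise_loglik)$waic
      rows[[st$label]] <- data.frame(model_structure = st$label, waic = w,
                                     ci_minus_eci = NA_real_,
                                     hci_minus_eci = NA_real_)
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$waic), ]
  tab$delta_waic <- tab$waic - tab$waic[1L]
  tab <- tab[, c("model_structure", "waic", "delta_waic", "ci_minus_eci",
                 "hci_minus_eci")]
  rownames(tab) <- NULL
  class(tab) <- c("model_comparison", "data.frame")
  list(table = tab, fits = fits)
}
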