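# Internal MCMC plumbing shared by all hierarchical model fits.
# Models are sampled with JAGS through rjags; convergence is assessed with
# the Gelman-Rubin statistic and effective sample sizes from coda.

#' Sampler configuration for the Bayesian model fits
#'
#' @param chains number of MCMC chains (>= 2 for convergence diagnostics)
#' @param adapt adaptation iterations
#' @param burn burn-in iterations discarded after adaptation
#' @param iter retained iterations per chain
#' @param thin thinning interval
#' @param seed integer seed; every chain gets a deterministic RNG stream
#'   derived from it
#' @return list of class `sampler_config`
#' @export
sampler_config <- function(chains = 2, adapt = 1000, burn = 1000,
                           iter = 2000, thin = 1, seed = 1) {
  stopifnot(chains >= 1, iter >= 1, seed == round(seed))
  structure(list(chains = chains, adapt = adapt, burn = burn, iter = iter,
                 thin = thin, seed = as.integer(seed)),
            class = "sampler_config")
}

# Run a JAGS model and return a draws matrix plus diagnostics.
# `monitor` names the nodes to keep; pointwise log-likelihoods are computed
# by the caller in R from the draws.
run_jags <- function(model_string, data, monitor, config, inits = list()) {
  inits <- lapply(seq_len(config$chains), function(ch) {
    c(list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = config$seed + 1000L * ch),
      inits)
  })
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = config$chains,
                          n.adapt = config$adapt, quiet = TRUE)
  if (config$burn > 0) stats::update(jm, n.iter = config$burn,
                                     progress.bar = "none")
  samp <- rjags::coda.samples(jm, variable.names = monitor,
                              n.iter = config$iter, thin = config$thin,
                              progress.bar = "none")
  draws <- as.matrix(samp)
  diag <- mcmc_diagnostics(samp)
  list(draws = draws, samples = samp, diagnostics = diag)
}

mcmc_diagnostics <- function(samp) {
  ess <- tryCatch(coda::effectiveSize(samp), error = function(e) NULL)
  rhat <- NULL
  if (coda::nchain(samp) >= 2) {
    keep <- apply(as.matrix(samp), 2, function(v) stats::sd(v) > 1e-12)
    rhat <- tryCatch({
      gd <- coda::gelman.diag(samp[, keep, drop = FALSE],
                              multivariate = FALSE, autoburnin = FALSE)
      gd$psrf[, 1L]
    }, error = function(e) NULL)
  }
  converged <- is.null(rhat) || all(is.na(rhat) | rhat < 1.05)
  list(rhat = rhat, ess = ess, converged = converged)
}

warn_if_unconverged <- function(diag, label) {
  if (!diag$converged)
    warning(sprintf("%s: Gelman-Rubin statistic >= 1.05 for %d parameter(s); treat this fit as unconverged",
                    label, sum(diag$rhat >= 1.05, na.rm = TRUE)),
            call. = FALSE)
  invisible(diag)
}

# Extract a draws sub-matrix for a vector-valued node, ordered by index.
draw_block <- function(draws, name, n) {
  if (n == 0L) return(matrix(0, nrow(draws), 0L))
  cols <- paste0(name, "[", seq_len(n), "]")
  missing <- setdiff(cols, colnames(draws))
  if (length(missing) > 0L)
    stop("draws are missing monitored node(s): ",
         paste(missing, collapse = ", "))
  draws[, cols, drop = FALSE]
}
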