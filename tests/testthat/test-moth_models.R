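# Hilltop moth GLMM and the hilltop-to-patch back-prediction model.
# Replicate loops use short chains; convergence warnings there are expected
# and suppressed, the assertions being about posterior location.

# one shared synthetic world; per-test moth panels are redrawn from it
moth_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- gen_bundle(make_bodega_like_scenario(21))
    cache
  }
})

moth_test_frame <- function(seed, b_ci = 1.27, b_elev = 0.02,
                            missing_years = NULL) {
  b <- moth_world()
  eff <- list(a0 = -0.89, b_ci = b_ci, b_elev = b_elev,
              sd_hilltop = 0.3, sd_year = 0.3)
  m <- gen_moth_counts(b$landscape, b$census$panel, eff, seed,
                       missing_years)
  build_moth_frame(m$panel, b$landscape, b$census$panel)
}

test_that("Poisson pointwise log-likelihood matches direct pmf evaluation", {
  frame <- data.frame(hilltop = c(1L, 1L, 2L), year = c(1L, 2L, 1L),
                      count = c(0, 1, 4), z_ci = c(0.5, -1, 0),
                      elev = c(30, 30, 80))
  null_params <- list(a0 = 0, b_ci = 0, b_elev = 0, b_int = 0,
                      u_hilltop = NULL, u_year = NULL)
  ll0 <- glmm_pointwise_loglik(null_params, frame)
  # all coefficients zero: Poisson(1), so counts 0 and 1 both have density e^-1
  expect_equal(ll0[1], -1)
  expect_equal(ll0[2], -1)

  params <- list(a0 = 0.4, b_ci = 0.9, b_elev = 0.01, b_int = -0.002,
                 u_hilltop = c(0.2, -0.1), u_year = c(0.05, -0.3))
  eta <- params$a0 + params$b_ci * frame$z_ci +
    params$b_elev * frame$elev + params$b_int * frame$z_ci * frame$elev +
    params$u_hilltop[frame$hilltop] + params$u_year[frame$year]
  manual <- frame$count * eta - exp(eta) - lfactorial(frame$count)
  expect_equal(glmm_pointwise_loglik(params, frame), manual,
               tolerance = 1e-12)

  frame$count[1] <- 0.5
  expect_error(glmm_pointwise_loglik(params, frame), "integer")
})

test_that("moth GLMM recovers a strong elevation effect and Poisson rate", {
  frame <- moth_test_frame(21)
  fit <- suppressWarnings(fit_moth_glmm(frame,
                                        config = sampler_config(seed = 5)))
  ps <- posterior_summary(fit, "b_elev")
  expect_lt(abs(ps$mean - 0.02), 2 * ps$sd)
  ps_ci <- posterior_summary(fit, "b_ci")
  expect_lt(abs(ps_ci$mean - 1.27), 2 * ps_ci$sd)
  expect_true(all(is.finite(fit$pointwise_loglik)))
  w <- waic(fit$pointwise_loglik)
  expect_equal(w$waic, -2 * (w$lppd - w$p_waic), tolerance = 1e-10)

  # intercept-only fit on near-homogeneous Poisson counts recovers the rate
  lam <- 6
  set.seed(8)
  counts <- matrix(rpois(7 * 10, lam), 7, 10,
                   dimnames = list(sprintf("H%d", 1:7), 2001:2010))
  frame0 <- data.frame(hilltop = rep(1:7, 10),
                       year = rep(1:10, each = 7),
                       count = as.vector(counts), z_ci = 0, elev = 0)
  fit0 <- suppressWarnings(
    fit_moth_glmm(frame0, moth_glmm_spec(FALSE, FALSE, FALSE),
                  quick_sampler(3)))
  expect_equal(mean(exp(fit0$draws[, "a0"])), lam, tolerance = 0.15)
})

test_that("posterior predictive draws from the GLMM are nonnegative integers", {
  frame <- moth_test_frame(22)
  fit <- suppressWarnings(fit_moth_glmm(frame, config = quick_sampler(4)))
  d <- fit$draws[1:50, ]
  H <- max(frame$hilltop); Tn <- max(frame$year)
  set.seed(1)
  for (s in 1:50) {
    eta <- d[s, "b_ci"] * frame$z_ci +
      d[s, paste0("u_h[", frame$hilltop, "]")] +
      d[s, paste0("u_y[", frame$year, "]")]
    y_rep <- rpois(length(eta), exp(eta))
    expect_true(all(y_rep >= 0 & y_rep == round(y_rep)))
  }
})

test_that("90% intervals for a null connectivity effect calibrate", {
  covered <- 0
  for (r in 1:20) {
    frame <- moth_test_frame(300 + r, b_ci = 0)
    fit <- suppressWarnings(
      fit_moth_glmm(frame, config = quick_sampler(r)))
    ps <- posterior_summary(fit, "b_ci", probs = c(0.05, 0.95))
    covered <- covered + (ps$lower <= 0 && 0 <= ps$upper)
  }
  expect_gte(covered, 17)
})

test_that("WAIC ranks the generating structure above intercept-only", {
  wins <- 0
  for (r in 1:20) {
    frame <- moth_test_frame(500 + r)
    cmp <- suppressWarnings(
      compare_moth_models(frame, sampler_config(2, 400, 400, 800, 1, r)))
    tab <- cmp$table
    rank_ce <- match("Connectivity+Elevation", tab$model_structure)
    rank_i0 <- match("Intercept only", tab$model_structure)
    wins <- wins + (rank_ce < rank_i0)
    if (r == 1) {
      expect_equal(tab$delta_waic[1], 0)
      expect_true(all(diff(tab$waic[!is.na(tab$waic)]) >= 0))
      expect_setequal(
        tab$model_structure,
        c("Connectivity+Elevation", "Connectivity", "Elevation",
          "Intercept only",
          "Connectivity+Elevation+Connectivity:Elevation"))
    }
  }
  expect_gte(wins, 16)
})

test_that("back-prediction model: noiseless recovery and null comparison", {
  sc <- make_bodega_like_scenario(31)
  b <- gen_bundle(sc)
  ex <- hilltop_exposure(b$landscape, b$moths$panel)

  # response manufactured from the scaled exposure itself: slope near 1
  sc_ex <- fit_scaler(as.vector(ex$values), log = TRUE, log_offset = 1)
  z <- apply_scaler(ex$values, sc_ex)
  fake <- b$census$panel
  fake$mean_count[, -1] <- exp(2 + z[, -ncol(z)]) - 1
  fake$mean_count[which(fake$mean_count < 0)] <- 0
  fake$mean_count[, 1] <- 1
  fit <- suppressWarnings(
    fit_hilltop_to_patch_model(fake, ex, config = sampler_config(seed = 6)))
  ps <- posterior_summary(fit, "b_ci")
  expect_lt(abs(ps$mean - 1), max(2 * ps$sd, 0.1))

  # null data: connectivity model close to intercept-only by WAIC
  small_deltas <- 0
  for (r in 1:5) {
    set.seed(700 + r)
    null_cen <- b$census$panel
    null_cen$mean_count[] <- exp(rnorm(length(null_cen$mean_count),
                                       1, 0.5)) - 1
    null_cen$mean_count[null_cen$mean_count < 0] <- 0
    cmp <- suppressWarnings(
      compare_patch_models(null_cen, ex, quick_sampler(r)))
    d <- abs(diff(cmp$table$waic))
    small_deltas <- small_deltas + (d < 4)
  }
  expect_gte(small_deltas, 3)
})

test_that("null connectivity effect calibrates in the back-prediction model", {
  sc <- make_bodega_like_scenario(33)
  b <- gen_bundle(sc)
  ex <- hilltop_exposure(b$landscape, b$moths$panel)
  covered <- 0
  for (r in 1:20) {
    set.seed(800 + r)
    cen <- b$census$panel
    cen$mean_count[] <- exp(rnorm(length(cen$mean_count), 1, 0.5)) - 1
    cen$mean_count[cen$mean_count < 0] <- 0
    fit <- suppressWarnings(
      fit_hilltop_to_patch_model(cen, ex, config = quick_sampler(r)))
    ps <- posterior_summary(fit, "b_ci", probs = c(0.05, 0.95))
    covered <- covered + (ps$lower <= 0 && 0 <= ps$upper)
  }
  expect_gte(covered, 17)
})
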