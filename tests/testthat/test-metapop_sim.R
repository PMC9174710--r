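# Metapopulation simulator and its summary statistics.

test_that("step means evaluate the linear predictor on the log scale", {
  p0 <- ts_params()
  expect_equal(step_means(0, 0, 0, 0, 0, p0), 1)
  p1 <- ts_params(a1 = 1)
  expect_equal(step_means(log(5), 0, 0, 0, 0, p1), 5)

  p <- ts_params(a0 = 0.5, a1 = 0.6, a2 = -0.2, b_precip = 0.3,
                 b_temp = 0.2, b_int = -0.1, b_conn = 0.15,
                 alpha_patch = 0.1)
  expect_equal(step_means(log(4), log(2), 0.5, -1, 0.8, p), 4.109,
               tolerance = 1e-3)
  p_bad <- ts_params(a0 = Inf)
  expect_error(step_means(0, 0, 0, 0, 0, p_bad, patch_ids = "P07"), "P07")
})

test_that("occupancy, colonization and extinction match transition counts", {
  m <- rbind(c(0, 2, 0, 1), c(1, 1, 0, 0))
  expect_equal(occupancy(m), 0.5)
  expect_equal(colonization_rate(m), 2 / 3)
  expect_equal(extinction_rate(m), 2 / 3)

  all_on <- matrix(1, 2, 4)
  expect_equal(occupancy(all_on), 1)
  expect_equal(extinction_rate(all_on), 0)
  expect_true(is.na(colonization_rate(all_on)))

  all_off <- matrix(0, 2, 4)
  expect_equal(occupancy(all_off), 0)
  expect_equal(colonization_rate(all_off), 0)
  expect_true(is.na(extinction_rate(all_off)))
})

test_that("regional synchrony is the mean pairwise log-scale correlation", {
  m_same <- rbind(1:4, 1:4, 1:4)
  expect_equal(regional_synchrony(m_same), 1)
  # reversed series: perfectly anticorrelated up to the log curvature
  m_anti <- rbind(c(1, 2, 3), c(3, 2, 1))
  expect_equal(regional_synchrony(m_anti),
               cor(log(c(1, 2, 3) + 1), log(c(3, 2, 1) + 1)),
               tolerance = 1e-12)
  expect_lt(regional_synchrony(m_anti), -0.95)
  # mean over the three pairwise correlations {1, r, r}
  m_mix <- rbind(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1))
  r <- cor(log(c(1, 2, 3) + 1), log(c(3, 2, 1) + 1))
  expect_equal(regional_synchrony(m_mix), (1 + 2 * r) / 3,
               tolerance = 1e-12)
  # constant series are excluded; all-constant yields missing
  expect_true(is.na(regional_synchrony(matrix(2, 3, 4))))
})

sim_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- make_contrast_scenario(42)
      land <- gen_landscape(sc, 42)
      clim <- gen_climate(sc$climate, sc$n_years, 43, sc$start_year)
      cen <- gen_census(land, clim, sc, 44)
      cache <<- list(sc = sc, land = land, clim = clim, cen = cen,
                     scalers = freeze_sim_scalers(land, cen$panel, clim))
    }
    cache
  }
})

world_params <- function(b_conn) {
  w <- sim_world()
  tp <- w$sc$ts
  ts_params(tp$a0, tp$a1, tp$a2, tp$b_precip, tp$b_temp, tp$b_int, b_conn,
            alpha_patch = w$cen$alpha_patch, sigma = rep_len(tp$sigma, 12))
}

test_that("simulation is deterministic under seed and integer-valued", {
  w <- sim_world()
  cfg <- sim_config(n_reps = 10, n_years = 10, connectivity_kind = "HCI",
                    seed = 5)
  r1 <- simulate_metapop(w$land, world_params(0.3), w$clim, w$cen$panel,
                         cfg, w$scalers)
  r2 <- simulate_metapop(w$land, world_params(0.3), w$clim, w$cen$panel,
                         cfg, w$scalers)
  expect_identical(r1$trajectories, r2$trajectories)
  tr <- r1$trajectories[!is.na(r1$trajectories)]
  expect_true(all(tr >= 0 & tr == round(tr)))
})

test_that("without a connectivity effect all dispersal modes coincide", {
  w <- sim_world()
  cfg <- sim_config(n_reps = 15, n_years = 12, seed = 3)
  ex <- run_experiment(w$land, world_params(0), w$clim, w$cen$panel, cfg)
  s <- ex$summaries
  for (col in c("occupancy", "colonization", "extinction", "synchrony")) {
    expect_identical(s[s$kind == "CI", col], s[s$kind == "HCI", col])
    expect_identical(s[s$kind == "CI", col], s[s$kind == "ECI", col])
  }
  expect_identical(ex$results$CI$trajectories,
                   ex$results$ECI$trajectories)
})

test_that("static dynamics give iid Poisson trajectories with matching moments", {
  w <- sim_world()
  mu <- 4
  params <- ts_params(a0 = log(mu), alpha_patch = rep(0, 12),
                      sigma = rep(1, 12))
  cfg <- sim_config(n_reps = 1000, n_years = 6, seed = 11)
  res <- simulate_metapop(w$land, params, w$clim, w$cen$panel, cfg,
                          w$scalers)
  draws <- res$trajectories[, , 3:6]
  se <- sqrt(mu / length(draws))
  expect_lt(abs(mean(draws) - mu), 3 * se)
  # Poisson: across-replicate variance matches the mean
  expect_lt(abs(var(as.vector(draws)) - mu), 0.1 * mu)
})

test_that("occupancy change equals colonizations minus extinctions each year", {
  w <- sim_world()
  cfg <- sim_config(n_reps = 30, n_years = 15, connectivity_kind = "ECI",
                    seed = 21)
  res <- simulate_metapop(w$land, world_params(0.3), w$clim, w$cen$panel,
                          cfg, w$scalers)
  for (r in 1:30) {
    m <- res$trajectories[r, , ]
    if (anyNA(m)) next
    occ <- colSums(m > 0)
    col_events <- colSums(m[, -ncol(m)] == 0 & m[, -1] > 0)
    ext_events <- colSums(m[, -ncol(m)] > 0 & m[, -1] == 0)
    expect_equal(diff(occ), col_events - ext_events,
                 ignore_attr = TRUE)
  }
  s <- res$summaries[!res$summaries$divergent, ]
  expect_true(all(s$occupancy >= 0 & s$occupancy <= 1))
  expect_true(all(s$colonization >= 0 & s$colonization <= 1, na.rm = TRUE))
  expect_true(all(s$extinction >= 0 & s$extinction <= 1, na.rm = TRUE))
  expect_true(all(s$synchrony >= -1 & s$synchrony <= 1, na.rm = TRUE))
})

test_that("the density cap flags runaway replicates instead of continuing", {
  w <- sim_world()
  explosive <- ts_params(a0 = 3, a1 = 1.2, alpha_patch = rep(0, 12),
                         sigma = rep(1, 12))
  cfg <- sim_config(n_reps = 5, n_years = 15, seed = 2, density_cap = 1e4)
  res <- simulate_metapop(w$land, explosive, w$clim, w$cen$panel, cfg,
                          w$scalers)
  expect_true(all(res$divergent))
  expect_true(all(is.na(res$summaries$occupancy)))
})
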