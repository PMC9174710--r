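# Small deterministic fixtures and random-instance generators shared across
# the test files.

# three collinear patches at 0, 1, 2 km on the x axis; one hilltop at 500 m
toy_landscape <- function() {
  landscape(
    data.frame(patch_id = c("A", "B", "C"), x = c(0, 1000, 2000), y = 0),
    data.frame(hilltop_id = "H1", x = 500, y = 0, elevation_m = 50))
}

toy_census <- function(values, years = NULL) {
  P <- nrow(values)
  if (is.null(years)) years <- seq(2001, length.out = ncol(values))
  dimnames(values) <- list(sprintf("P%d", seq_len(P)), years)
  nb <- matrix(10L, P, ncol(values), dimnames = dimnames(values))
  census_panel(values, nb)
}

# random small instance for oracle-equivalence checks
rand_instance <- function(seed) {
  set.seed(seed)
  P <- sample(2:6, 1)
  H <- sample(1:4, 1)
  Tn <- sample(2:5, 1)
  land <- landscape(
    data.frame(patch_id = sprintf("P%d", 1:P),
               x = runif(P, 0, 3000), y = runif(P, 0, 3000)),
    data.frame(hilltop_id = sprintf("H%d", 1:H),
               x = runif(H, 0, 3000), y = runif(H, 0, 3000),
               elevation_m = runif(H, 0, 150)))
  A <- matrix(runif(P * Tn, 0, 3), P, Tn,
              dimnames = list(sprintf("P%d", 1:P), 2000 + 1:Tn))
  counts <- matrix(rpois(H * Tn, 3), H, Tn,
                   dimnames = list(sprintf("H%d", 1:H), 2000 + 1:Tn))
  counts[runif(H * Tn) < 0.2] <- NA
  list(land = land, A = A, counts = counts, alpha = runif(1, 0.5, 2))
}

# fast sampler settings for replicate loops
quick_sampler <- function(seed) sampler_config(2, 300, 300, 500, 1, seed)
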