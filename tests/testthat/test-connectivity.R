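test_that("Hanski CI matches hand values and excludes self", {
  # single patch: empty sum
  l1 <- landscape(data.frame(patch_id = "A", x = 0, y = 0),
                  data.frame(hilltop_id = "H", x = 0, y = 0,
                             elevation_m = 1))
  A1 <- matrix(2, 1, 1, dimnames = list("A", 2001))
  expect_equal(unname(hanski_ci(l1, A1)$values[1, 1]), 0)

  # coincident pair: e^0 * A
  l2 <- landscape(data.frame(patch_id = c("A", "B"), x = 0, y = 0),
                  data.frame(hilltop_id = "H", x = 0, y = 0,
                             elevation_m = 1))
  A2 <- matrix(c(2, 2), 2, 1, dimnames = list(c("A", "B"), 2001))
  expect_equal(unname(hanski_ci(l2, A2)$values[, 1]), c(2, 2))

  # collinear 0,1,2 km, A = 1, alpha = 1: end patch gets e^-1 + e^-2
  A3 <- matrix(1, 3, 1, dimnames = list(c("A", "B", "C"), 2001))
  ci <- hanski_ci(toy_landscape(), A3)
  expect_equal(unname(ci$values["A", 1]), exp(-1) + exp(-2),
               tolerance = 1e-6)
  expect_equal(unname(ci$values["A", 1]), 0.503215, tolerance = 1e-6)
})

test_that("moth prediction equation matches its fitted coefficients", {
  expect_identical(predict_log_moths(0, 0), -0.89)
  expect_equal(predict_log_moths(1, 0), 0.38)
  expect_equal(predict_log_moths(0, 100), 1.11)
})

test_that("HCI symmetry, identity-scaler limit, and staged structure", {
  # two patches symmetric about one hilltop with equal abundance
  land <- landscape(
    data.frame(patch_id = c("A", "B"), x = c(-700, 700), y = 0),
    data.frame(hilltop_id = "H", x = 0, y = 0, elevation_m = 10))
  A <- matrix(c(1, 1, 2, 2), 2, 2, dimnames = list(c("A", "B"), 2001:2002))
  hci <- hilltop_ci(land, A)
  expect_equal(hci$values[1, ], hci$values[2, ])

  # frozen identity scaler: HCI equals the raw two-stage kernel sum
  hci_id <- hilltop_ci(land, A, inner_scaler = identity_scaler())
  raw <- exp(-land$d_ph) %*% (t(exp(-land$d_ph)) %*% A)
  expect_equal(unname(hci_id$values), unname(raw), tolerance = 1e-12)

  # one-hilltop case against the nested-loop oracle
  A3 <- matrix(c(1, 0.5, 2, 3, 0.2, 1.4), 3, 2,
               dimnames = list(c("A", "B", "C"), 2001:2002))
  expect_equal(unname(hilltop_ci(toy_landscape(), A3)$values),
               oracle_hci(toy_landscape(), A3), tolerance = 1e-10)
})

test_that("ECI limits and staged oracle", {
  land <- toy_landscape()
  A <- matrix(c(1, 0.5, 2, 3, 0.2, 1.4), 3, 2,
              dimnames = list(c("A", "B", "C"), 2001:2002))
  z0 <- elevation_ci(land, A, coefs = moth_pred_coefs(0, 0, 0))
  expect_true(all(z0$values == 0))

  c_only <- elevation_ci(land, A, coefs = moth_pred_coefs(2, 0, 0))
  expect_equal(unname(c_only$values),
               unname(2 * exp(-land$d_ph) %*% matrix(1, 1, 2)),
               tolerance = 1e-12)

  expect_equal(unname(elevation_ci(land, A)$values), oracle_eci(land, A),
               tolerance = 1e-10)
})

test_that("hilltop exposure handles unsurveyed years and matches oracle", {
  land <- landscape(
    data.frame(patch_id = c("A", "B"), x = c(0, 1000), y = 0),
    data.frame(hilltop_id = c("H1", "H2"), x = c(0, 2000), y = 0,
               elevation_m = c(10, 20)))
  counts <- matrix(c(2, NA, NA, NA, 4, 2), 2, 3,
                   dimnames = list(c("H1", "H2"), 2001:2003))
  ex <- hilltop_exposure(land, moth_panel(counts))
  # surveyed hilltop at distance 0: exposure is its offset-logged count
  expect_equal(unname(ex$values["A", 1]), log(3), tolerance = 1e-12)
  # fully unsurveyed year is missing for every patch
  expect_true(all(is.na(ex$values[, 2])))
  expect_equal(unname(ex$values), oracle_exposure(land, counts),
               tolerance = 1e-10)
})

test_that("all indices agree with nested-loop oracles on random instances", {
  for (seed in 1:25) {
    inst <- rand_instance(seed)
    p <- kernel_params(inst$alpha)
    expect_equal(unname(hanski_ci(inst$land, inst$A, p)$values),
                 oracle_ci(inst$land, inst$A, inst$alpha),
                 tolerance = 1e-10)
    expect_equal(unname(hilltop_exposure(inst$land, moth_panel(inst$counts),
                                         p)$values),
                 oracle_exposure(inst$land, inst$counts, inst$alpha),
                 tolerance = 1e-10)
    if (length(unique(as.vector(oracle_inner(inst$land, inst$A,
                                             inst$alpha)))) > 1) {
      expect_equal(unname(hilltop_ci(inst$land, inst$A, p)$values),
                   oracle_hci(inst$land, inst$A, inst$alpha),
                   tolerance = 1e-10)
      expect_equal(unname(elevation_ci(inst$land, inst$A, p)$values),
                   oracle_eci(inst$land, inst$A, inst$alpha),
                   tolerance = 1e-10)
    }
  }
})

test_that("kernel properties: distance monotonicity, alpha limit, permutation equivariance", {
  inst <- rand_instance(99)
  land <- inst$land; A <- inst$A

  # scaling all coordinates up cannot increase CI (nonnegative abundances)
  land_far <- landscape(transform(land$patches, x = x * 3, y = y * 3),
                        transform(land$hilltops, x = x * 3, y = y * 3))
  expect_true(all(hanski_ci(land_far, A)$values <=
                  hanski_ci(land, A)$values + 1e-12))
  id <- identity_scaler()
  expect_true(all(hilltop_ci(land_far, A, inner_scaler = id)$values <=
                  hilltop_ci(land, A, inner_scaler = id)$values + 1e-12))

  # alpha -> infinity kills connectivity at positive distances
  expect_true(all(abs(hanski_ci(land, A, kernel_params(1e3))$values) < 1e-12))

  # permuting patch order permutes index rows identically
  perm <- rev(seq_len(nrow(land$patches)))
  land_p <- landscape(land$patches[perm, ], land$hilltops)
  expect_equal(unname(hanski_ci(land_p, A[perm, , drop = FALSE])$values),
               unname(hanski_ci(land, A)$values[perm, , drop = FALSE]),
               tolerance = 1e-12)
  expect_equal(unname(elevation_ci(land_p, A[perm, , drop = FALSE])$values),
               unname(elevation_ci(land, A)$values[perm, , drop = FALSE]),
               tolerance = 1e-12)
})

test_that("connectivity matrices export as long CSV", {
  ci <- hanski_ci(toy_landscape(),
                  matrix(1, 3, 2, dimnames = list(c("A", "B", "C"),
                                                  2001:2002)))
  p <- tempfile(fileext = ".csv")
  write_connectivity(ci, p)
  df <- read.csv(p)
  expect_equal(nrow(df), 6)
  expect_equal(unique(df$kind), "CI")
  expect_equal(df$value[df$patch_id == "A" & df$year == 2001],
               unname(ci$values["A", "2001"]))
})
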