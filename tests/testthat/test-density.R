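test_that("null geometry predicts a perfectly uniform density", {
  np <- null_dinuc_params()
  prof <- plectoneme_density(random_seq(1000, 4), params = np)
  d <- prof$density[prof$defined]
  expect_lt(max(abs(d - 1)), 1e-9)
  expect_true(all(is.finite(prof$free_energy[prof$defined])))
  # masked linear ends are NA, never zero
  expect_equal(sum(!prof$defined), 130L)
  expect_true(all(is.na(prof$density[!prof$defined])))
})

test_that("density is normalized to mean 1 over defined positions", {
  prof <- plectoneme_density(random_seq(2000, 12))
  expect_equal(mean(prof$density[prof$defined]), 1, tolerance = 1e-9)
  expect_true(all(prof$w_tot[prof$defined] > 0))
  expect_equal(prof$free_energy[prof$defined],
               -log(prof$w_tot[prof$defined]))
})

test_that("a homopolymer is translation invariant: uniform density", {
  prof <- plectoneme_density(strrep("A", 800))
  expect_lt(max(abs(prof$density[prof$defined] - 1)), 1e-9)
})

test_that("the energy grid has 11 x 8 cells with Boltzmann weights", {
  g <- energy_grid(random_seq(300, 6), 150)
  expect_equal(nrow(g), 88L)
  expect_equal(sort(unique(g$loop_size)), seq(40L, 120L, by = 8L))
  expect_equal(sort(unique(g$direction)), 0:7)
  expect_equal(g$w, exp(-g$e_total), tolerance = 1e-12)
  expect_true(all(g$w > 0))
  # with no intrinsic curvature and isotropic stiffness all 8 directions of a
  # given loop size carry the same energy
  gn <- energy_grid(strrep("A", 300), 150, params = null_dinuc_params())
  spread <- tapply(gn$e_total, gn$loop_size, function(x) diff(range(x)))
  expect_lt(max(spread), 1e-9)
})

test_that("one grid cell equals the hand-chained public operations", {
  p <- dinuc_params()
  sq <- random_seq(400, 17)
  i <- 200L
  g <- energy_grid(sq, i, tension = 3, params = p)
  path <- ground_state_path(sq, p)
  for (N in c(40L, 72L, 120L)) {
    cp <- curvature_profile(path, N)
    theta <- cp$theta[cp$position == i]
    phi_b <- cp$phi_b[cp$position == i]
    sig <- summed_covariance(sq, i, N, p)
    for (k in c(0L, 3L, 5L)) {
      phi <- phi_b + k * pi / 4
      A <- directional_persistence_length(sig, N, phi)
      e <- total_energy(N, 3, A, theta, phi = phi, phi_b = phi_b)
      cell <- g[g$loop_size == N & g$direction == k, ]
      expect_equal(cell$theta, theta, tolerance = 1e-9)
      expect_equal(cell$persistence_length, A, tolerance = 1e-9)
      expect_equal(cell$e_total, e, tolerance = 1e-9)
    }
  }
})

test_that("production W_tot equals the independent nested-loop oracle", {
  p <- dinuc_params()
  sq <- random_seq(300, 77)
  prof <- plectoneme_density(sq, tension = 3, params = p)
  orc <- oracle_wtot(sq, 3, p)
  expect_equal(prof$position[prof$defined], orc$positions)
  expect_equal(prof$w_tot[prof$defined], orc$w_tot, tolerance = 1e-9)
})

test_that("a single curved 75 bp insert pins the density peak, and moves with it", {
  curved <- make_fixture("phased_tract", length = 75, period = 10.5)
  fx1 <- make_fixture("insert_in_backbone", insert = curved,
                      backbone_length = 2000L, insert_position = 1000L,
                      seed = 5)
  prof1 <- plectoneme_density(fx1)
  pk1 <- prof1$position[prof1$defined][which.max(prof1$density[prof1$defined])]
  expect_gt(max(prof1$density, na.rm = TRUE), 2)
  expect_lt(abs(pk1 - (1000 + 37)), 50)
  # translation equivariance: moving the insert moves the peak by the same amount
  fx2 <- make_fixture("insert_in_backbone", insert = curved,
                      backbone_length = 2000L, insert_position = 1400L,
                      seed = 5)
  prof2 <- plectoneme_density(fx2)
  pk2 <- prof2$position[prof2$defined][which.max(prof2$density[prof2$defined])]
  expect_lt(abs((pk2 - pk1) - 400), 20)
})

test_that("more concatenated curved units pin more total weight", {
  excess_weight <- function(n_units) {
    ins <- strrep(make_fixture("phased_tract", length = 75, period = 10.5),
                  n_units)
    fx <- make_fixture("insert_in_backbone", insert = ins,
                       backbone_length = 3000L, insert_position = 1200L,
                       seed = 19)
    prof <- plectoneme_density(fx)
    a <- attr(fx, "insert_start") - 100L
    b <- attr(fx, "insert_end") + 100L
    inside <- prof$defined & prof$position >= a & prof$position <= b
    # total Boltzmann weight captured by the insert, relative to the
    # flat-backbone weight scale outside it
    sum(prof$w_tot[inside]) / stats::median(prof$w_tot[prof$defined & !inside])
  }
  a <- sapply(c(1, 2, 4), excess_weight)
  expect_true(all(diff(a) > 0))
})

test_that("GC-rich curved inserts pin while GC-matched flat sequence does not", {
  gc <- make_fixture("gc_rich_curved", n_repeats = 8)
  fx <- make_fixture("insert_in_backbone", insert = gc,
                     backbone_length = 4000L, insert_position = 1700L,
                     seed = 29)
  prof_gc <- plectoneme_density(fx)
  prof_flat <- plectoneme_density(make_fixture("flat_random", length = 4000L,
                                               seed = 29))
  expect_gte(max(prof_gc$density, na.rm = TRUE),
             1.2 * max(prof_flat$density, na.rm = TRUE))
})

test_that("gaussian smoothing has the right kernel, preserves means and constants", {
  # unit impulse reads back the Gaussian with sigma = fwhm / 2.3548
  n <- 8001L
  x <- rep(0, n)
  x[4001] <- 1
  y <- gaussian_smooth(x, fwhm = 1600)
  sigma <- 1600 / sqrt(8 * log(2))
  expect_equal(sigma, 679.4, tolerance = 1e-3)
  kk <- seq_len(n) - 4001L
  expected <- exp(-kk^2 / (2 * sigma^2))
  expected[abs(kk) > ceiling(4 * sigma)] <- 0  # kernel support is +/- 4 sigma
  # compare shapes away from the edge-renormalization zone of the boundaries
  interior <- abs(kk) <= 4001L - ceiling(4 * sigma) - 2L
  expect_equal(y[interior] / max(y), expected[interior] / max(expected),
               tolerance = 1e-9, ignore_attr = TRUE)
  # constants are unchanged, means preserved, including with masked edges
  expect_equal(gaussian_smooth(rep(2.5, 500), 1600), rep(2.5, 500),
               tolerance = 1e-9)
  prof <- plectoneme_density(random_seq(3000, 41))
  sm <- gaussian_smooth(prof, 1600)
  expect_equal(mean(sm$smoothed_density[sm$defined]),
               mean(prof$density[prof$defined]), tolerance = 1e-6)
  # circular smoothing wraps
  profc <- plectoneme_density(random_seq(1000, 42), circular = TRUE)
  smc <- gaussian_smooth(profc, 400)
  expect_equal(mean(smc$smoothed_density), mean(profc$density),
               tolerance = 1e-9)
})

test_that("sequences below the supported minimum are rejected with the minimum", {
  expect_error(plectoneme_density(random_seq(100, 1)), "131")
})
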