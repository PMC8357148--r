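test_that("the iteration step matches a brute-force loop oracle", {
  set.seed(11)
  p <- gks_map_params(D = 0.17, B = 0.02, R_amp = 3)
  f <- matrix(runif(25, 0.2, 1.5), 5, 5)
  sites <- rbind(c(1L, 2L), c(4L, 0L))
  got <- gks_iterate_step(f, sites, p, clamp = FALSE)

  # oracle: direct loop over cells with explicit periodic neighbors
  L <- 5
  oracle <- matrix(NA_real_, L, L)
  for (i in 1:L) for (j in 1:L) {
    up <- f[(i %% L) + 1, j]; dn <- f[((i - 2) %% L) + 1, j]
    rt <- f[i, (j %% L) + 1]; lf <- f[i, ((j - 2) %% L) + 1]
    R <- if (any(sites[, 1] + 1 == i & sites[, 2] + 1 == j)) p$R_amp else 0
    oracle[i, j] <- f[i, j] + p$D * (up + dn + rt + lf - 4 * f[i, j]) -
      R + p$B * (p$gks_max - f[i, j])
  }
  expect_equal(got, oracle)
})

test_that("a uniform ceiling field with no release is a fixed point", {
  f <- matrix(1.5, 20, 20)
  expect_equal(gks_iterate_step(f, NULL), f)
})

test_that("the diffusion term alone conserves the lattice sum", {
  set.seed(3)
  p <- gks_map_params(D = 0.2, B = 0, R_amp = 0)
  f <- matrix(1.5, 3, 3)
  f[2, 2] <- 0.7  # one perturbed site
  nxt <- gks_iterate_step(f, NULL, p, clamp = FALSE)
  expect_equal(sum(nxt), sum(f))
  f2 <- matrix(runif(64, 0, 2), 8, 8)
  expect_equal(sum(gks_iterate_step(f2, NULL, p, clamp = FALSE)), sum(f2))
})

test_that("single-site maps are radially monotone with unimodal cross-sections", {
  m <- generate_gks_map(cbind(10L, 10L), target_radius = 5.4)
  E <- m$E_values
  d <- outer(0:19, 0:19, function(x, y)
    periodic_distance(cbind(x, y), c(10, 10), 20))
  # binned radial profile is non-decreasing with distance
  prof <- tapply(as.vector(E), round(as.vector(d)), mean)
  expect_true(all(diff(prof) > -1e-9))
  # the cross-sections through the site dip once and rise once
  for (cs in list(E[, 11], E[11, ])) {
    sgn <- sign(diff(cs))
    sgn <- sgn[sgn != 0]
    expect_lte(sum(diff(sgn) != 0), 1)
  }
})

test_that("frozen maps respect the clamp bounds and block-average I assignment", {
  maps <- list(
    generate_gks_map(cbind(10L, 10L), 4.2),
    generate_gks_map(rbind(c(6L, 10L), c(14L, 10L)), 6.1),
    generate_gks_map(random_sites(9, seed = 2), 4.2))
  for (m in maps) {
    expect_true(all(m$E_values >= 0.2 & m$E_values <= 1.5))
    expect_true(all(m$I_values >= 0.2 & m$I_values <= 1.5))
    # every I value is the mean of its 2x2 E block
    for (ii in c(1, 37, 100)) {
      x <- (ii - 1) %/% 10; y <- (ii - 1) %% 10
      blk <- m$E_values[2 * x + 1:2, 2 * y + 1:2]
      expect_equal(m$I_values[x + 1, y + 1], mean(blk))
    }
  }
  # custom lower bound propagates
  m0 <- generate_gks_map(cbind(10L, 10L), 4.2,
                         params = gks_map_params(gks_min = 0))
  expect_gte(min(m0$E_values), 0)
  expect_lt(min(m0$E_values), 0.2)
})

test_that("I-cell assignment supports the uniform and zero-override cases", {
  E <- matrix(0.8, 20, 20)
  expect_true(all(assign_I_gks(E) == 0.8))
  blk <- matrix(1.5, 20, 20)
  blk[1, 1] <- 1.5; blk[2, 1] <- 1.5; blk[1, 2] <- 0.3; blk[2, 2] <- 0.7
  expect_equal(assign_I_gks(blk)[1, 1], 1.0)
  expect_true(all(assign_I_gks(E, override_zero = TRUE) == 0))
  m <- generate_gks_map(cbind(10L, 10L), 4.2, I_gks_zero = TRUE)
  expect_true(all(m$I_values == 0))
})

test_that("the effective radius is the area-equivalent radius at the contour", {
  E <- matrix(1.5, 20, 20)
  expect_error(hotspot_radius(E), "no hotspot")
  E[10, 10] <- 0.5
  expect_equal(hotspot_radius(E), sqrt(1 / pi))
  # calibration self-consistency: r = 5.6 puts ~pi*5.6^2 cells under 0.6
  m <- generate_gks_map(cbind(10L, 10L), 5.6)
  expect_lt(abs(sum(m$E_values < 0.6) - pi * 5.6^2), 5)
})

test_that("maps are deterministic, symmetric for mirrored sites, and deepen monotonely", {
  m1 <- generate_gks_map(cbind(10L, 10L), 4.2)
  m2 <- generate_gks_map(cbind(10L, 10L), 4.2)
  expect_identical(m1$E_values, m2$E_values)

  # mirror-symmetric site pair -> map symmetric under the same reflection
  mm <- generate_gks_map(rbind(c(5L, 10L), c(15L, 10L)), 5.4)
  E <- mm$E_values
  refl <- E[c(1, 20:2), ]   # x -> (20 - x) mod 20
  expect_equal(E, refl)

  # freezing later never raises the site minimum
  s <- cbind(10L, 10L)
  m10 <- generate_gks_map(s, n_steps = 10)
  m60 <- generate_gks_map(s, n_steps = 60)
  expect_lte(min(m60$E_values), min(m10$E_values))

  # random sites: reproducible, sized, possibly coincident
  expect_identical(random_sites(6, seed = 9), random_sites(6, seed = 9))
  expect_equal(nrow(random_sites(0, seed = 1)), 0)
  expect_false(identical(random_sites(6, seed = 1), random_sites(6, seed = 2)))
})

test_that("unreachable radii fail with a message naming the step cap", {
  p <- gks_map_params(step_cap = 50L)
  expect_error(generate_gks_map(cbind(10L, 10L), target_radius = 6.1, params = p),
               "step cap 50")
  # homogeneous control: no sites -> uniform ceiling
  m <- generate_gks_map(NULL)
  expect_true(all(m$E_values == 1.5))
})
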