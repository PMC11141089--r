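test_that("receptor matrix columns are the primaries' alpha-opic values", {
  dev <- multiprimary_device(list(delta_spd(555)))
  m <- receptor_matrix(dev, alpha_receptors())
  expect_equal(dim(m), c(5L, 1L))
  for (a in alpha_receptors())
    expect_equal(m[a, 1], oracle_alpha(delta_spd(555), a))
  # doubling a primary's spectrum doubles its column
  dev2 <- multiprimary_device(list(delta_spd(555, 2)))
  expect_equal(receptor_matrix(dev2, alpha_receptors())[, 1], 2 * m[, 1])
  # shape of the study-style device
  expect_equal(dim(receptor_matrix(gaussian_device())), c(3L, 5L))
  expect_error(multiprimary_device(list()),
               class = "melanophot_validation_error")
})

test_that("solve_weights reproduces cone targets and respects the gamut", {
  dev <- gaussian_device()
  m <- receptor_matrix(dev)
  sub <- c(1, 4, 5)
  # self-consistency: target = 0.5 x full drive of the subset itself
  target <- as.numeric(m[, sub] %*% rep(0.5, 3))
  w <- solve_weights(dev, sub, target)
  expect_equal(unname(w[sub]), rep(0.5, 3), tolerance = 1e-9)
  expect_equal(unname(w[-sub]), rep(0, 2))
  # zero target -> zero weights
  expect_equal(unname(solve_weights(dev, sub, c(0, 0, 0))), rep(0, 5))
  # out-of-gamut target names the violating primary
  big <- as.numeric(m[, sub] %*% rep(5, 3))
  expect_error(solve_weights(dev, sub, big),
               class = "melanophot_gamut_error")
  # singular subsets are a degeneracy error
  same <- multiprimary_device(list(delta_spd(500), delta_spd(500),
                                   delta_spd(600)))
  expect_error(solve_weights(same, 1:3, c(1, 1, 1)),
               class = "melanophot_degeneracy_error")
})

test_that("solver matches the explicit-inverse oracle on random devices", {
  set.seed(101)
  for (i in 1:100) {
    dev <- random_device()
    m <- receptor_matrix(dev)
    w_true <- runif(3, 0.05, 0.95)
    target <- as.numeric(m %*% w_true)
    w <- solve_weights(dev, 1:3, target)
    w_oracle <- as.numeric(inverse_3x3(m) %*% target)
    expect_equal(unname(w), w_oracle, tolerance = 1e-9)
    resid <- max(abs(m %*% w - target) / pmax(abs(target), 1e-300))
    expect_lt(resid, 1e-9)
  }
})

test_that("melanopsin contrast has its defining algebra", {
  expect_equal(round_half_up(melanopsin_contrast(20.11, 4.91)), 310)
  expect_equal(round_half_up(melanopsin_contrast(193.62, 64.17)), 202)
  expect_equal(melanopsin_contrast(5, 5), 0)
  expect_error(melanopsin_contrast(1, 0),
               class = "melanophot_validation_error")
  # unit invariance: identical on irradiance and EDI scales
  k <- d65_efficacy("mel")
  expect_equal(melanopsin_contrast(20.11 / k, 4.91 / k),
               melanopsin_contrast(20.11, 4.91))
})

test_that("designed pairs silence the cones", {
  dev <- gaussian_device()
  target <- c(6.40, 11.19, 13.32)
  pair <- design_metamer_pair(dev, c(1, 4, 5), c(2, 3, 5), target)
  expect_lt(pair$cone_residual, 1e-9)
  cones <- c("sc", "mc", "lc")
  expect_equal(unname(pair$achieved_lm$irradiance_mw_m2[cones]), target,
               tolerance = 1e-9)
  expect_equal(unname(pair$achieved_hm$irradiance_mw_m2[cones]), target,
               tolerance = 1e-9)
  expect_gt(pair$contrast_mel, 0)
  # identical subsets give exactly zero contrast
  same <- design_metamer_pair(dev, c(1, 4, 5), c(1, 4, 5), target)
  expect_equal(same$contrast_mel, 0)
  # rescaling the target leaves the contrast unchanged
  half <- design_metamer_pair(dev, c(1, 4, 5), c(2, 3, 5), target / 2)
  expect_equal(half$contrast_mel, pair$contrast_mel, tolerance = 1e-9)
})

test_that("contrast maximisation scales to the gamut boundary", {
  dev <- gaussian_device()
  mx <- maximize_melanopsin_contrast(dev, c(1, 4, 5), c(2, 3, 5))
  # binding weight sits exactly at full drive
  expect_equal(max(c(mx$weights_lm, mx$weights_hm)), 1, tolerance = 1e-9)
  expect_true(nzchar(mx$binding_primary))
  # no feasible direction can beat the reported optimum (grid audit)
  expect_gte(mx$contrast_mel,
             design_metamer_pair(dev, c(1, 4, 5), c(2, 3, 5),
                                 c(6.40, 11.19, 13.32))$contrast_mel - 0.5)
  # degenerate identical subsets -> maximum contrast is zero
  z <- maximize_melanopsin_contrast(dev, c(1, 4, 5), c(1, 4, 5))
  expect_equal(z$contrast_mel, 0, tolerance = 1e-9)
  # explicit illuminance target is honoured; infeasible ones error
  ill <- photopic_illuminance(mx$spd_lm)
  mx2 <- maximize_melanopsin_contrast(dev, c(1, 4, 5), c(2, 3, 5),
                                      illuminance_lx = ill / 2)
  expect_equal(photopic_illuminance(mx2$spd_lm), ill / 2, tolerance = 1e-6)
  expect_equal(mx2$contrast_mel, mx$contrast_mel, tolerance = 1e-6)
  expect_error(
    maximize_melanopsin_contrast(dev, c(1, 4, 5), c(2, 3, 5),
                                 illuminance_lx = ill * 3),
    class = "melanophot_gamut_error")
})

test_that("the study-style device reaches the published contrast range", {
  mx <- maximize_melanopsin_contrast(gaussian_device(), c(1, 4, 5),
                                     c(2, 3, 5))
  expect_gt(mx$contrast_mel, 200)
  expect_lt(mx$contrast_mel, 300)
})
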