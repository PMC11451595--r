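test_that("uniform bulk ions give relative density 1 in every bin", {
  # ideal-gas ions at the bulk number density in a box enclosing the cylinder
  set.seed(101)
  rho <- 300 * 6.02214076e23 / 1e30          # ions / A^3 at 300 mM
  half <- 8
  n_per_frame <- 2L
  zlen <- n_per_frame / (rho * (2 * half)^2) # box sized to exact bulk density
  nf <- 4000
  coords <- array(c(runif(nf * n_per_frame, -half, half),
                    runif(nf * n_per_frame, -half, half),
                    runif(nf * n_per_frame, -zlen / 2, zlen / 2)),
                  dim = c(nf, n_per_frame, 3))
  frames <- make_frames(coords, roles = rep("ion", n_per_frame),
                        names = rep("K", n_per_frame))
  prof <- axial_density(frames, model_default, bin_width = 2,
                        zlim = c(-zlen / 2, zlen / 2))
  inner <- prof[prof$z > -zlen / 2 + 2 & prof$z < zlen / 2 - 2, ]
  expected <- nf * pi * 6^2 * 2 * rho        # counts per bin if uniform
  expect_true(all(abs(inner$count - expected) <= 4 * sqrt(expected)))
  expect_equal(mean(inner$density), 1, tolerance = 0.05)
})

test_that("an empty cylinder gives zero density everywhere", {
  coords <- array(rep(c(30, 30, 0), each = 10), dim = c(10, 1, 3))
  frames <- make_frames(coords, roles = "ion", names = "K")
  prof <- axial_density(frames, model_default, zlim = c(-10, 10))
  expect_true(all(prof$density == 0))
})

test_that("the synthetic run shows density maxima at every binding site", {
  p <- generator_params(seed = 8, duration_us = 10)
  frames <- emit_coordinates(simulate_knockon(p), model_default)
  prof <- axial_density(frames, model_default, zlim = c(-20, 20))
  ctr <- site_centers(model_default)
  for (site in c("S0", "S1", "S2", "S3", "S4", "SCAV")) {
    zc <- sum((ctr[site, ] - model_default$origin) * model_default$direction)
    at <- prof$density[which.min(abs(prof$z - zc))]
    gap_up <- prof$density[which.min(abs(prof$z - (zc + 1.4)))]
    gap_dn <- prof$density[which.min(abs(prof$z - (zc - 1.4)))]
    expect_gt(at, gap_up)
    expect_gt(at, gap_dn)
  }
})

test_that("xy histogram conserves mass and localizes a static atom to one bin", {
  coords <- array(rep(c(1.3, -2.2, 0), each = 25), dim = c(25, 1, 3))
  frames <- make_frames(coords, roles = "ion", names = "K")
  h <- xy_histogram(frames, "ion", model_default)
  expect_identical(sum(h$counts), 25L)
  expect_identical(max(h$counts), 25L)
})

test_that("TEA stays close to the axis; RY785 sits off-axis at its offset", {
  pt <- generator_params(mode = "TEA", seed = 2, duration_us = 5)
  ft <- emit_coordinates(simulate_knockon(pt), model_default)
  h <- xy_histogram(ft, "ligand_N", model_default)
  xc <- (h$xbreaks[-1] + h$xbreaks[-length(h$xbreaks)]) / 2
  rr <- sqrt(outer(xc^2, xc^2, `+`))
  expect_gte(sum(h$counts[rr < 2]) / sum(h$counts), 0.85)

  pr <- generator_params(mode = "RY785", seed = 3, duration_us = 2)
  fr <- emit_coordinates(simulate_knockon(pr), model_default)
  idx <- which(fr$atoms$role == "ligand_N")
  r_mode <- median(axial_and_radial(
    matrix(fr$coords[, idx, ], ncol = 3), model_default)[, "r"])
  expect_equal(r_mode, pr$ry785_r0, tolerance = 0.05)
})

test_that("radial quantiles follow the Rayleigh closed form for TEA", {
  p <- generator_params(mode = "TEA", seed = 2, duration_us = 12)
  frames <- emit_coordinates(simulate_knockon(p), model_default)
  sigma <- p$tea_sigma
  p95 <- radial_percentile(frames, "ligand_N", model_default, 0.95)
  p50 <- radial_percentile(frames, "ligand_N", model_default, 0.50)
  expect_equal(p95, sigma * sqrt(-2 * log(0.05)), tolerance = 0.05)
  expect_equal(p50, sigma * sqrt(2 * log(2)), tolerance = 0.05)
  # monotone in q
  qs <- radial_percentile(frames, "ligand_N", model_default,
                          c(0.1, 0.3, 0.5, 0.7, 0.9))
  expect_true(all(diff(qs) > 0))
  # all atoms exactly on the axis -> 0 for any q
  ctr <- site_centers(model_default)["S2", ]
  on_axis <- make_frames(array(rep(ctr, each = 10), c(10, 1, 3)),
                         roles = "ion", names = "K")
  expect_equal(radial_percentile(on_axis, "ion", model_default, 0.9), 0)
  expect_error(radial_percentile(frames, "ligand_N", model_default, 1.2),
               class = "kvperm_value_error")
})
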