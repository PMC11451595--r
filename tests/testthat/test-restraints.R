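test_that("dihedral bias is zero and stationary at the reference angle", {
  spec <- dihedral_bias_spec(theta_exp_deg = 37, k = 1)
  expect_equal(dihedral_bias_energy(37, spec), 0)
  # numeric gradient vanishes at the minimum
  h <- 1e-5
  grad <- (dihedral_bias_energy(37 + h, spec) -
             dihedral_bias_energy(37 - h, spec)) / (2 * h)
  expect_lt(abs(grad), 1e-6)
  # even in the deviation, 360-degree periodic, non-negative
  for (d in c(5, 20, 90, 133)) {
    expect_equal(dihedral_bias_energy(37 + d, spec),
                 dihedral_bias_energy(37 - d, spec))
    expect_equal(dihedral_bias_energy(37 + d + 360, spec),
                 dihedral_bias_energy(37 + d, spec))
    expect_gte(dihedral_bias_energy(37 + d, spec), 0)
  }
})

test_that("the 6-term sum at 180 degrees equals 2.35 k", {
  spec <- dihedral_bias_spec(theta_exp_deg = 0, k = 1)
  # odd harmonics only: 2 (1 + 1/3! + 1/5!) = 2 + 1/3 + 1/60
  expect_equal(dihedral_bias_energy(180, spec), 2 + 1 / 3 + 1 / 60)
  spec2 <- dihedral_bias_spec(theta_exp_deg = 0, k = 0.5925)
  expect_equal(dihedral_bias_energy(180, spec2), 0.5925 * 2.35)
  # the literal alternating-sign reading has its minimum at 180 instead
  lit <- dihedral_bias_spec(theta_exp_deg = 0, k = 1, form = "literal")
  expect_equal(dihedral_bias_energy(180, lit), -2.35)
})

test_that("flat-bottom potential is zero inside and C1 at the boundary", {
  spec <- flat_bottom_spec("radial")      # d0 = 10, k = 100
  fb <- flat_bottom_energy(c(0, 9, 10, 12), spec)
  expect_equal(fb$energy, c(0, 0, 0, 200))
  expect_equal(fb$force, c(0, 0, 0, 200))
  # analytic force matches numeric differentiation
  h <- 1e-7
  for (d in c(10.5, 13, 25)) {
    num <- (flat_bottom_energy(d + h, spec)$energy -
              flat_bottom_energy(d - h, spec)$energy) / (2 * h)
    expect_equal(flat_bottom_energy(d, spec)$force, num, tolerance = 1e-6)
  }
  ax <- flat_bottom_spec("axial")
  expect_equal(ax$d0, 15)
  expect_equal(flat_bottom_energy(15, ax)$energy, 0)
})

test_that("restraint distances agree with the pore-model geometry", {
  rad <- flat_bottom_spec("radial"); ax <- flat_bottom_spec("axial")
  expect_equal(restraint_distance(c(0, 0, 3), rad, sc_default), 0)
  # 15 A below the V409:CB center along the axis
  expect_equal(restraint_distance(c(0, 0, -12 - 15), ax, sc_default), 15)
  set.seed(9)
  pos <- cbind(runif(25, -10, 10), runif(25, -10, 10), runif(25, -20, 20))
  zr <- axial_and_radial(pos, model_default)
  expect_equal(restraint_distance(pos, rad, sc_default), unname(zr[, "r"]))
  # axial distance is measured from the bottom anchor plane (z = -12)
  expect_equal(restraint_distance(pos, ax, sc_default),
               abs(unname(zr[, "z"]) + 12))
})

test_that("voltage/field conversion reproduces the unit constant", {
  expect_equal(round(unit_constant(), 1), 43.4)
  expect_equal(unit_constant(), 43.364, tolerance = 1e-4)
  expect_equal(voltage_field_conversion(0, 92), 0)
  expect_equal(voltage_field_conversion(100, 100), 0.02306, tolerance = 1e-3)
  set.seed(10)
  for (i in 1:5) {
    v <- runif(1, -300, 300); l <- runif(1, 50, 150)
    expect_equal(voltage_field_conversion(v, l) * l * unit_constant(), v)
  }
  expect_error(voltage_field_conversion(100, 0), class = "kvperm_value_error")
})

test_that("restraint documents round-trip and reject unknown kinds", {
  specs <- default_restraint_set(theta_exp_deg = -65)
  expect_length(specs, 4L)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  export_restraints(specs, f1)
  back <- read_restraints(f1)
  export_restraints(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  rad <- back[[2]]
  expect_equal(rad$d0, 10)
  expect_equal(rad$k, 100)
  bogus <- structure(list(kind = "pi_stacking"), class = "restraint_spec")
  expect_error(export_restraints(list(bogus), f1),
               class = "kvperm_input_error")
})
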