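test_that("no loading means no permeation", {
  log <- simulate_knockon(generator_params(k_enter = 0, inward = FALSE,
                                           duration_us = 2, seed = 1))
  expect_identical(log$counts$eject_out, 0L)
  expect_identical(sum(log$events$type == "eject"), 0L)
})

test_that("default rates reproduce the calibrated permeation budget", {
  # mean interval calibrated to 24.5/45 us at 100 mV: the ejection count in
  # 24.5 us should fall within 3 sigma (Poisson) of 45
  log <- simulate_knockon(generator_params(seed = 1))
  expect_gte(log$counts$eject_out, 45 - ceiling(3 * sqrt(45)))
  expect_lte(log$counts$eject_out, 45 + ceiling(3 * sqrt(45)))
})

test_that("a tagged ion permeates in exactly four knock-on cycles (deterministic)", {
  log <- simulate_knockon(generator_params(seed = 4, deterministic = TRUE,
                                           duration_us = 3))
  series <- site_series_from_log(log)
  first_loaded <- log$events$ion[log$events$type == "load"][1]
  expect_identical(cycles_per_permeation(series, first_loaded), 4L)
})

test_that("identical seeds give bit-identical logs and frames", {
  p <- generator_params(seed = 42, duration_us = 1.5)
  l1 <- simulate_knockon(p); l2 <- simulate_knockon(p)
  expect_identical(l1$events, l2$events)
  m <- model_default
  f1 <- emit_coordinates(l1, m); f2 <- emit_coordinates(l2, m)
  expect_identical(f1$coords, f2$coords)
})

test_that("permeation count is monotone nonincreasing in the RY785 attenuation", {
  counts <- vapply(c(1, 2, 4, 8), function(a) {
    p <- generator_params(mode = "RY785", ry785_attenuation = a,
                          duration_us = 147, k_breathe = 0, seed = 99)
    simulate_knockon(p)$counts$eject_out
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("net flux vanishes at zero voltage within sampling error", {
  log <- simulate_knockon(generator_params(voltage_mV = 0, duration_us = 300,
                                           k_breathe = 0, seed = 7))
  n_out <- log$counts$eject_out; n_in <- log$counts$eject_in
  expect_gt(n_out + n_in, 10)                       # both directions active
  expect_lte(abs(n_out - n_in), 4 * sqrt(n_out + n_in))
})

test_that("parameter validation names the offending field", {
  expect_error(generator_params(), "seed", class = "kvperm_config_error")
  expect_error(generator_params(k_return = -1, seed = 1), "k_return",
               class = "kvperm_config_error")
  expect_error(generator_params(ry785_attenuation = 0.5, seed = 1),
               "ry785_attenuation", class = "kvperm_config_error")
  expect_error(generator_params(duration_us = 0.001, frame_interval_ns = 10,
                                seed = 1),
               "frame_interval", class = "kvperm_config_error")
})

test_that("event logs conserve ion identity and keep single-file order", {
  log <- simulate_knockon(generator_params(seed = 3, duration_us = 6))
  e <- log$events[!is.na(log$events$ion), ]
  expect_false(is.unsorted(log$events$time))
  ini <- stats::setNames(log$initial$compartment, log$initial$ion)
  for (ion in unique(e$ion)) {
    ee <- e[e$ion == ion, ]
    chain <- c(ini[[as.character(ion)]], ee$dst)
    expect_identical(ee$src, chain[-length(chain)])   # connected moves only
  }
  # no two ions share a filter site in any frame
  series <- site_series_from_log(log)
  for (site in c("S0", "S1", "S2", "S3", "S4", "SCAV")) {
    s <- series$segments[series$segments$label == site, ]
    d <- numeric(series$n_frames + 1L)
    if (nrow(s)) d <- tabulate(s$from, series$n_frames + 1L) -
        tabulate(s$to + 1L, series$n_frames + 1L)
    expect_lte(max(cumsum(d)), 1L)
  }
})

test_that("TEA binding is absorbing at voltage and blocks all loading", {
  log <- simulate_knockon(generator_params(mode = "TEA", seed = 5))
  expect_identical(log$counts$eject_out, 0L)
  expect_identical(log$counts$loads, 0L)
  expect_identical(sum(log$events$type == "unbind_inhibitor"), 0L)
})

test_that("induced knock-on requires zero voltage and an in-window pull time", {
  p100 <- generator_params(mode = "TEA", seed = 1, duration_us = 0.2)
  expect_error(apply_induced_knockon(p100, 100), "zero voltage",
               class = "kvperm_config_error")
  p0 <- generator_params(mode = "TEA", voltage_mV = 0, seed = 1,
                         duration_us = 0.2)
  expect_error(apply_induced_knockon(p0, 500), "window",
               class = "kvperm_config_error")
  log <- apply_induced_knockon(p0, 100)
  expect_identical(sum(log$events$type == "induced_pull"), 3L)
})
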