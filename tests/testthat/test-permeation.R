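test_that("hand-written label paths are counted correctly", {
  # a complete outward passage
  s1 <- series_from_labels(list(`1` = c("CYTO", "CAVITY", "SCAV", "S4", "S2",
                                        "S1", "S0", "EXT")))
  ev <- detect_permeation_events(s1)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$direction, "outward")
  expect_equal(ev$entry_ns, 1)   # first frame after leaving CYTO
  expect_equal(ev$exit_ns, 7)
  # an excursion that returns to the cytoplasmic side counts nothing
  s2 <- series_from_labels(list(`1` = c("CYTO", "CAVITY", "S4", "CAVITY", "CYTO")))
  expect_identical(nrow(detect_permeation_events(s2)), 0L)
  # an inward passage
  s3 <- series_from_labels(list(`1` = c("EXT", "S0", "S2", "S4", "CAVITY", "CYTO")))
  ev3 <- detect_permeation_events(s3)
  expect_identical(ev3$direction, "inward")
  # an extracellular excursion that returns
  s4 <- series_from_labels(list(`1` = c("EXT", "S0", "EXT")))
  expect_identical(nrow(detect_permeation_events(s4)), 0L)
})

test_that("a stationary ion yields a constant series", {
  ctr <- site_centers(model_default)["S2", ]
  coords <- array(rep(ctr, each = 100), dim = c(100, 1, 3))
  frames <- make_frames(coords, roles = "ion", names = "K")
  series <- build_site_series(frames, model_default)
  expect_identical(series$segments$label, "S2")
  expect_identical(series$segments$from, 1L)
  expect_identical(series$segments$to, 100L)
})

test_that("noiseless frames round-trip the generator occupancy exactly", {
  p <- generator_params(seed = 5, duration_us = 2, sigma_z = 0, sigma_xy = 0)
  log <- simulate_knockon(p)
  frames <- emit_coordinates(log, model_default)
  s_log <- site_series_from_log(log)
  s_frm <- build_site_series(frames, model_default)
  ord <- function(s) {
    x <- s$segments[order(s$segments$ion, s$segments$from), ]
    rownames(x) <- NULL
    x
  }
  expect_identical(ord(s_frm), ord(s_log))
})

test_that("noisy frames agree with the generator log on >= 99% of labels", {
  p <- generator_params(seed = 6, duration_us = 2, sigma_z = 0.5, sigma_xy = 0.5)
  log <- simulate_knockon(p)
  frames <- emit_coordinates(log, model_default)
  s_log <- site_series_from_log(log)
  s_frm <- build_site_series(frames, model_default)
  ions <- unique(s_log$segments$ion)
  agree <- vapply(ions, function(i)
    mean(expand_labels(s_log, i) == expand_labels(s_frm, i)), numeric(1))
  expect_gte(mean(agree), 0.99)
})

test_that("the event counter equals the generator ejection count on noiseless frames", {
  for (seed in c(2, 3, 9)) {
    p <- generator_params(seed = seed, duration_us = 8, sigma_z = 0, sigma_xy = 0)
    log <- simulate_knockon(p)
    series <- build_site_series(emit_coordinates(log, model_default),
                                model_default)
    ev <- detect_permeation_events(series)
    expect_identical(sum(ev$direction == "outward"), log$counts$eject_out)
  }
})

test_that("time reversal converts outward events to inward events one-to-one", {
  p <- generator_params(seed = 12, duration_us = 4)
  series <- site_series_from_log(simulate_knockon(p))
  # restrict to ions whose trajectories begin and end in bulk solution, so
  # that no start-inside/end-inside boundary convention is involved
  bulk <- c("CYTO", "EXT")
  labs <- lapply(unique(series$segments$ion),
                 function(i) expand_labels(series, i))
  names(labs) <- unique(series$segments$ion)
  keep <- vapply(labs, function(l)
    l[1] %in% bulk && l[length(l)] %in% bulk, logical(1))
  labs <- labs[keep]
  fwd <- detect_permeation_events(series_from_labels(labs))
  bwd <- detect_permeation_events(series_from_labels(lapply(labs, rev)))
  expect_gt(nrow(fwd), 0L)
  expect_identical(sum(fwd$direction == "outward"),
                   sum(bwd$direction == "inward"))
  expect_identical(sum(fwd$direction == "inward"),
                   sum(bwd$direction == "outward"))
})

test_that("conductance matches hand-evaluated values and is homogeneous", {
  expect_equal(conductance(45, 24.5, 100), 2.9428, tolerance = 1e-4)
  expect_equal(conductance(100, 16.02, 100), 10.0, tolerance = 1e-3)
  expect_identical(conductance(0, 5, 100), 0)
  set.seed(31)
  for (i in 1:5) {
    n <- sample(1:200, 1); t <- runif(1, 1, 50); v <- runif(1, 10, 200)
    g <- conductance(n, t, v)
    expect_equal(conductance(2 * n, t, v), 2 * g)
    expect_equal(conductance(n, 2 * t, v), g / 2)
    expect_equal(conductance(n, t, 2 * v), g / 2)
  }
  expect_error(conductance(10, 0, 100), class = "kvperm_value_error")
  expect_error(conductance(10, 10, 0), class = "kvperm_value_error")
})

test_that("mean interval is duration over events, NA when undefined", {
  expect_equal(mean_interval(45, 24.5), 0.5444, tolerance = 1e-3)
  expect_equal(mean_interval(1, 7), 7)
  expect_equal(mean_interval(10, 5.44), 0.544)
  expect_true(is.na(mean_interval(0, 10)))
})

test_that("filter occupancy counts S0..S4 and excludes S_cav", {
  s <- series_from_labels(list(`1` = "S1", `2` = "S3", `3` = "S4",
                               `4` = "SCAV"))
  occ <- filter_occupancy(s)
  expect_identical(occ$occupancy, 3L)
  # occupancy from noiseless frames equals occupancy from the log
  p <- generator_params(seed = 8, duration_us = 2, sigma_z = 0, sigma_xy = 0)
  log <- simulate_knockon(p)
  o1 <- filter_occupancy(site_series_from_log(log))
  o2 <- filter_occupancy(build_site_series(emit_coordinates(log, model_default),
                                           model_default))
  expect_identical(o1$occupancy, o2$occupancy)
})

test_that("knock-on cycles equal ejections; no ejections means no cycles", {
  log <- simulate_knockon(generator_params(seed = 13, duration_us = 8))
  series <- site_series_from_log(log)
  expect_identical(nrow(detect_knockon_cycles(series)), log$counts$eject_out)
  log0 <- simulate_knockon(generator_params(k_eject = 0, k_enter = 0.5,
                                            inward = FALSE,
                                            duration_us = 2, seed = 1))
  expect_identical(nrow(detect_knockon_cycles(site_series_from_log(log0))), 0L)
})

test_that("s4_reload reports vacancy, latency and the degenerate no-pull case", {
  # no vacancy ever: latency 0, flagged
  s <- series_from_labels(list(`1` = rep("S4", 50)))
  r <- s4_reload(s, 10, 20)
  expect_false(r$vacancy)
  expect_equal(r$latency_ns, 0)
  # vacancy refilled after 3 frames
  s2 <- series_from_labels(list(`1` = c(rep("S4", 10), rep("S3", 40)),
                                `2` = c(rep("CYTO", 13), rep("S4", 37))))
  r2 <- s4_reload(s2, 9, 50)
  expect_true(r2$vacancy)
  expect_equal(r2$latency_ns, 4)
  expect_error(s4_reload(s2, 500, 50), class = "kvperm_input_error")
})

test_that("rate ratio arithmetic, bootstrap CI and the undefined-ratio signal", {
  expect_equal(rate_ratio(20, 10, 5, 10, seed = 1)$ratio, 4)
  expect_equal(rate_ratio(7, 3, 7, 3, seed = 1)$ratio, 1)
  rr <- rate_ratio(45, 24.5, 11, 24.5, seed = 1)
  expect_lt(rr$ci[1], rr$ratio)
  expect_gt(rr$ci[2], rr$ratio)
  expect_warning(out <- rate_ratio(10, 5, 0, 5, seed = 1), "undefined")
  expect_true(is.na(out$ratio))
})

test_that("generator attenuation factors are recovered within bootstrap CIs", {
  base <- simulate_knockon(generator_params(seed = 1, duration_us = 24.5,
                                            k_breathe = 0))
  n0 <- sum(detect_permeation_events(
    site_series_from_log(base))$direction == "outward")
  for (a in c(1, 2, 4, 8)) {
    p <- generator_params(mode = "RY785", ry785_attenuation = a, seed = 1,
                          duration_us = 24.5, k_breathe = 0)
    na <- sum(detect_permeation_events(
      site_series_from_log(simulate_knockon(p)))$direction == "outward")
    rr <- rate_ratio(n0, 24.5, na, 24.5, seed = 2)
    expect_lte(rr$ci[1], a)
    expect_gte(rr$ci[2], a)
  }
})
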