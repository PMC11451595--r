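# Synthetic knock-on trajectory generator: a seeded continuous-time Markov
# automaton over pore compartments (Gillespie algorithm), plus an emitter
# that realizes compartment states as noisy 3D coordinates on the scaffold.

#' Parameters for the synthetic knock-on generator
#'
#' Rates are per microsecond; the transmembrane voltage scales the
#' direction-forward rates (cytoplasmic loading and outward ejection) by
#' `exp(V/v0)` and the mirrored inward path by `exp(-V/v0)`.  The default
#' `k_enter` is calibrated in closed form so the mean outward permeation
#' interval at +100 mV equals 24.5/45 us (see [calibrate_k_enter()]).
#'
#' @param duration_us Simulated duration (us).  Defaults to 24.5 for the
#'   uninhibited mode, 5 for TEA and 5.5 for RY785.
#' @param frame_interval_ns Frame spacing of emitted trajectories (ns);
#'   must divide the duration.
#' @param voltage_mV Transmembrane voltage (mV, positive inside drives K+ out).
#' @param k_enter Cavity loading rate CYTO->CAVITY (per us) at 0 mV;
#'   `NULL` selects the calibrated default.
#' @param k_scav CAVITY->SCAV transit rate (per us).
#' @param k_return Return rate of the extra ion (SCAV->CYTO, or S0->EXT on
#'   the inward path) (per us).
#' @param k_eject Base ejection rate resolving the 4-ion configuration
#'   (per us) at 0 mV.
#' @param k_reload S4 vacancy reload rate (per us) used after an induced
#'   knock-on; subject to the same inhibitor attenuation/blocking as loading.
#' @param k_breathe Rate (per us) of the concerted fluctuation of the
#'   resting 3-ion file between its two registers, (S1,S3,S4) and
#'   (S0,S2,S4): the outermost ion fluctuates between S0 and S1 and the
#'   central ion between S2 and S3.  Purely positional (does not gate any
#'   loading or ejection rate).
#' @param v0_mV Voltage coupling constant (mV).
#' @param mode One of `"none"`, `"TEA"`, `"RY785"`.
#' @param tea_k_bind,tea_k_unbind TEA binding/unbinding rates (per us);
#'   unbinding is permitted only at 0 mV (at 100 mV bound TEA is absorbing).
#' @param tea_bound_at_start In TEA mode, start with TEA bound (the
#'   generator emulates the post-binding epoch).
#' @param ry785_attenuation Fold reduction of the cytoplasmic loading path
#'   (and of inward ejection through the cavity) while RY785 is bound
#'   (default 4).
#' @param sigma_z,sigma_xy Gaussian positional noise of emitted ion
#'   coordinates, axial and lateral (Angstrom).
#' @param tea_sigma,tea_sigma_z Lateral and axial spread of the TEA nitrogen
#'   proxy about its on-axis site (Angstrom; lateral default 0.8).
#' @param ry785_r0 Radial offset of the RY785 rigid 3-site proxy from the
#'   axis (Angstrom, default 6).
#' @param ry785_angle_deg Azimuth of the RY785 site (45 = the A/B subunit
#'   interface).
#' @param ry785_sigma Isotropic rigid-body positional noise of the RY785
#'   proxy (Angstrom).
#' @param inward Enable the mirrored inward knock-on path (net flux -> 0 at
#'   0 mV).
#' @param deterministic Replace exponential waiting times by their means and
#'   force ejection to win every branching (used for cycle-arithmetic checks).
#' @param seed Mandatory RNG seed.
#' @return A `generator_params` list.
#' @export
generator_params <- function(duration_us = NULL, frame_interval_ns = 1,
                             voltage_mV = 100,
                             k_enter = NULL, k_scav = 100, k_return = 200,
                             k_eject = 32, k_reload = 400, k_breathe = 20,
                             v0_mV = 50,
                             mode = c("none", "TEA", "RY785"),
                             tea_k_bind = 20, tea_k_unbind = 2,
                             tea_bound_at_start = TRUE,
                             ry785_attenuation = 4,
                             sigma_z = 0.5, sigma_xy = 0.5,
                             tea_sigma = 0.8, tea_sigma_z = 0.8,
                             ry785_r0 = 6, ry785_angle_deg = 45,
                             ry785_sigma = 0.3,
                             inward = TRUE, deterministic = FALSE,
                             seed) {
  mode <- match.arg(mode)
  if (missing(seed)) stop_config("seed is mandatory in generator_params")
  if (is.null(duration_us))
    duration_us <- switch(mode, none = 24.5, TEA = 5, RY785 = 5.5)
  if (is.null(k_enter))
    k_enter <- calibrate_k_enter(24.5 / 45, 100, k_scav, k_return, k_eject, v0_mV)
  p <- list(
    duration_us = duration_us, frame_interval_ns = frame_interval_ns,
    voltage_mV = voltage_mV, k_enter = k_enter, k_scav = k_scav,
    k_return = k_return, k_eject = k_eject, k_reload = k_reload,
    k_breathe = k_breathe, v0_mV = v0_mV, mode = mode, tea_k_bind = tea_k_bind,
    tea_k_unbind = tea_k_unbind, tea_bound_at_start = tea_bound_at_start,
    ry785_attenuation = ry785_attenuation, sigma_z = sigma_z,
    sigma_xy = sigma_xy, tea_sigma = tea_sigma, tea_sigma_z = tea_sigma_z,
    ry785_r0 = ry785_r0, ry785_angle_deg = ry785_angle_deg,
    ry785_sigma = ry785_sigma, inward = inward,
    deterministic = deterministic, seed = as.integer(seed)
  )
  validate_generator_params(p)
  structure(p, class = "generator_params")
}

validate_generator_params <- function(p) {
  rates <- c("k_enter", "k_scav", "k_return", "k_eject", "k_reload",
             "k_breathe", "tea_k_bind", "tea_k_unbind")
  for (r in rates)
    if (!is_scalar_num(p[[r]]) || p[[r]] < 0)
      stop_config(sprintf("rate '%s' must be a single non-negative number", r))
  if (!is_scalar_num(p$duration_us) || p$duration_us <= 0)
    stop_config("'duration_us' must be positive")
  if (!is_scalar_num(p$frame_interval_ns) || p$frame_interval_ns <= 0 ||
      p$frame_interval_ns > p$duration_us * 1000)
    stop_config("'frame_interval_ns' must be positive and at most the duration")
  if (!is_scalar_num(p$ry785_attenuation) || p$ry785_attenuation < 1)
    stop_config("'ry785_attenuation' must be >= 1")
  for (s in c("sigma_z", "sigma_xy", "tea_sigma", "tea_sigma_z", "ry785_sigma"))
    if (!is_scalar_num(p[[s]]) || p[[s]] < 0)
      stop_config(sprintf("noise scale '%s' must be non-negative", s))
  if (!is_scalar_num(p$v0_mV) || p$v0_mV <= 0)
    stop_config("'v0_mV' must be positive")
  invisible(p)
}

#' Calibrate the cavity loading rate to a target permeation interval
#'
#' Solves, in closed form, the loading rate `k_enter` for which the mean
#' time per outward permeation event of the knock-on automaton equals
#' `target_interval_us` at the given voltage: one event takes, on average,
#' `1/p` loading cycles of mean length `1/(k_enter*phi) + 1/k_scav +
#' 1/(k_eject*phi + k_return)`, where `p` is the probability that a 4-ion
#' configuration resolves by ejection and `phi = exp(V/v0)`.
#'
#' @param target_interval_us Mean outward permeation interval (us).
#' @param voltage_mV Voltage at which the calibration holds.
#' @inheritParams generator_params
#' @return Loading rate (per us).
#' @export
calibrate_k_enter <- function(target_interval_us, voltage_mV = 100,
                              k_scav = 100, k_return = 200, k_eject = 32,
                              v0_mV = 50) {
  phi <- exp(voltage_mV / v0_mV)
  lambda_b <- k_eject * phi + k_return
  p <- k_eject * phi / lambda_b
  wait <- target_interval_us * p - 1 / k_scav - 1 / lambda_b
  if (wait <= 0)
    stop_config("target interval unattainably short for the given branch rates")
  1 / (phi * wait)
}

new_event_buffer <- function(n0 = 1024L) {
  env <- new.env(parent = emptyenv())
  env$time <- numeric(n0); env$type <- character(n0)
  env$ion <- integer(n0); env$src <- character(n0); env$dst <- character(n0)
  env$n <- 0L
  env
}

push_event <- function(buf, time, type, ion, src, dst) {
  n <- buf$n + 1L
  if (n > length(buf$time)) {
    m <- 2L * length(buf$time)
    length(buf$time) <- m; length(buf$type) <- m
    length(buf$ion) <- m; length(buf$src) <- m; length(buf$dst) <- m
  }
  buf$time[n] <- time; buf$type[n] <- type; buf$ion[n] <- ion
  buf$src[n] <- src; buf$dst[n] <- dst
  buf$n <- n
}

buffer_to_df <- function(buf) {
  n <- buf$n
  data.frame(time = buf$time[seq_len(n)], type = buf$type[seq_len(n)],
             ion = buf$ion[seq_len(n)], src = buf$src[seq_len(n)],
             dst = buf$dst[seq_len(n)], stringsAsFactors = FALSE)
}

#' Simulate the knock-on automaton
#'
#' Continuous-time stochastic simulation of single-file K+ transport through
#' the filter: the canonical 3-ion file (slots S1, S3, S4) is perturbed by
#' arrival of a cytoplasmic ion at S_cav (via the cavity), producing a
#' metastable 4-ion configuration that resolves either by return of the
#' incoming ion or by ejection of the outermost ion into the extracellular
#' space, upon which the whole file (including the S_cav ion) shifts
#' outward in concert.  A mirrored inward path (extracellular arrival at S0,
#' ejection of the S4 ion into the cytoplasm) carries the reverse flux.
#' A bound TEA sets the loading path to zero; bound RY785 divides it by the
#' attenuation factor.  All waiting times are exponential and seeded.
#'
#' @param params A `generator_params`.
#' @param t_pull_ns Optional time (ns) of an induced knock-on (see
#'   [apply_induced_knockon()]); `NA` for none.
#' @return A `knockon_log`: `$events` (time ns, type, ion, src, dst),
#'   `$initial` (ion, compartment at t = 0), `$duration_ns`, `$params`,
#'   and `$counts` (outward/inward ejections, loads, returns).
#' @export
simulate_knockon <- function(params, t_pull_ns = NA_real_) {
  validate_generator_params(params)
  with_seed(params$seed, simulate_knockon_impl(params, t_pull_ns))
}

simulate_knockon_impl <- function(p, t_pull_ns) {
  dur <- p$duration_us * 1000               # ns
  phi_f <- exp(p$voltage_mV / p$v0_mV)
  phi_b <- exp(-p$voltage_mV / p$v0_mV)
  # rates per ns
  kE <- p$k_enter / 1000; kS <- p$k_scav / 1000
  kR <- p$k_return / 1000; kJ <- p$k_eject / 1000
  kV <- p$k_reload / 1000; kBr <- p$k_breathe / 1000
  kB <- p$tea_k_bind / 1000; kU <- p$tea_k_unbind / 1000

  # ion bookkeeping: 1..3 start in the filter; a cytoplasmic and an
  # extracellular reservoir supply further identities
  s1 <- 1L; s3 <- 2L; s4 <- 3L
  cyto_pool <- 4:9
  ext_pool  <- 101:106
  next_cyto <- 10L; next_ext <- 107L
  initial <- data.frame(
    ion = c(s1, s3, s4, cyto_pool, ext_pool),
    compartment = c("S1", "S3", "S4", rep("CYTO", length(cyto_pool)),
                    rep("EXT", length(ext_pool))),
    stringsAsFactors = FALSE)

  cav_ion <- NA_integer_; scav_ion <- NA_integer_; s0_ion <- NA_integer_
  tea_bound <- p$mode == "TEA" && p$tea_bound_at_start
  vacancy <- FALSE
  # register of the resting 3-ion file: "X" = (S1,S3,S4), "Y" = (S0,S2,S4)
  cfg <- "X"

  buf <- new_event_buffer()
  if (tea_bound) push_event(buf, 0, "bind_inhibitor", NA_integer_, "CYTO", "SCAV_ADJ")

  g_load <- function() {
    if (p$mode == "TEA" && tea_bound) 0
    else if (p$mode == "RY785") 1 / p$ry785_attenuation
    else 1
  }
  take_cyto <- function() {
    if (length(cyto_pool) == 0L) {
      cyto_pool <<- next_cyto; next_cyto <<- next_cyto + 1L
      initial <<- rbind(initial, data.frame(ion = cyto_pool,
                                            compartment = "CYTO"))
    }
    ion <- cyto_pool[1]; cyto_pool <<- cyto_pool[-1]; ion
  }
  take_ext <- function() {
    if (length(ext_pool) == 0L) {
      ext_pool <<- next_ext; next_ext <<- next_ext + 1L
      initial <<- rbind(initial, data.frame(ion = ext_pool,
                                            compartment = "EXT"))
    }
    ion <- ext_pool[1]; ext_pool <<- ext_pool[-1]; ion
  }

  snap_to_x <- function(t) {
    # compress a breathing (S0,S2,S4) file back to the canonical register
    if (cfg == "Y") {
      push_event(buf, t, "shift", s1, "S0", "S1")
      push_event(buf, t, "shift", s3, "S2", "S3")
      cfg <<- "X"
    }
  }

  do_pull <- function(t) {
    # resolve any extra ion first so the filter holds exactly 3 ions
    if (!is.na(scav_ion)) { push_event(buf, t, "return", scav_ion, "SCAV", "CYTO"); cyto_pool <<- c(cyto_pool, scav_ion); scav_ion <<- NA_integer_ }
    if (!is.na(cav_ion))  { push_event(buf, t, "return", cav_ion, "CAVITY", "CYTO"); cyto_pool <<- c(cyto_pool, cav_ion); cav_ion <<- NA_integer_ }
    if (!is.na(s0_ion))   { push_event(buf, t, "return", s0_ion, "S0", "EXT"); ext_pool <<- c(ext_pool, s0_ion); s0_ion <<- NA_integer_ }
    snap_to_x(t)
    if (is.na(s1) || is.na(s3) || is.na(s4))
      stop_internal("induced knock-on requires a 3-ion filter configuration")
    push_event(buf, t, "induced_pull", s1, "S1", "EXT")
    push_event(buf, t, "induced_pull", s3, "S3", "S1")
    push_event(buf, t, "induced_pull", s4, "S4", "S3")
    ext_pool <<- c(ext_pool, s1)
    s1 <<- s3; s3 <<- s4; s4 <<- NA_integer_
    vacancy <<- TRUE
  }

  t <- 0
  pull_pending <- is.finite(t_pull_ns)
  if (pull_pending && (t_pull_ns < 0 || t_pull_ns > dur))
    stop_config("t_pull_ns lies outside the simulated window")

  repeat {
    # enumerate possible transitions and rates in the current state
    ev <- character(0); rt <- numeric(0)
    if (vacancy) {
      r <- kV * g_load()
      if (r > 0) { ev <- c(ev, "reload"); rt <- c(rt, r) }
    } else if (!is.na(cav_ion)) {
      r <- kS * g_load()
      if (r > 0) { ev <- c(ev, "to_scav"); rt <- c(rt, r) }
    } else if (!is.na(scav_ion)) {
      ev <- c(ev, "eject", "return"); rt <- c(rt, kJ * phi_f, kR)
    } else if (!is.na(s0_ion)) {
      r_in <- kJ * phi_b * g_load()
      ev <- c(ev, "in_eject", "in_return"); rt <- c(rt, r_in, kR)
    } else {
      r <- kE * phi_f * g_load()
      if (r > 0) { ev <- c(ev, "out_load"); rt <- c(rt, r) }
      if (p$inward && !p$deterministic) {
        ev <- c(ev, "in_load"); rt <- c(rt, kE * phi_b)
      }
    }
    if (!p$deterministic && !vacancy && is.na(scav_ion) && is.na(s0_ion) &&
        kBr > 0) {
      ev <- c(ev, "breathe"); rt <- c(rt, kBr)
    }
    if (p$mode == "TEA" && !p$deterministic) {
      if (tea_bound && p$voltage_mV == 0) { ev <- c(ev, "tea_unbind"); rt <- c(rt, kU) }
      if (!tea_bound) { ev <- c(ev, "tea_bind"); rt <- c(rt, kB) }
    }
    keep <- rt > 0
    ev <- ev[keep]; rt <- rt[keep]
    if (length(ev) == 0L) break                        # absorbing state

    if (p$deterministic) {
      pri <- c(eject = 1, to_scav = 2, out_load = 3, reload = 4)
      i <- which.min(pri[ev])
      dt <- 1 / rt[i]
    } else {
      total <- sum(rt)
      dt <- stats::rexp(1, total)
      i <- if (length(rt) == 1L) 1L else
        sample.int(length(rt), 1L, prob = rt)
    }

    if (pull_pending && t + dt >= t_pull_ns) {
      t <- t_pull_ns
      do_pull(t)
      pull_pending <- FALSE
      next          # memoryless: redraw from the post-pull state
    }
    t <- t + dt
    if (t > dur) break

    switch(ev[i],
      out_load = {
        cav_ion <- take_cyto()
        push_event(buf, t, "load", cav_ion, "CYTO", "CAVITY")
      },
      to_scav = {
        snap_to_x(t)
        scav_ion <- cav_ion; cav_ion <- NA_integer_
        push_event(buf, t, "load", scav_ion, "CAVITY", "SCAV")
      },
      breathe = {
        if (cfg == "X") {
          push_event(buf, t, "shift", s1, "S1", "S0")
          push_event(buf, t, "shift", s3, "S3", "S2")
          cfg <- "Y"
        } else {
          push_event(buf, t, "shift", s1, "S0", "S1")
          push_event(buf, t, "shift", s3, "S2", "S3")
          cfg <- "X"
        }
      },
      eject = {
        push_event(buf, t, "eject", s1, "S1", "EXT")
        push_event(buf, t, "shift", s3, "S3", "S1")
        push_event(buf, t, "shift", s4, "S4", "S3")
        push_event(buf, t, "shift", scav_ion, "SCAV", "S4")
        ext_pool <- c(ext_pool, s1)
        s1 <- s3; s3 <- s4; s4 <- scav_ion; scav_ion <- NA_integer_
      },
      `return` = {
        push_event(buf, t, "return", scav_ion, "SCAV", "CYTO")
        cyto_pool <- c(cyto_pool, scav_ion); scav_ion <- NA_integer_
      },
      in_load = {
        snap_to_x(t)
        s0_ion <- take_ext()
        push_event(buf, t, "load", s0_ion, "EXT", "S0")
      },
      in_eject = {
        push_event(buf, t, "eject", s4, "S4", "CYTO")
        push_event(buf, t, "shift", s3, "S3", "S4")
        push_event(buf, t, "shift", s1, "S1", "S3")
        push_event(buf, t, "shift", s0_ion, "S0", "S1")
        cyto_pool <- c(cyto_pool, s4)
        s4 <- s3; s3 <- s1; s1 <- s0_ion; s0_ion <- NA_integer_
      },
      in_return = {
        push_event(buf, t, "return", s0_ion, "S0", "EXT")
        ext_pool <- c(ext_pool, s0_ion); s0_ion <- NA_integer_
      },
      reload = {
        s4 <- take_cyto()
        push_event(buf, t, "load", s4, "CYTO", "S4")
        vacancy <- FALSE
      },
      tea_bind = {
        tea_bound <- TRUE
        push_event(buf, t, "bind_inhibitor", NA_integer_, "CYTO", "SCAV_ADJ")
      },
      tea_unbind = {
        tea_bound <- FALSE
        push_event(buf, t, "unbind_inhibitor", NA_integer_, "SCAV_ADJ", "CYTO")
      }
    )
  }
  if (pull_pending) { do_pull(t_pull_ns) }   # pull at/after last transition

  events <- buffer_to_df(buf)
  validate_event_log(events, initial)
  counts <- list(
    eject_out = sum(events$type == "eject" & events$dst == "EXT"),
    eject_in  = sum(events$type == "eject" & events$dst == "CYTO"),
    loads     = sum(events$type == "load"),
    returns   = sum(events$type == "return")
  )
  structure(list(events = events, initial = initial, duration_ns = dur,
                 params = p, counts = counts, t_pull_ns = t_pull_ns),
            class = "knockon_log")
}

# EventLog invariants: non-decreasing times; no two ions in one filter site;
# single-file order never violated.
validate_event_log <- function(events, initial = NULL) {
  if (nrow(events) == 0L) return(invisible(events))
  if (is.unsorted(events$time))
    stop_internal("event log times must be non-decreasing")
  occ <- list()
  if (!is.null(initial)) {
    inside <- initial$compartment %in% c(FILTER_SITES, "SCAV", "CAVITY")
    occ <- as.list(stats::setNames(initial$ion[inside],
                                   initial$compartment[inside]))
  }
  for (i in seq_len(nrow(events))) {
    ion <- events$ion[i]
    if (is.na(ion)) next
    src <- events$src[i]; dst <- events$dst[i]
    if (src %in% names(occ) && identical(occ[[src]], ion)) occ[[src]] <- NULL
    if (dst %in% FILTER_SITES || dst %in% c("SCAV", "CAVITY")) {
      if (!is.null(occ[[dst]]) && events$time[i] > events$time[max(1L, i - 1L)])
        stop_internal(sprintf("two ions in compartment %s at t=%g", dst, events$time[i]))
      occ[[dst]] <- ion
    }
  }
  invisible(events)
}

#' @export
print.knockon_log <- function(x, ...) {
  cat(sprintf("knockon_log: %.3f us at %g mV, mode=%s, seed=%d\n",
              x$duration_ns / 1000, x$params$voltage_mV, x$params$mode,
              x$params$seed))
  cat(sprintf("  %d outward ejections, %d inward, %d loads, %d returns\n",
              x$counts$eject_out, x$counts$eject_in, x$counts$loads,
              x$counts$returns))
  invisible(x)
}

#' Induced knock-on protocol
#'
#' At `t_pull_ns` the central filter ion is driven outward: the outermost
#' ion is ejected to the extracellular side, the central ion takes its
#' place, the innermost ion moves to the filter center, and site S4 is left
#' vacant.  The subsequent reload of S4 is governed by `k_reload` under the
#' same inhibitor attenuation/blocking as ordinary loading.  The protocol
#' runs at zero voltage; TEA may dissociate spontaneously before the pull
#' (`tea_k_unbind`, active only at 0 mV).
#'
#' @param params A `generator_params`; its voltage must be 0 mV.
#' @param t_pull_ns Time of the induced knock-on (ns); must lie within the
#'   simulated window.
#' @return A `knockon_log` whose events include the `induced_pull` records.
#' @export
apply_induced_knockon <- function(params, t_pull_ns = 100) {
  if (params$voltage_mV != 0)
    stop_config("the induced knock-on protocol is defined at zero voltage")
  if (!is_scalar_num(t_pull_ns) || t_pull_ns < 0 ||
      t_pull_ns > params$duration_us * 1000)
    stop_config("t_pull_ns lies outside the simulated window")
  simulate_knockon(params, t_pull_ns = t_pull_ns)
}

#' Write / read an event log as TSV
#'
#' @param log A `knockon_log` (write) or path (read).
#' @param file Path to a TSV file.
#' @return `read_event_log` returns the event data.frame.
#' @export
write_event_log <- function(log, file) {
  utils::write.table(log$events, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
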