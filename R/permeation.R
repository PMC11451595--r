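# Permeation statistics: event detection, knock-on cycles, occupancy,
# conductance and the S4 vacancy/reload diagnostic.

#' Detect complete permeation events
#'
#' A permeation event is a complete passage from one bulk compartment to the
#' other (CYTO -> ... -> EXT outward, or the reverse inward) that visits at
#' least one filter site in between.  Excursions that enter the pore and
#' return to the side they came from count nothing.  The entry time is the
#' start of the last excursion from the bulk side that completes the
#' passage; the exit time is the first frame on the far side.  Ions whose
#' first label is already inside the pore (the initial filter file of a
#' simulation) are treated as having entered from the cytoplasmic side at
#' the first frame, so that the detected outward count equals the
#' generator's ejection count exactly.
#'
#' @param series A `site_series`.
#' @return data.frame with columns `ion`, `entry_ns`, `exit_ns`,
#'   `direction` ("outward"/"inward"); zero rows if no events.
#' @export
detect_permeation_events <- function(series) {
  out <- list()
  times <- series$times
  for (ion in unique(series$segments$ion)) {
    s <- series$segments[series$segments$ion == ion, ]
    s <- s[order(s$from), ]
    last_boundary <- NA_character_
    pending_entry <- NA_real_
    filter_seen <- FALSE
    if (!(s$label[1] %in% c("CYTO", "EXT"))) {
      last_boundary <- "CYTO"
      pending_entry <- times[s$from[1]]
    }
    for (i in seq_len(nrow(s))) {
      lab <- s$label[i]
      if (lab %in% c("CYTO", "EXT")) {
        if (!is.na(last_boundary) && lab != last_boundary && filter_seen) {
          out[[length(out) + 1L]] <- data.frame(
            ion = ion, entry_ns = pending_entry, exit_ns = times[s$from[i]],
            direction = if (lab == "EXT") "outward" else "inward",
            stringsAsFactors = FALSE)
        }
        last_boundary <- lab
        pending_entry <- NA_real_
        filter_seen <- FALSE
      } else {
        if (is.na(pending_entry)) pending_entry <- times[s$from[i]]
        if (lab %in% FILTER_SITES) filter_seen <- TRUE
      }
    }
  }
  if (!length(out))
    return(data.frame(ion = integer(0), entry_ns = numeric(0),
                      exit_ns = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE))
  ev <- do.call(rbind, out)
  ev[order(ev$exit_ns), , drop = FALSE]
}

#' Single-channel conductance from an event count
#'
#' g = N e / (t V): `n_events` elementary charges carried in `duration_us`
#' at `voltage_mV`, in picosiemens.  No rounding is applied.
#'
#' @param n_events Number of complete permeation events.
#' @param duration_us Observation time (us), > 0.
#' @param voltage_mV Transmembrane voltage (mV), non-zero.
#' @return Conductance in pS.
#' @export
conductance <- function(n_events, duration_us, voltage_mV) {
  if (!is_scalar_num(duration_us) || duration_us <= 0)
    stop_value("duration must be positive")
  if (!is_scalar_num(voltage_mV) || voltage_mV == 0)
    stop_value("voltage must be non-zero")
  n_events * E_CHARGE / (duration_us * 1e-6 * voltage_mV * 1e-3) * 1e12
}

#' Mean permeation interval
#'
#' `duration_us / n_events`; returns `NA_real_` (an undefined-interval
#' signal, not an error) when no events were observed.
#'
#' @inheritParams conductance
#' @return Mean interval in us per event, or `NA_real_`.
#' @export
mean_interval <- function(n_events, duration_us) {
  if (n_events == 0) return(NA_real_)
  duration_us / n_events
}

#' Filter occupancy per frame
#'
#' Counts ions labeled S0..S4 (S0 counts toward the filter) in every frame
#' and summarizes the modal occupancy and the fraction of frames at each
#' occupancy level.
#'
#' @param series A `site_series`.
#' @return List with `occupancy` (integer per frame), `modal`, and
#'   `fractions` (named numeric, occupancy level -> fraction of frames).
#' @export
filter_occupancy <- function(series) {
  n <- series$n_frames
  fs <- series$segments[series$segments$label %in% FILTER_SITES, ]
  d <- numeric(n + 1L)
  if (nrow(fs)) {
    add <- tabulate(fs$from, nbins = n + 1L)
    sub <- tabulate(fs$to + 1L, nbins = n + 1L)
    d <- add - sub
  }
  occ <- as.integer(cumsum(d)[seq_len(n)])
  tab <- table(occ)
  list(occupancy = occ,
       modal = as.integer(names(tab)[which.max(tab)]),
       fractions = stats::setNames(as.numeric(tab) / n, names(tab)))
}

#' Detect knock-on cycles
#'
#' A cycle is an S_cav-loaded 4-ion configuration resolved by ejection of
#' the outermost filter ion (a return of the incoming ion resolves the
#' configuration without a cycle).  Detection keys on the frame-to-frame
#' transition of an ion from a filter site S1..S4 to EXT, which is robust to
#' S_cav dwell times shorter than one frame; a transition S0 -> EXT counts
#' only when S0 was reached from inside the filter (the resting file's outer
#' register) -- reached from EXT it is the return of an inward excursion,
#' not an ejection.  The
#' load time is the start of the entering ion's S_cav residence when that
#' residence is resolved on the frame grid, otherwise the ejection time.
#'
#' @param series A `site_series`.
#' @return data.frame with `load_ns`, `eject_ns`, `ejected_ion`,
#'   `entering_ion` (NA when no ion refilled S4, e.g. an induced vacancy).
#' @export
detect_knockon_cycles <- function(series) {
  times <- series$times
  segs <- series$segments
  cycles <- list()
  # ejections: run label in S1..S4 immediately followed by EXT
  for (ion in unique(segs$ion)) {
    s <- segs[segs$ion == ion, ]
    s <- s[order(s$from), ]
    k <- nrow(s)
    if (k < 2L) next
    deep <- s$label[-k] %in% c("S1", "S2", "S3", "S4") & s$label[-1] == "EXT"
    # S0 -> EXT is an ejection only when S0 was reached from inside the
    # filter; reached from EXT it is the return of an inward excursion
    from_s0 <- s$label[-k] == "S0" & s$label[-1] == "EXT" &
      c(FALSE, utils::head(s$label, -2) != "EXT")[seq_len(k - 1L)]
    hit <- which(deep | from_s0)
    for (i in hit) {
      f <- s$from[i + 1L]          # frame at which the ejected ion is EXT
      # entering ion: acquires label S4 at frame f coming from outside the filter
      ent <- segs[segs$label == "S4" & segs$from == f, ]
      entering <- NA_integer_; load_ns <- times[f]
      if (nrow(ent)) {
        entering <- ent$ion[1]
        prev <- segs[segs$ion == entering & segs$to == f - 1L, ]
        if (nrow(prev) && prev$label[1] == "SCAV")
          load_ns <- times[prev$from[1]]
      }
      cycles[[length(cycles) + 1L]] <- data.frame(
        load_ns = load_ns, eject_ns = times[f], ejected_ion = ion,
        entering_ion = entering, stringsAsFactors = FALSE)
    }
  }
  if (!length(cycles))
    return(data.frame(load_ns = numeric(0), eject_ns = numeric(0),
                      ejected_ion = integer(0), entering_ion = integer(0)))
  cy <- do.call(rbind, cycles)
  cy[order(cy$eject_ns), , drop = FALSE]
}

#' Knock-on cycles per permeation of a tagged ion
#'
#' Number of knock-on cycles between the tagged ion's arrival in the cavity
#' region (first CAVITY or SCAV label) and its exit to the extracellular
#' side.  In the deterministic automaton this is exactly 4: the ion advances
#' S_cav -> S4 -> S3 -> S1 -> out, one step per cycle.
#'
#' @param series A `site_series`.
#' @param ion Tagged ion identity.
#' @return Integer cycle count.
#' @export
cycles_per_permeation <- function(series, ion) {
  s <- series$segments[series$segments$ion == ion, ]
  s <- s[order(s$from), ]
  arr <- s$from[s$label %in% c("CAVITY", "SCAV")]
  if (!length(arr)) stop_input("tagged ion never reaches the cavity")
  t_arr <- series$times[min(arr)]
  ex <- s$from[s$label == "EXT" & series$times[s$from] > t_arr]
  if (!length(ex)) stop_input("tagged ion never exits to EXT")
  t_exit <- series$times[min(ex)]
  cy <- detect_knockon_cycles(series)
  sum(cy$eject_ns > t_arr & cy$eject_ns <= t_exit)
}

#' S4 reload latency after an induced vacancy
#'
#' Looks for the first frame after `t_pull_ns` at which site S4 is occupied
#' again, within `window_ns`.  If S4 never vacates after `t_pull_ns` the
#' series contains no vacancy (no pull was applied): latency 0 with
#' `vacancy = FALSE`.
#'
#' @param series A `site_series`.
#' @param t_pull_ns Time of the induced knock-on (ns).
#' @param window_ns Follow-up window (ns, default 100).
#' @return List with `latency_ns` (NA if no reload within the window),
#'   `reloaded`, `vacancy`.
#' @export
s4_reload <- function(series, t_pull_ns, window_ns = 100) {
  times <- series$times
  if (t_pull_ns < times[1] || t_pull_ns > times[length(times)])
    stop_input("t_pull_ns lies outside the series")
  s4 <- series$segments[series$segments$label == "S4", ]
  occupied <- logical(series$n_frames)
  for (i in seq_len(nrow(s4))) occupied[s4$from[i]:s4$to[i]] <- TRUE
  after <- which(times > t_pull_ns)
  if (!length(after) || all(occupied[after]))
    return(list(latency_ns = 0, reloaded = TRUE, vacancy = FALSE))
  first_vac <- after[which(!occupied[after])[1]]
  inwin <- after[times[after] <= t_pull_ns + window_ns]
  refill <- inwin[inwin >= first_vac & occupied[inwin]]
  if (length(refill))
    list(latency_ns = times[refill[1]] - t_pull_ns, reloaded = TRUE,
         vacancy = TRUE)
  else
    list(latency_ns = NA_real_, reloaded = FALSE, vacancy = TRUE)
}

#' Ratio of permeation rates with a bootstrap confidence interval
#'
#' `(n_a/t_a) / (n_b/t_b)` with a seeded percentile bootstrap over the event
#' counts (Poisson resampling, 10,000 resamples by default).  A zero count
#' in the denominator condition yields `NA` (undefined-ratio signal) with a
#' warning.
#'
#' @param n_a,duration_a_us Event count and duration of the numerator
#'   condition (e.g. uninhibited).
#' @param n_b,duration_b_us Event count and duration of the denominator
#'   condition (e.g. RY785-bound).
#' @param n_boot Number of bootstrap resamples.
#' @param conf Confidence level for the percentile interval.
#' @param seed RNG seed for the bootstrap.
#' @return List with `ratio`, `ci` (length 2), `conf`, `n_boot`.
#' @export
rate_ratio <- function(n_a, duration_a_us, n_b, duration_b_us,
                       n_boot = 10000, conf = 0.95, seed = 1) {
  if (duration_a_us <= 0 || duration_b_us <= 0)
    stop_value("durations must be positive")
  if (n_b == 0) {
    warning("zero events in the denominator condition: ratio undefined")
    return(list(ratio = NA_real_, ci = c(NA_real_, NA_real_),
                conf = conf, n_boot = n_boot))
  }
  ratio <- (n_a / duration_a_us) / (n_b / duration_b_us)
  ci <- with_seed(seed, {
    ra <- stats::rpois(n_boot, n_a) / duration_a_us
    rb <- stats::rpois(n_boot, n_b) / duration_b_us
    ok <- rb > 0
    stats::quantile(ra[ok] / rb[ok], c((1 - conf) / 2, 1 - (1 - conf) / 2),
                    names = FALSE)
  })
  list(ratio = ratio, ci = ci, conf = conf, n_boot = n_boot)
}
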