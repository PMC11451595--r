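# FrameSet (time-ordered coordinates) and SiteLabelSeries (per-ion,
# per-frame compartment labels), with conversions from the event log and
# from coordinates, and multi-frame XYZ I/O.

frame_grid <- function(duration_ns, interval_ns) {
  steps <- duration_ns / interval_ns
  if (abs(steps - round(steps)) > 1e-6)
    stop_config("frame interval must divide the simulated duration")
  (0:as.integer(round(steps))) * interval_ns
}

# Per-ion compartment segments on the frame grid, replayed from an event log.
ion_segments <- function(log, interval_ns) {
  times <- frame_grid(log$duration_ns, interval_ns)
  n <- length(times)
  ev <- log$events[!is.na(log$events$ion), c("time", "ion", "dst")]
  changes <- rbind(
    data.frame(time = -Inf, ion = log$initial$ion,
               dst = log$initial$compartment, stringsAsFactors = FALSE),
    ev)
  o <- order(changes$ion, changes$time)
  changes <- changes[o, ]
  from <- rep(1L, nrow(changes))
  fin <- is.finite(changes$time)
  from[fin] <- pmax(1L, as.integer(ceiling(changes$time[fin] / interval_ns - 1e-9)) + 1L)
  k <- nrow(changes)
  same_ion_next <- c(changes$ion[-1] == changes$ion[-k], FALSE)
  to <- ifelse(same_ion_next, c(from[-1] - 1L, NA), n)
  seg <- data.frame(ion = changes$ion, label = changes$dst,
                    from = from, to = to, stringsAsFactors = FALSE)
  seg <- seg[seg$from <= seg$to & seg$from <= n, ]
  rownames(seg) <- NULL
  list(segments = seg, times = times)
}

new_site_series <- function(segments, times) {
  # merge adjacent equal-label runs per ion
  o <- order(segments$ion, segments$from)
  s <- segments[o, ]
  if (nrow(s) > 1L) {
    k <- nrow(s)
    dup <- c(FALSE, s$ion[-1] == s$ion[-k] & s$label[-1] == s$label[-k] &
               s$from[-1] == s$to[-k] + 1L)
    grp <- cumsum(!dup)
    s <- data.frame(ion = s$ion[!dup], label = s$label[!dup],
                    from = s$from[!dup],
                    to = as.integer(tapply(s$to, grp, max)),
                    stringsAsFactors = FALSE)
  }
  rownames(s) <- NULL
  structure(list(segments = s, times = times,
                 interval_ns = if (length(times) > 1) times[2] - times[1] else NA_real_,
                 n_frames = length(times)),
            class = "site_series")
}

#' Site-label series from an event log
#'
#' Samples the automaton's occupancy onto the frame grid: each ion's
#' compartment at frame time t is its compartment after all events with
#' time <= t.  This is the exact (noise-free) reference series against which
#' coordinate-derived series are validated.
#'
#' @param log A `knockon_log`.
#' @param interval_ns Frame interval (ns); default the generator's.
#' @return A `site_series`: per-ion label segments (`$segments`: ion, label,
#'   from, to frame indices), frame times and interval.
#' @export
site_series_from_log <- function(log, interval_ns = log$params$frame_interval_ns) {
  r <- ion_segments(log, interval_ns)
  new_site_series(r$segments, r$times)
}

#' Site-label series from explicit per-ion label vectors
#'
#' Convenience constructor, mainly for building small hand-written series:
#' `labels` is a named list of equal-length character vectors (one per ion,
#' one label per frame).
#'
#' @param labels Named list of per-frame label vectors.
#' @param interval_ns Frame interval (ns).
#' @return A `site_series`.
#' @export
series_from_labels <- function(labels, interval_ns = 1) {
  if (!length(labels)) stop_input("labels must be a non-empty list")
  n <- unique(vapply(labels, length, integer(1)))
  if (length(n) != 1L) stop_input("all ions must have one label per frame")
  bad <- setdiff(unique(unlist(labels)), SITE_LABELS)
  if (length(bad))
    stop_input(paste0("unknown compartment label(s): ", paste(bad, collapse = ", ")))
  ids <- if (!is.null(names(labels))) as.integer(names(labels)) else seq_along(labels)
  segs <- do.call(rbind, lapply(seq_along(labels), function(i) {
    r <- rle(labels[[i]])
    to <- cumsum(r$lengths)
    data.frame(ion = ids[i], label = r$values,
               from = c(1L, utils::head(to, -1) + 1L), to = to,
               stringsAsFactors = FALSE)
  }))
  new_site_series(segs, (seq_len(n) - 1) * interval_ns)
}

#' @export
print.site_series <- function(x, ...) {
  cat(sprintf("site_series: %d ions, %d frames at %g ns\n",
              length(unique(x$segments$ion)), x$n_frames, x$interval_ns))
  invisible(x)
}

# expand one ion's segments to a per-frame label vector
series_labels_for_ion <- function(series, ion) {
  s <- series$segments[series$segments$ion == ion, ]
  out <- character(series$n_frames)
  for (i in seq_len(nrow(s))) out[s$from[i]:s$to[i]] <- s$label[i]
  out
}

transverse_noise <- function(n, model, sigma_z, sigma_xy) {
  outer(stats::rnorm(n, 0, sigma_z), model$direction) +
    outer(stats::rnorm(n, 0, sigma_xy), model$u) +
    outer(stats::rnorm(n, 0, sigma_xy), model$v)
}

#' Emit 3D coordinates for an event log
#'
#' Realizes each frame's compartment state as coordinates on the scaffold:
#' every ion sits at its compartment's reference center plus Gaussian noise
#' (`sigma_z` axially, `sigma_xy` laterally).  In TEA mode the TEA nitrogen
#' proxy sits on-axis at the S_cav-adjacent blocked site (1.5 A intracellular
#' of the S_cav center) with lateral spread `tea_sigma` while bound.  In
#' RY785 mode a rigid 3-site proxy (m-methoxybenzene ring carbon, central
#' nitrogen, thiazole sulfur) is placed at radial offset `ry785_r0` against
#' the S6 wall of one subunit interface, ring carbon most extracellular,
#' with a shared rigid-body displacement per frame.  Seeded and reproducible.
#'
#' @param log A `knockon_log`.
#' @param model A `pore_model` built from the matching scaffold.
#' @param params A `generator_params` (defaults to the log's own).
#' @return A `frame_set`: `$times_ns`, `$atoms` (id, name, role, resid,
#'   chain), `$coords` (array frames x atoms x 3).
#' @export
emit_coordinates <- function(log, model, params = log$params) {
  r <- ion_segments(log, params$frame_interval_ns)
  times <- r$times
  nf <- length(times)
  ions <- sort(unique(r$segments$ion))
  centers <- site_centers(model)

  atoms <- data.frame(id = ions, name = "K", role = "ion", resid = "POT",
                      chain = NA_character_, stringsAsFactors = FALSE)
  if (params$mode == "TEA")
    atoms <- rbind(atoms, data.frame(id = max(ions) + 1L, name = "N",
                                     role = "ligand_N", resid = "TEA",
                                     chain = NA, stringsAsFactors = FALSE))
  if (params$mode == "RY785")
    atoms <- rbind(atoms, data.frame(
      id = max(ions) + 1:3, name = c("C", "N", "S"),
      role = c("ligand_C", "ligand_N", "ligand_S"), resid = "RY7",
      chain = NA, stringsAsFactors = FALSE))

  coords <- array(NA_real_, dim = c(nf, nrow(atoms), 3))
  with_seed(params$seed, {
    for (i in seq_along(ions)) {
      seg <- r$segments[r$segments$ion == ions[i], ]
      lab <- character(nf)
      for (k in seq_len(nrow(seg))) lab[seg$from[k]:seg$to[k]] <- seg$label[k]
      base <- centers[lab, , drop = FALSE]
      coords[, i, ] <- base + transverse_noise(nf, model, params$sigma_z,
                                               params$sigma_xy)
    }
    if (params$mode == "TEA") {
      site <- model$origin + (model$z_scav - 1.5) * model$direction
      bound <- tea_bound_per_frame(log, times)
      pos <- matrix(rep(site, each = nf), ncol = 3)
      pos[!bound, ] <- matrix(rep(centers["CYTO", ], each = sum(!bound)), ncol = 3)
      noise <- transverse_noise(nf, model, params$tea_sigma_z, params$tea_sigma)
      coords[, length(ions) + 1L, ] <- pos + noise
    }
    if (params$mode == "RY785") {
      a <- params$ry785_angle_deg * pi / 180
      radial <- cos(a) * model$u + sin(a) * model$v
      anchor <- model$origin + model$z_cavity * model$direction +
        params$ry785_r0 * radial
      offs <- c(1.8, 0, -1.8)      # ring C above, N central, S below
      wob <- matrix(stats::rnorm(nf * 3, 0, params$ry785_sigma), ncol = 3)
      for (k in 1:3)
        coords[, length(ions) + k, ] <-
          matrix(rep(anchor + offs[k] * model$direction, each = nf), ncol = 3) + wob
    }
  })
  structure(list(times_ns = times, atoms = atoms, coords = coords),
            class = "frame_set")
}

tea_bound_per_frame <- function(log, times) {
  ev <- log$events[log$events$type %in% c("bind_inhibitor", "unbind_inhibitor"), ]
  bound <- logical(length(times))
  if (nrow(ev) == 0L) return(bound)
  states <- ev$type == "bind_inhibitor"
  idx <- findInterval(times, ev$time)   # last bind/unbind with time <= t
  bound[idx > 0] <- states[idx[idx > 0]]
  bound
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("frame_set: %d frames x %d atoms (%s)\n", length(x$times_ns),
              nrow(x$atoms), paste(unique(x$atoms$resid), collapse = ", ")))
  invisible(x)
}

#' Site-label series from coordinates
#'
#' Composes [assign_site()] over the ion atoms of a frame set.  An EXT label
#' is only awarded once the ion's axial coordinate exceeds the S0 ceiling by
#' `hysteresis` (Angstrom); positions in the hysteresis band keep the S0
#' label, which prevents boundary jitter from fabricating exits.
#'
#' @param frames A `frame_set` containing atoms with role `"ion"`.
#' @param model A `pore_model`.
#' @param hysteresis EXT hysteresis margin (Angstrom, default 1).
#' @return A `site_series`.
#' @export
build_site_series <- function(frames, model, hysteresis = 1) {
  idx <- which(frames$atoms$role == "ion")
  if (!length(idx))
    stop_input("frame set contains no atoms with role 'ion'")
  nf <- length(frames$times_ns)
  segs <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    pos <- frames$coords[, idx[j], , drop = TRUE]
    if (nf == 1L) pos <- matrix(pos, ncol = 3)
    lab <- assign_site(pos, model)
    if (hysteresis > 0) {
      z <- axial_and_radial(pos, model)[, "z"]
      lab[lab == "EXT" & z < model$s0_ceiling + hysteresis] <- "S0"
    }
    r <- rle(lab)
    to <- cumsum(r$lengths)
    segs[[j]] <- data.frame(ion = frames$atoms$id[idx[j]], label = r$values,
                            from = c(1L, utils::head(to, -1) + 1L), to = to,
                            stringsAsFactors = FALSE)
  }
  new_site_series(do.call(rbind, segs), frames$times_ns)
}

#' Write / read a frame set as multi-frame XYZ
#'
#' Plain-text XYZ with one block per frame; the comment line records the
#' frame time in ns.  The reader recovers times, element names and
#' coordinates (role metadata is not stored in XYZ).
#'
#' @param frames A `frame_set`.
#' @param file Path to an .xyz file.
#' @export
write_frames_xyz <- function(frames, file) {
  con <- file(file, "w")
  on.exit(close(con))
  na <- nrow(frames$atoms)
  for (i in seq_along(frames$times_ns)) {
    writeLines(c(as.character(na), sprintf("t= %.6f ns", frames$times_ns[i])), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", frames$atoms$name,
                       frames$coords[i, , 1], frames$coords[i, , 2],
                       frames$coords[i, , 3]), con)
  }
  invisible(file)
}

#' @rdname write_frames_xyz
#' @export
read_frames_xyz <- function(file) {
  lines <- readLines(file)
  if (!length(lines)) stop_input("empty XYZ file")
  na <- as.integer(lines[1])
  block <- na + 2L
  nf <- length(lines) %/% block
  times <- as.numeric(sub("^t= *([-0-9.eE+]+) ns$", "\\1", lines[seq_len(nf) * block - block + 2L]))
  coords <- array(NA_real_, dim = c(nf, na, 3))
  nm <- character(na)
  for (i in seq_len(nf)) {
    rows <- strsplit(lines[(i - 1L) * block + 2L + seq_len(na)], " +")
    m <- matrix(as.numeric(unlist(lapply(rows, `[`, 2:4))), ncol = 3, byrow = TRUE)
    coords[i, , ] <- m
    if (i == 1L) nm <- vapply(rows, `[`, character(1), 1L)
  }
  structure(list(times_ns = times,
                 atoms = data.frame(id = seq_len(na), name = nm, role = NA,
                                    resid = NA, chain = NA,
                                    stringsAsFactors = FALSE),
                 coords = coords),
            class = "frame_set")
}
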