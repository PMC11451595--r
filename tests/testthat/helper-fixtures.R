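# Shared fixtures: default scaffold/model are deterministic, build once.

sc_default <- make_scaffold()
model_default <- build_pore_model(sc_default)

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(xyz, rot, shift) {
  sweep(as.matrix(xyz) %*% t(rot), 2, shift, `+`)
}

transform_scaffold <- function(sc, rot, shift) {
  xyz <- apply_rigid(sc[, c("x", "y", "z")], rot, shift)
  sc$x <- xyz[, 1]; sc$y <- xyz[, 2]; sc$z <- xyz[, 3]
  sc
}

# minimal frame_set around explicit coordinates
make_frames <- function(coords, roles, names = roles, resid = NA) {
  structure(list(
    times_ns = seq_len(dim(coords)[1]) - 1,
    atoms = data.frame(id = seq_len(dim(coords)[2]), name = names,
                       role = roles, resid = resid, chain = NA,
                       stringsAsFactors = FALSE),
    coords = coords), class = "frame_set")
}

# all-pairs brute-force contact oracle (independent of find_contacts)
brute_contacts <- function(frames, scaffold, cutoff) {
  lig <- which(frames$atoms$role %in% c("ligand_C", "ligand_S"))
  sc <- scaffold[scaffold$role == "s6_sidechain", ]
  res <- paste0(c(VAL = "V", PRO = "P", ILE = "I")[sc$resid], sc$resno)
  out <- list()
  for (f in seq_along(frames$times_ns)) {
    for (j in seq_len(nrow(sc))) {
      np <- 0L
      for (l in lig) {
        d <- sqrt(sum((frames$coords[f, l, ] -
                         as.numeric(sc[j, c("x", "y", "z")]))^2))
        if (d <= cutoff) np <- np + 1L
      }
      if (np > 0L)
        out[[length(out) + 1L]] <- data.frame(
          frame = f, residue = res[j], subunit = sc$chain[j], n_pairs = np,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(0), residue = character(0),
                      subunit = character(0), n_pairs = integer(0)))
  df <- do.call(rbind, out)
  df[order(df$frame, df$residue, df$subunit), ]
}

expand_labels <- function(series, ion) {
  s <- series$segments[series$segments$ion == ion, ]
  out <- character(series$n_frames)
  for (i in seq_len(nrow(s))) out[s$from[i]:s$to[i]] <- s$label[i]
  out
}
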