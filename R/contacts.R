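# Hydrophobic contact statistics between a bound ligand and the S6 cavity
# wall: a contact is a ligand C/S heavy atom within the cutoff of a
# side-chain carbon of V409, P406, I405, I401 or V398 in any subunit.

S6_RESIDUES <- c("V409", "P406", "I405", "I401", "V398")

aa3to1 <- c(VAL = "V", PRO = "P", ILE = "I", GLY = "G", TYR = "Y", THR = "T")

s6_residue_label <- function(scaffold) {
  paste0(aa3to1[scaffold$resid], scaffold$resno)
}

#' Ligand-sidechain contacts per frame
#'
#' For every frame, finds which subunits' side-chain carbons (residues V409,
#' P406, I405, I401, V398 on helix S6) lie within `cutoff` of any ligand C
#' or S heavy atom (ligand nitrogens and hydrogens are not counted).  The
#' criterion is a plain distance threshold (<= cutoff), symmetric in atom
#' order and deterministic.
#'
#' @param frames A `frame_set` containing ligand atoms with roles
#'   `ligand_C` / `ligand_S`.
#' @param scaffold The matching `scaffold` (provides the S6 side-chain
#'   pseudo-atoms with subunit labels).
#' @param cutoff Contact distance (Angstrom, default 4.5).
#' @return A `contact_table`: data.frame `frame`, `residue`, `subunit`,
#'   `n_pairs` (number of atom pairs within cutoff), one row per contacted
#'   frame-residue-subunit; attributes `cutoff`, `n_frames`, `residues`.
#' @export
find_contacts <- function(frames, scaffold, cutoff = 4.5) {
  if (!is_scalar_num(cutoff) || cutoff <= 0)
    stop_value("cutoff must be positive")
  lig <- which(frames$atoms$role %in% c("ligand_C", "ligand_S"))
  if (!length(lig)) stop_input("frame set contains no ligand C/S atoms")
  sc <- scaffold[scaffold$role == "s6_sidechain", ]
  sc_pos <- as.matrix(sc[, c("x", "y", "z")])
  res <- s6_residue_label(sc)
  nf <- length(frames$times_ns)
  ns <- nrow(sc)
  cut2 <- cutoff^2

  pairs <- matrix(0L, nrow = nf, ncol = ns)     # atom pairs within cutoff
  for (l in lig) {
    d2 <- matrix(0, nf, ns)
    for (d in 1:3)
      d2 <- d2 + (outer(frames$coords[, l, d], sc_pos[, d], "-"))^2
    pairs <- pairs + (d2 <= cut2)
  }
  hit <- which(pairs > 0L, arr.ind = TRUE)
  out <- data.frame(frame = hit[, 1],
                    residue = res[hit[, 2]],
                    subunit = sc$chain[hit[, 2]],
                    n_pairs = pairs[hit],
                    stringsAsFactors = FALSE)
  out <- out[order(out$frame, out$residue, out$subunit), ]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  attr(out, "n_frames") <- nf
  attr(out, "residues") <- intersect(S6_RESIDUES, unique(res))
  class(out) <- c("contact_table", "data.frame")
  out
}

#' Distribution of simultaneous subunit contacts per residue
#'
#' For each S6 residue, the percentage of frames in which its side chain is
#' contacted in 0, 1, 2, 3 or 4 distinct subunits (a residue may touch the
#' ligand in two adjacent subunits at once).  Percentages sum to 100 per
#' residue; the modal count is reported as the headline statistic.  The raw
#' atom-pair multiplicity is retained in the contact table for users who
#' prefer atom-level counting.
#'
#' @param table A `contact_table` from [find_contacts()].
#' @return List with `distribution` (data.frame residue, count, percent) and
#'   `modal` (named integer, per residue).
#' @export
contact_distribution <- function(table) {
  nf <- attr(table, "n_frames")
  residues <- attr(table, "residues") %||% S6_RESIDUES
  if (is.null(nf) || nf < 1L) stop_input("contact table lacks frame count")
  rows <- list()
  modal <- stats::setNames(integer(length(residues)), residues)
  for (res in residues) {
    t_res <- table[table$residue == res, ]
    per_frame <- integer(nf)
    if (nrow(t_res)) {
      cnt <- tapply(t_res$subunit, t_res$frame, function(x) length(unique(x)))
      per_frame[as.integer(names(cnt))] <- as.integer(cnt)
    }
    pct <- vapply(0:4, function(k) 100 * mean(per_frame == k), numeric(1))
    rows[[res]] <- data.frame(residue = res, count = 0:4, percent = pct,
                              stringsAsFactors = FALSE)
    modal[res] <- (0:4)[which.max(pct)]
  }
  list(distribution = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       modal = modal)
}

#' Write a contact table as TSV
#'
#' @param table A `contact_table`.
#' @param file Output path.
#' @export
write_contact_table <- function(table, file) {
  utils::write.table(as.data.frame(table), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
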