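# Geometric contact detection across a complex interface: salt bridges
# (side-chain/terminal donor N to acceptor O under 4.0 Angstrom), hydrogen
# bonds (distance-plus-angle criteria; aromatic acceptors excluded), and
# intra-chain disulfides.  A cell-list neighbour search keeps detection
# O(n) while remaining exactly equivalent to brute-force enumeration.

# Donor/acceptor atom dictionaries ------------------------------------------

.sb_donor_atoms <- function(include_his = TRUE) {
  d <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ")
  if (include_his) d$HIS <- c("ND1", "NE2")
  d
}
.sb_acceptor_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

# Hydrogen-bond donor heavy atoms (with antecedent used for the fallback
# angle): backbone amide N plus polar side-chain donors.
.hb_donors <- list(
  backbone = c(N = "CA"),
  SER = c(OG = "CB"), THR = c(OG1 = "CB"), TYR = c(OH = "CZ"),
  CYS = c(SG = "CB"), ASN = c(ND2 = "CG"), GLN = c(NE2 = "CD"),
  LYS = c(NZ = "CE"), ARG = c(NE = "CD", NH1 = "CZ", NH2 = "CZ"),
  HIS = c(ND1 = "CG", NE2 = "CD2"), TRP = c(NE1 = "CD1"))

# Acceptors with their antecedent atom (for the D-A-AA angle); aromatic ring
# atoms are deliberately absent (no pi hydrogen bonds).
.hb_acceptors <- list(
  backbone = c(O = "C", OXT = "C"),
  ASP = c(OD1 = "CG", OD2 = "CG"), GLU = c(OE1 = "CD", OE2 = "CD"),
  ASN = c(OD1 = "CG"), GLN = c(OE1 = "CD"),
  SER = c(OG = "CB"), THR = c(OG1 = "CB"), TYR = c(OH = "CZ"),
  HIS = c(ND1 = "CG", NE2 = "CD2"), MET = c(SD = "CG"))

# First/last standard residue (by file order) per chain -> terminal atoms.
.terminal_atoms <- function(atoms) {
  std <- atoms[atoms$std_aa & !atoms$het, , drop = FALSE]
  out <- list(nterm = character(0), cterm = character(0))
  for (ch in unique(std$chain)) {
    sub <- std[std$chain == ch, , drop = FALSE]
    keys <- unique(paste(sub$resno, sub$insert, sep = "|"))
    out$nterm <- c(out$nterm, paste(ch, keys[1], sep = "|"))
    out$cterm <- c(out$cterm, paste(ch, keys[length(keys)], sep = "|"))
  }
  out
}

.atom_key <- function(atoms) paste(atoms$chain, atoms$resno, atoms$insert,
                                   sep = "|")

#' Find salt bridges across a complex interface
#'
#' Atom pairs of a donor nitrogen (Arg NE/NH1/NH2, Lys NZ, optionally His
#' ND1/NE2, plus chain N-terminal amide N) and an acceptor oxygen (Asp
#' OD1/OD2, Glu OE1/OE2, plus C-terminal O/OXT) on opposite sides of the
#' partition, strictly closer than `cutoff`.  Pairs are counted at the atom
#' level; aggregate over residues downstream if residue pairs are wanted.
#'
#' @param partition A [partition_complex()] result.
#' @param cutoff Distance cutoff in Angstrom (strict `<`), default 4.0.
#' @param include_termini Include terminal charged groups.
#' @param include_his Treat histidine as a donor.
#' @param method `"grid"` (cell list) or `"brute"` (all pairs); identical
#'   output guaranteed.
#' @return Data frame of bridges: donor/acceptor chain, residue, atom, and
#'   `distance`.
#' @export
find_salt_bridges <- function(partition, cutoff = 4.0, include_termini = TRUE,
                              include_his = TRUE,
                              method = c("grid", "brute")) {
  method <- match.arg(method)
  at <- partition$model$atoms
  don_tab <- .sb_donor_atoms(include_his)
  is_don <- mapply(function(r, a) {
    !is.null(don_tab[[r]]) && a %in% don_tab[[r]]
  }, at$resid, at$elety)
  is_acc <- mapply(function(r, a) {
    !is.null(.sb_acceptor_atoms[[r]]) && a %in% .sb_acceptor_atoms[[r]]
  }, at$resid, at$elety)
  if (include_termini) {
    term <- .terminal_atoms(at)
    key <- .atom_key(at)
    is_don <- is_don | (key %in% term$nterm & at$elety == "N" & at$std_aa)
    is_acc <- is_acc | (key %in% term$cterm & at$elety %in% c("O", "OXT") &
                          at$std_aa)
  }
  don <- at[is_don & at$std_aa, , drop = FALSE]
  acc <- at[is_acc & at$std_aa, , drop = FALSE]
  pairs <- .cross_pairs(don, acc, partition, cutoff, method,
                        strict = TRUE)
  if (nrow(pairs) == 0L)
    return(data.frame(donor_chain = character(0), donor_resno = integer(0),
                      donor_resid = character(0), donor_atom = character(0),
                      acceptor_chain = character(0), acceptor_resno = integer(0),
                      acceptor_resid = character(0), acceptor_atom = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE))
  data.frame(donor_chain = don$chain[pairs$i], donor_resno = don$resno[pairs$i],
             donor_resid = don$resid[pairs$i], donor_atom = don$elety[pairs$i],
             acceptor_chain = acc$chain[pairs$j],
             acceptor_resno = acc$resno[pairs$j],
             acceptor_resid = acc$resid[pairs$j],
             acceptor_atom = acc$elety[pairs$j],
             distance = pairs$d, stringsAsFactors = FALSE)
}

# Donor/acceptor cross pairs on opposite sides of the partition within
# cutoff.  Returns data.frame(i, j, d) indexing rows of `don` and `acc`.
.cross_pairs <- function(don, acc, partition, cutoff, method, strict = TRUE) {
  if (nrow(don) == 0L || nrow(acc) == 0L)
    return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  side <- function(ch) ifelse(ch == partition$segment, "S",
                              ifelse(ch %in% partition$partner, "P", "-"))
  sd <- side(don$chain)
  sa <- side(acc$chain)
  cmp <- function(i, j) (sd[i] == "S" & sa[j] == "P") |
    (sd[i] == "P" & sa[j] == "S")
  if (method == "brute") {
    idx <- expand.grid(i = seq_len(nrow(don)), j = seq_len(nrow(acc)))
    d <- sqrt(rowSums((as.matrix(don[idx$i, c("x", "y", "z")]) -
                       as.matrix(acc[idx$j, c("x", "y", "z")]))^2))
    ok <- if (strict) d < cutoff else d <= cutoff
    ok <- ok & cmp(idx$i, idx$j)
    return(data.frame(i = idx$i[ok], j = idx$j[ok], d = d[ok]))
  }
  # grid: pool both sets, find neighbour pairs, keep donor-acceptor ones
  coords <- rbind(as.matrix(don[, c("x", "y", "z")]),
                  as.matrix(acc[, c("x", "y", "z")]))
  pr <- .neighbor_pairs(coords, cutoff)
  if (nrow(pr) == 0L)
    return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  nd <- nrow(don)
  da <- pr[, 1] <= nd & pr[, 2] > nd    # donor, acceptor
  ad <- pr[, 2] <= nd & pr[, 1] > nd
  i <- c(pr[da, 1], pr[ad, 2])
  j <- c(pr[da, 2], pr[ad, 1]) - nd
  d <- sqrt(rowSums((as.matrix(don[i, c("x", "y", "z")]) -
                     as.matrix(acc[j, c("x", "y", "z")]))^2))
  ok <- (if (strict) d < cutoff else d <= cutoff) & cmp(i, j)
  out <- data.frame(i = i[ok], j = j[ok], d = d[ok])
  out[order(out$i, out$j), , drop = FALSE]
}

#' Find hydrogen bonds across a complex interface
#'
#' Donor-acceptor pairs (backbone amides and polar side chains; aromatic
#' ring acceptors excluded) meeting geometric criteria: donor-acceptor
#' distance `d_DA <= d_max` and, where an amide hydrogen can be placed by
#' ideal geometry, a D-H...A angle of at least `angle_min`; for donors whose
#' hydrogen position is rotationally ambiguous the fallback criterion is the
#' D-A-antecedent angle at the acceptor (>= `angle_min`).
#'
#' @param partition A [partition_complex()] result.
#' @param d_max Maximum donor-acceptor distance, Angstrom.
#' @param angle_min Minimum angle, degrees.
#' @param method `"grid"` or `"brute"`.
#' @return Data frame of bonds with donor/acceptor identifiers, `d_da` and
#'   the angle applied (`angle`, degrees; D-H-A where H was placed,
#'   otherwise D-A-AA).
#' @export
find_hbonds <- function(partition, d_max = 3.9, angle_min = 90,
                        method = c("grid", "brute")) {
  method <- match.arg(method)
  at <- partition$model$atoms
  at <- at[at$std_aa & !at$het, , drop = FALSE]

  pick <- function(tab) {
    hit <- vector("list", 0L)
    # backbone entries apply to every residue type
    bb <- tab$backbone
    sel <- at$elety %in% names(bb)
    if (any(sel)) {
      sub <- at[sel, , drop = FALSE]
      sub$ante <- unname(bb[sub$elety])
      hit[["bb"]] <- sub
    }
    for (res in setdiff(names(tab), "backbone")) {
      sel <- at$resid == res & at$elety %in% names(tab[[res]])
      if (any(sel)) {
        sub <- at[sel, , drop = FALSE]
        sub$ante <- unname(tab[[res]][sub$elety])
        hit[[res]] <- sub
      }
    }
    do.call(rbind, hit)
  }
  don <- pick(.hb_donors)
  acc <- pick(.hb_acceptors)
  # proline has no amide hydrogen
  if (!is.null(don))
    don <- don[!(don$resid == "PRO" & don$elety == "N"), , drop = FALSE]
  if (is.null(don) || is.null(acc) || nrow(don) == 0L || nrow(acc) == 0L)
    return(.empty_hbonds())

  pairs <- .cross_pairs(don, acc, partition, d_max, method, strict = FALSE)
  if (nrow(pairs) == 0L) return(.empty_hbonds())

  # self pairs (same residue) are not bonds
  same <- paste(don$chain[pairs$i], don$resno[pairs$i], don$insert[pairs$i]) ==
    paste(acc$chain[pairs$j], acc$resno[pairs$j], acc$insert[pairs$j])
  pairs <- pairs[!same, , drop = FALSE]
  if (nrow(pairs) == 0L) return(.empty_hbonds())

  key_all <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  coord_of <- function(chain, resno, insert, elety) {
    idx <- match(paste(chain, resno, insert, elety, sep = "|"), key_all)
    if (is.na(idx)) return(NULL)
    c(at$x[idx], at$y[idx], at$z[idx])
  }

  keep <- logical(nrow(pairs))
  angle <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    D <- c(don$x[i], don$y[i], don$z[i])
    A <- c(acc$x[j], acc$y[j], acc$z[j])
    h <- NULL
    if (don$elety[i] == "N") {
      # amide H by ideal geometry: in the C(prev)-N-CA plane, bisecting
      ca <- coord_of(don$chain[i], don$resno[i], don$insert[i], "CA")
      cprev <- .prev_carbonyl(at, don$chain[i], don$resno[i], don$insert[i])
      if (!is.null(ca) && !is.null(cprev)) {
        u <- (D - ca) / sqrt(sum((D - ca)^2)) + (D - cprev) / sqrt(sum((D - cprev)^2))
        nu <- sqrt(sum(u^2))
        if (nu > 1e-6) h <- D + u / nu * 1.01
      }
    }
    if (!is.null(h)) {
      angle[k] <- .angle_deg(D, h, A)
      keep[k] <- angle[k] >= angle_min
    } else {
      aa <- coord_of(acc$chain[j], acc$resno[j], acc$insert[j], acc$ante[j])
      if (is.null(aa)) { keep[k] <- TRUE; angle[k] <- NA } else {
        angle[k] <- .angle_deg(D, A, aa)
        keep[k] <- angle[k] >= angle_min
      }
    }
  }
  pairs <- pairs[keep, , drop = FALSE]
  angle <- angle[keep]
  if (nrow(pairs) == 0L) return(.empty_hbonds())
  data.frame(donor_chain = don$chain[pairs$i], donor_resno = don$resno[pairs$i],
             donor_resid = don$resid[pairs$i], donor_atom = don$elety[pairs$i],
             acceptor_chain = acc$chain[pairs$j],
             acceptor_resno = acc$resno[pairs$j],
             acceptor_resid = acc$resid[pairs$j],
             acceptor_atom = acc$elety[pairs$j],
             d_da = pairs$d, angle = angle, stringsAsFactors = FALSE)
}

.empty_hbonds <- function() {
  data.frame(donor_chain = character(0), donor_resno = integer(0),
             donor_resid = character(0), donor_atom = character(0),
             acceptor_chain = character(0), acceptor_resno = integer(0),
             acceptor_resid = character(0), acceptor_atom = character(0),
             d_da = numeric(0), angle = numeric(0), stringsAsFactors = FALSE)
}

# Carbonyl C of the preceding residue in the same chain (file order).
.prev_carbonyl <- function(at, chain, resno, insert) {
  sub <- at[at$chain == chain & at$std_aa, , drop = FALSE]
  keys <- unique(paste(sub$resno, sub$insert, sep = "|"))
  pos <- match(paste(resno, insert, sep = "|"), keys)
  if (is.na(pos) || pos == 1L) return(NULL)
  prev <- keys[pos - 1L]
  idx <- which(paste(sub$resno, sub$insert, sep = "|") == prev &
                 sub$elety == "C")
  if (length(idx) == 0L) return(NULL)
  c(sub$x[idx[1]], sub$y[idx[1]], sub$z[idx[1]])
}

#' Find disulfide bonds within a chain
#'
#' Cys SG-SG pairs at most `cutoff` apart; each SG participates in at most
#' one bond (greedy pairing, nearest pair first).
#'
#' @param model A `structure_model`.
#' @param chain Chain identifier; `NULL` scans every chain separately.
#' @param cutoff Maximum SG-SG distance, Angstrom (default 2.5, covering the
#'   2.05 canonical bond plus coordinate error).
#' @return Data frame with the two residue numbers and the distance.
#' @export
find_disulfides <- function(model, chain = NULL, cutoff = 2.5) {
  at <- model$atoms
  sg <- at[at$resid == "CYS" & at$elety == "SG" & at$std_aa, , drop = FALSE]
  if (!is.null(chain)) sg <- sg[sg$chain == chain, , drop = FALSE]
  empty <- data.frame(chain = character(0), resno1 = integer(0),
                      resno2 = integer(0), distance = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(sg) < 2L) return(empty)
  out <- list()
  for (ch in unique(sg$chain)) {
    sub <- sg[sg$chain == ch, , drop = FALSE]
    if (nrow(sub) < 2L) next
    cmb <- t(utils::combn(nrow(sub), 2L))
    d <- sqrt(rowSums((as.matrix(sub[cmb[, 1], c("x", "y", "z")]) -
                       as.matrix(sub[cmb[, 2], c("x", "y", "z")]))^2))
    ok <- d <= cutoff
    cmb <- cmb[ok, , drop = FALSE]; d <- d[ok]
    used <- logical(nrow(sub))
    for (k in order(d)) {
      i <- cmb[k, 1]; j <- cmb[k, 2]
      if (used[i] || used[j]) next
      used[i] <- used[j] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        chain = ch, resno1 = sub$resno[i], resno2 = sub$resno[j],
        distance = d[k], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Summarise interface contacts
#'
#' Raw salt-bridge and hydrogen-bond counts plus counts normalised per
#' 100 Angstrom^2 of interface area.
#'
#' @param bridges Result of [find_salt_bridges()].
#' @param hbonds Result of [find_hbonds()].
#' @param interface_area Interface area in Angstrom^2 (half-sum convention).
#' @return A `contact_summary` list.
#' @export
summarize_contacts <- function(bridges, hbonds, interface_area) {
  nsb <- nrow(bridges)
  nhb <- nrow(hbonds)
  if (interface_area <= 0) {
    if (nsb + nhb > 0)
      stop("zero interface area but non-zero contact counts")
    return(structure(list(n_salt_bridges = 0L, n_hbonds = 0L,
                          salt_bridges_per_100A2 = 0, hbonds_per_100A2 = 0,
                          interface_area = interface_area),
                     class = "contact_summary"))
  }
  structure(list(n_salt_bridges = nsb, n_hbonds = nhb,
                 salt_bridges_per_100A2 = nsb / (interface_area / 100),
                 hbonds_per_100A2 = nhb / (interface_area / 100),
                 interface_area = interface_area),
            class = "contact_summary")
}

#' @export
print.contact_summary <- function(x, ...) {
  cat("contact_summary over ", sprintf("%.1f", x$interface_area), " A^2:\n",
      "  salt bridges: ", x$n_salt_bridges, " (",
      sprintf("%.3f", x$salt_bridges_per_100A2), " / 100 A^2)\n",
      "  hydrogen bonds: ", x$n_hbonds, " (",
      sprintf("%.3f", x$hbonds_per_100A2), " / 100 A^2)\n", sep = "")
  invisible(x)
}
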