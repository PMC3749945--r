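# Internal-coordinate peptide builder.  Produces idealised heavy-atom
# geometry (Engh/Huber-like bond lengths and angles, trans side-chain
# dihedrals) sufficient for surface-area and contact geometry; it makes no
# claim of being energy-minimised.

# Backbone ideal values
.bb <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8
)

# Side-chain topology: per residue, rows of
# (atom, parent a, parent b, parent c, bond, angle, dihedral).
# Atom is bonded to parent c; angle is b-c-atom; dihedral a-b-c-atom.
.sidechain_topology <- local({
  t0 <- function(...) {
    m <- matrix(c(...), ncol = 7, byrow = TRUE)
    data.frame(atom = m[, 1], a = m[, 2], b = m[, 3], c = m[, 4],
               bond = as.numeric(m[, 5]), angle = as.numeric(m[, 6]),
               dihedral = as.numeric(m[, 7]), stringsAsFactors = FALSE)
  }
  list(
    GLY = NULL,
    ALA = t0("CB", "C", "N", "CA", 1.521, 110.5, -122.6),
    SER = t0("CB", "C", "N", "CA", 1.530, 110.5, -122.6,
             "OG", "N", "CA", "CB", 1.417, 110.8, 180),
    CYS = t0("CB", "C", "N", "CA", 1.530, 110.5, -122.6,
             "SG", "N", "CA", "CB", 1.808, 113.8, 180),
    THR = t0("CB", "C", "N", "CA", 1.540, 110.5, -122.6,
             "OG1", "N", "CA", "CB", 1.433, 109.6, 180,
             "CG2", "N", "CA", "CB", 1.521, 110.5, -60),
    VAL = t0("CB", "C", "N", "CA", 1.540, 110.5, -122.6,
             "CG1", "N", "CA", "CB", 1.527, 110.5, 180,
             "CG2", "N", "CA", "CB", 1.527, 110.5, -60),
    LEU = t0("CB", "C", "N", "CA", 1.530, 110.5, -122.6,
             "CG", "N", "CA", "CB", 1.530, 116.3, 180,
             "CD1", "CA", "CB", "CG", 1.521, 110.7, 180,
             "CD2", "CA", "CB", "CG", 1.521, 110.7, 60),
    ILE = t0("CB", "C", "N", "CA", 1.540, 110.5, -122.6,
             "CG1", "N", "CA", "CB", 1.530, 110.4, 180,
             "CG2", "N", "CA", "CB", 1.521, 110.5, -60,
             "CD1", "CA", "CB", "CG1", 1.513, 113.8, 180),
    MET = t0("CB", "C", "N", "CA", 1.530, 110.5, -122.6,
             "CG", "N", "CA", "CB", 1.520, 114.1, 180,
             "SD", "CA", "CB", "CG", 1.803, 112.7, 180,
             "CE", "CB", "CG", "SD", 1.791, 100.9, 180),
    PRO = t0("CB", "C", "N", "CA", 1.530, 103.0, -120.0,
             "CG", "N", "CA", "CB", 1.495, 104.5, 30,
             "CD", "CA", "CB", "CG", 1.507, 105.5, -35),
    PHE = t0("CB", "C", "N", "CA", 1.530, 110.5, -122.6,
             "CG", "N", "CA", "CB", 1.502, 113.8, 180,
             "CD1", "CA", "CB", "CG", 1.391, 120.8, 90,
             "CD2", "CA", "CB", "CG", 1.391, 120.8, -90,
             "CE1", "CB", "CG", "CD1", 1.393, 120.8, 180,
             "CE2", "CB", "CG", "CD2", 1.393, 120.8, 180,
             "CZ", "CG", "CD1", "CE1", 1.390, 120.1, 0),
    TYR = t0("CB", "C", "N", "CA", 1.530, 110.5, -122.6,
             "CG", "N", "CA", "CB", 1.502, 113.8, 180,
             "CD1", "CA", "CB", "CG", 1.391, 120.8, 90,
             "CD2", "CA", "CB", "CG", 1.391, 120.8, -90,
             "CE1", "CB", "CG", "CD1", 1.393, 121.1, 180,
             "CE2", "CB", "CG", "CD2", 1.393, 121.1, 180,
             "CZ", "CG", "CD1", "CE1", 1.380, 119.5, 0,
             "OH", "CD1", "CE1", "CZ", 1.376, 119.9, 180),
    TRP = t0("CB", "C", "N", "CA", 1.530, 110.5, -122.6,
             "CG", "N", "CA", "CB", 1.498, 113.6, 180,
             "CD1", "CA", "CB", "CG", 1.365, 126.9, 90,
             "CD2", "CA", "CB", "CG", 1.433, 126.6, -90,
             "NE1", "CB", "CG", "CD1", 1.374, 110.2, 180,
             "CE2", "CB", "CG", "CD2", 1.409, 107.2, 180,
             "CE3", "CB", "CG", "CD2", 1.398, 133.9, 0,
             "CZ2", "CG", "CD2", "CE2", 1.394, 122.4, 180,
             "CZ3", "CG", "CD2", "CE3", 1.382, 118.6, 180,
             "CH2", "CD2", "CE2", "CZ2", 1.368, 117.5, 180),
    ASP = t0("CB", "C", "N", "CA", 1.530, 110.5, -122.6,
             "CG", "N", "CA", "CB", 1.516, 112.6, 180,
             "OD1", "CA", "CB", "CG", 1.249, 118.4, 0,
             "OD2", "CA", "CB", "CG", 1.249, 118.4, 180),
    ASN = t0("CB", "C", "N", "CA", 1.530, 110.5, -122.6,
             "CG", "N", "CA", "CB", 1.516, 112.6, 180,
             "OD1", "CA", "CB", "CG", 1.231, 120.8, 0,
             "ND2", "CA", "CB", "CG", 1.328, 116.4, 180),
    GLU = t0("CB", "C", "N", "CA", 1.530, 110.5, -122.6,
             "CG", "N", "CA", "CB", 1.520, 114.1, 180,
             "CD", "CA", "CB", "CG", 1.516, 112.6, 180,
             "OE1", "CB", "CG", "CD", 1.249, 118.4, 0,
             "OE2", "CB", "CG", "CD", 1.249, 118.4, 180),
    GLN = t0("CB", "C", "N", "CA", 1.530, 110.5, -122.6,
             "CG", "N", "CA", "CB", 1.520, 114.1, 180,
             "CD", "CA", "CB", "CG", 1.516, 112.6, 180,
             "OE1", "CB", "CG", "CD", 1.231, 120.8, 0,
             "NE2", "CB", "CG", "CD", 1.328, 116.4, 180),
    LYS = t0("CB", "C", "N", "CA", 1.530, 110.5, -122.6,
             "CG", "N", "CA", "CB", 1.520, 114.1, 180,
             "CD", "CA", "CB", "CG", 1.520, 111.3, 180,
             "CE", "CB", "CG", "CD", 1.520, 111.3, 180,
             "NZ", "CG", "CD", "CE", 1.489, 111.9, 180),
    ARG = t0("CB", "C", "N", "CA", 1.530, 110.5, -122.6,
             "CG", "N", "CA", "CB", 1.520, 114.1, 180,
             "CD", "CA", "CB", "CG", 1.520, 111.3, 180,
             "NE", "CB", "CG", "CD", 1.461, 112.0, 180,
             "CZ", "CG", "CD", "NE", 1.329, 124.2, 180,
             "NH1", "CD", "NE", "CZ", 1.326, 120.0, 0,
             "NH2", "CD", "NE", "CZ", 1.326, 120.0, 180),
    HIS = t0("CB", "C", "N", "CA", 1.530, 110.5, -122.6,
             "CG", "N", "CA", "CB", 1.497, 113.8, 180,
             "ND1", "CA", "CB", "CG", 1.378, 122.7, 90,
             "CD2", "CA", "CB", "CG", 1.354, 131.0, -90,
             "CE1", "CB", "CG", "ND1", 1.320, 109.0, 180,
             "NE2", "CB", "CG", "CD2", 1.374, 107.2, 180)
  )
})

#' Build an idealised peptide
#'
#' Construct heavy-atom coordinates for a peptide of the given sequence
#' with uniform backbone dihedrals.  The default `phi = psi = 180` degrees
#' yields a fully extended chain, the conformation used for the Gly-X-Gly
#' reference surface areas.
#'
#' @param sequence Character vector of three-letter residue codes.
#' @param phi,psi Backbone dihedrals in degrees (recycled over residues).
#' @param chain_id Chain identifier for the output.
#' @param resno_start First residue number.
#' @param oxt Add a terminal carboxylate OXT atom.
#' @return An atom data frame (see [model_from_atoms()]) with columns
#'   `chain`, `resno`, `insert`, `resid`, `elety`, `elesy`, `x`, `y`, `z`,
#'   `o`, `het`.
#' @export
build_peptide <- function(sequence, phi = 180, psi = 180, chain_id = "A",
                          resno_start = 1L, oxt = TRUE) {
  sequence <- toupper(sequence)
  bad <- setdiff(sequence, standard_aa())
  if (length(bad)) stop("unknown residue type(s): ", paste(bad, collapse = ", "))
  n <- length(sequence)
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)

  rows <- list()
  add <- function(resno, resid, atom, xyz) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain_id, resno = resno, insert = "", resid = resid,
      elety = atom, elesy = .element_from_name(atom),
      x = xyz[1], y = xyz[2], z = xyz[3], o = 1, het = FALSE,
      std_aa = TRUE, stringsAsFactors = FALSE)
  }

  # backbone
  pos <- vector("list", n)  # per residue: named list N, CA, C
  for (i in seq_len(n)) {
    if (i == 1L) {
      Npos <- c(0, 0, 0)
      CApos <- c(.bb$n_ca, 0, 0)
      Cpos <- .place_atom(c(0, 1, 0), Npos, CApos,
                          .bb$ca_c, .bb$ang_n_ca_c, phi[1])
    } else {
      p <- pos[[i - 1L]]
      Npos <- .place_atom(p$N, p$CA, p$C, .bb$c_n, .bb$ang_ca_c_n, psi[i - 1L])
      CApos <- .place_atom(p$CA, p$C, Npos, .bb$n_ca, .bb$ang_c_n_ca, 180)
      Cpos <- .place_atom(p$C, Npos, CApos, .bb$ca_c, .bb$ang_n_ca_c, phi[i])
    }
    pos[[i]] <- list(N = Npos, CA = CApos, C = Cpos)
  }

  for (i in seq_len(n)) {
    resno <- resno_start + i - 1L
    p <- pos[[i]]
    add(resno, sequence[i], "N", p$N)
    add(resno, sequence[i], "CA", p$CA)
    add(resno, sequence[i], "C", p$C)
    # carbonyl O anti to the next amide N (or trans for the last residue)
    opsi <- if (i < n) psi[i] else 180
    add(resno, sequence[i], "O",
        .place_atom(p$N, p$CA, p$C, .bb$c_o, .bb$ang_ca_c_o, opsi + 180))
    if (oxt && i == n)
      add(resno, sequence[i], "OXT",
          .place_atom(p$N, p$CA, p$C, 1.25, 117.0, opsi))
    topo <- .sidechain_topology[[sequence[i]]]
    if (!is.null(topo)) {
      placed <- list(N = p$N, CA = p$CA, C = p$C)
      for (j in seq_len(nrow(topo))) {
        xyz <- .place_atom(placed[[topo$a[j]]], placed[[topo$b[j]]],
                           placed[[topo$c[j]]], topo$bond[j], topo$angle[j],
                           topo$dihedral[j])
        placed[[topo$atom[j]]] <- xyz
        add(resno, sequence[i], topo$atom[j], xyz)
      }
    }
  }
  do.call(rbind, rows)
}

#' Build one idealised residue
#'
#' A standalone residue (backbone plus side chain) in a local frame, used as
#' a rigid unit when assembling designed toy complexes.
#'
#' @inheritParams build_peptide
#' @param res_name Three-letter residue code.
#' @return Atom data frame as in [build_peptide()].
#' @export
build_residue <- function(res_name, chain_id = "A", resno_start = 1L) {
  build_peptide(res_name, chain_id = chain_id, resno_start = resno_start,
                oxt = FALSE)
}

# Rigid-transform an atom data frame so that atom `anchor` lands at `at` and
# the `orient` atom direction (anchor -> orient) points along `towards`.
.orient_residue <- function(atoms, anchor, at, orient = NULL, towards = NULL) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  a <- xyz[match(anchor, atoms$elety), ]
  if (!is.null(orient) && !is.null(towards)) {
    b <- xyz[match(orient, atoms$elety), ]
    v <- b - a
    v <- v / sqrt(sum(v^2))
    w <- towards / sqrt(sum(towards^2))
    axis <- .cross3(v, w)
    s <- sqrt(sum(axis^2))
    if (s > 1e-12) {
      theta <- atan2(s, sum(v * w))
      R <- .rotation_matrix(axis, theta)
      xyz <- sweep(xyz, 2, a) %*% t(R)
      xyz <- sweep(xyz, 2, a, `+`)
    } else if (sum(v * w) < 0) {
      ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      R <- .rotation_matrix(.cross3(v, ref), pi)
      xyz <- sweep(xyz, 2, a) %*% t(R)
      xyz <- sweep(xyz, 2, a, `+`)
    }
  }
  shift <- at - xyz[match(anchor, atoms$elety), ]
  xyz <- sweep(xyz, 2, shift, `+`)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}
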