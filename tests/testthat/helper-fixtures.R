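# Shared helpers: tiny hand-built models and independent brute-force
# oracles used across the suite.

# Minimal atom row / single-sphere models -----------------------------------

atom_row <- function(chain = "A", resno = 1L, resid = "GLY", elety = "CA",
                     x = 0, y = 0, z = 0, o = 1, het = FALSE,
                     elesy = NULL) {
  if (is.null(elesy)) elesy <- substr(gsub("[0-9]", "", elety), 1, 1)
  data.frame(chain = chain, resno = resno, insert = "", resid = resid,
             elety = elety, elesy = elesy, x = x, y = y, z = z, o = o,
             het = het, std_aa = resid %in% standard_aa() & !het,
             stringsAsFactors = FALSE)
}

# Two single-atom "chains" separated by `d` along x.
two_sphere_model <- function(d = 3.0) {
  model_from_atoms(rbind(
    atom_row(chain = "A", x = 0),
    atom_row(chain = "B", resno = 1L, x = d)), id = "two_sphere")
}

# A LYS...GLU pair across two chains with NZ-OE1 at distance `d`.
bridge_pair_model <- function(d) {
  lys <- build_residue("LYS", chain_id = "A")
  lys <- idrg:::.orient_residue(lys, "NZ", c(0, 0, 0), "CE", c(-1, 0, 0))
  glu <- build_residue("GLU", chain_id = "B")
  glu <- idrg:::.orient_residue(glu, "OE1", c(d, 0, 0), "CD", c(1, 0, 0))
  model_from_atoms(rbind(lys, glu), id = sprintf("bridge_%g", d))
}

# Random rigid transformation ------------------------------------------------

random_rigid_transform <- function(coords, seed) {
  set.seed(seed)
  ax <- stats::rnorm(3)
  R <- idrg:::.rotation_matrix(ax, stats::runif(1, 0, 2 * pi))
  shift <- stats::rnorm(3, sd = 50)
  sweep(coords %*% t(R), 2, shift, `+`)
}

transform_model <- function(model, seed) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- random_rigid_transform(xyz, seed)
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}

# Independent oracles --------------------------------------------------------

# AUC by exhaustive pair counting (ties half credit).
pair_count_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Spherical-cap buried area for two equal spheres of effective radius R at
# centre distance d: each loses 2*pi*R*h with h = R - d/2.
cap_buried_area <- function(R, d) 2 * pi * R * (R - d / 2)

# Total SASA of a model computed by biotite (same per-atom radii), for
# cross-implementation checks.
biotite_total_sasa <- function(model, probe = 1.4, n_points = 960) {
  pdbf <- tempfile(fileext = ".pdb")
  write_structure(model, pdbf)
  radf <- tempfile(fileext = ".txt")
  writeLines(as.character(vdw_radii()[model$atoms$elesy]), radf)
  py <- c(
    "import numpy as np",
    "import biotite.structure.io.pdb as pdb",
    "import biotite.structure as struc",
    sprintf("arr = pdb.PDBFile.read(%s).get_structure(model=1)",
            deparse(pdbf)),
    sprintf("radii = np.loadtxt(%s)", deparse(radf)),
    sprintf(
      "a = struc.sasa(arr, probe_radius=%g, point_number=%d, vdw_radii=radii)",
      probe, n_points),
    "print(repr(float(np.nansum(a))))")
  pyf <- tempfile(fileext = ".py")
  writeLines(py, pyf)
  out <- suppressWarnings(system2("python", pyf, stdout = TRUE, stderr = TRUE))
  val <- suppressWarnings(as.numeric(out[length(out)]))
  if (is.na(val)) stop("biotite oracle failed: ", paste(out, collapse = "\n"))
  val
}

# Per-residue central SASA of Gly-X-Gly tripeptides by biotite.
biotite_gxg <- function(probe = 1.4, n_points = 960) {
  vapply(standard_aa(), function(res) {
    at <- build_peptide(c("GLY", res, "GLY"))
    m <- model_from_atoms(at, id = res)
    pdbf <- tempfile(fileext = ".pdb")
    write_structure(m, pdbf)
    radf <- tempfile(fileext = ".txt")
    writeLines(as.character(vdw_radii()[m$atoms$elesy]), radf)
    py <- c(
      "import numpy as np",
      "import biotite.structure.io.pdb as pdb",
      "import biotite.structure as struc",
      sprintf("arr = pdb.PDBFile.read(%s).get_structure(model=1)",
              deparse(pdbf)),
      sprintf("radii = np.loadtxt(%s)", deparse(radf)),
      sprintf(
        "a = struc.sasa(arr, probe_radius=%g, point_number=%d, vdw_radii=radii)",
        probe, n_points),
      "print(repr(float(np.nansum(a[arr.res_id == 2]))))")
    pyf <- tempfile(fileext = ".py")
    writeLines(py, pyf)
    out <- suppressWarnings(system2("python", pyf, stdout = TRUE, stderr = TRUE))
    val <- suppressWarnings(as.numeric(out[length(out)]))
    if (is.na(val)) stop("biotite oracle failed: ", paste(out, collapse = "\n"))
    val
  }, numeric(1))
}

# Write a small PDB file directly (hand-formatted records), for parser tests
# that must not go through write_structure().
write_raw_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, alt = " ", element = NULL,
                          record = "ATOM  ") {
  if (is.null(element)) element <- substr(gsub("[0-9]", "", name), 1, 1)
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %-4s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, alt, resname, chain, resno, x, y, z, occ, 0,
          element)
}
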