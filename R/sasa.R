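# Solvent-accessible surface area by the Shrake-Rupley method: each atom is
# inflated by the probe radius and sampled with a deterministic
# Fibonacci-spiral point set; points falling inside any neighbouring
# inflated sphere are inaccessible.  Hydrogens are ignored (crystal
# structures rarely resolve them); radii come from an element-keyed table
# with CHARMM22 values for the Zn/Ca/Na ions.

# Candidate neighbour pairs within `cutoff` using a cell grid; returns a
# 2-column index matrix (i < j).  Falls back to all pairs for tiny sets.
.neighbor_pairs <- function(coords, cutoff) {
  n <- nrow(coords)
  if (n < 2L) return(matrix(integer(0), ncol = 2))
  if (n <= 64L) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    d2 <- rowSums((coords[idx[, 1], , drop = FALSE] -
                   coords[idx[, 2], , drop = FALSE])^2)
    return(idx[d2 <= cutoff^2, , drop = FALSE])
  }
  cell <- pmax(cutoff, 1e-6)
  key <- floor(sweep(coords, 2, apply(coords, 2, min)) / cell)
  kid <- paste(key[, 1], key[, 2], key[, 3], sep = ",")
  cells <- split(seq_len(n), kid)
  ckey <- do.call(rbind, strsplit(names(cells), ","))
  ckey <- matrix(as.integer(ckey), ncol = 3)
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (k in seq_along(cells)) assign(names(cells)[k], cells[[k]], envir = lookup)
  out <- vector("list", length(cells) * 14L)
  m <- 0L
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[14:27, , drop = FALSE]  # self + forward half of the 27 cells
  for (k in seq_along(cells)) {
    a <- cells[[k]]
    for (r in seq_len(nrow(offs))) {
      nb <- paste(ckey[k, 1] + offs$dx[r], ckey[k, 2] + offs$dy[r],
                  ckey[k, 3] + offs$dz[r], sep = ",")
      b <- if (exists(nb, envir = lookup, inherits = FALSE))
        get(nb, envir = lookup) else NULL
      if (is.null(b)) next
      if (offs$dx[r] == 0 && offs$dy[r] == 0 && offs$dz[r] == 0) {
        if (length(a) < 2L) next
        pr <- t(utils::combn(a, 2L))
      } else {
        pr <- cbind(rep(a, each = length(b)), rep(b, times = length(a)))
      }
      m <- m + 1L
      out[[m]] <- pr
    }
  }
  pr <- do.call(rbind, out[seq_len(m)])
  if (is.null(pr) || nrow(pr) == 0L) return(matrix(integer(0), ncol = 2))
  d2 <- rowSums((coords[pr[, 1], , drop = FALSE] -
                 coords[pr[, 2], , drop = FALSE])^2)
  pr <- pr[d2 <= cutoff^2, , drop = FALSE]
  # orient i < j
  flip <- pr[, 1] > pr[, 2]
  pr[flip, ] <- pr[flip, 2:1]
  pr[!duplicated(pr), , drop = FALSE]
}

# Atom selection for a SASA run.
.sasa_atoms <- function(atoms, include_hetero = FALSE, include_ions = TRUE) {
  h <- atoms$elesy %in% c("H", "D")
  ion <- atoms$het & atoms$resid %in% c("ZN", "CA", "NA", "MG", "K", "CL",
                                        "FE", "MN", "CU")
  keep <- !h & (atoms$std_aa | (include_ions & ion) |
                  (include_hetero & atoms$het & !ion))
  atoms[keep, , drop = FALSE]
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' @param x A `structure_model` or an atom data frame (see
#'   [model_from_atoms()]).
#' @param probe Probe radius in Angstrom (water: 1.4).
#' @param n_points Sphere sample points per atom (deterministic Fibonacci
#'   lattice); accuracy improves roughly as 1/n_points.
#' @param radii Named radii table from [vdw_radii()] (element-keyed,
#'   Angstrom).
#' @param include_hetero Include non-ion HETATM ligand atoms.
#' @param include_ions Include bound metal ions (Zn, Ca, Na, ...).
#' @param default_radius Radius for elements absent from `radii`; `NULL`
#'   (default) raises an error naming the offending atoms.
#' @return A `sasa_result`: list with `atoms` (the atoms used, with an
#'   `area` column in Angstrom^2), `residue` (per-residue sums for standard
#'   residues), `total`, `probe`, `n_points`.
#' @export
shrake_rupley <- function(x, probe = 1.4, n_points = 960L,
                          radii = vdw_radii(), include_hetero = FALSE,
                          include_ions = TRUE, default_radius = NULL) {
  atoms <- if (inherits(x, "structure_model")) x$atoms else x
  stopifnot(probe >= 0, n_points >= 60L)
  atoms <- .sasa_atoms(atoms, include_hetero, include_ions)
  if (nrow(atoms) == 0L) stop("no atoms selected for SASA")
  r <- unname(radii[atoms$elesy])
  if (anyNA(r)) {
    if (is.null(default_radius))
      stop("no van der Waals radius for atom(s): ",
           paste(unique(paste0(atoms$resid[is.na(r)], "/",
                               atoms$elety[is.na(r)])), collapse = ", "))
    r[is.na(r)] <- default_radius
  }
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  rr <- r + probe
  n <- nrow(coords)
  sphere <- fibonacci_sphere(n_points)

  maxcut <- 2 * max(rr)
  pr <- .neighbor_pairs(coords, maxcut)
  # prune to actually-overlapping inflated spheres
  if (nrow(pr) > 0L) {
    d2 <- rowSums((coords[pr[, 1], , drop = FALSE] -
                   coords[pr[, 2], , drop = FALSE])^2)
    keep <- d2 < (rr[pr[, 1]] + rr[pr[, 2]])^2
    pr <- pr[keep, , drop = FALSE]
  }
  nb <- vector("list", n)
  if (nrow(pr) > 0L) {
    for (k in seq_len(nrow(pr))) {
      i <- pr[k, 1]; j <- pr[k, 2]
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }

  area <- numeric(n)
  four_pi <- 4 * pi
  for (i in seq_len(n)) {
    js <- nb[[i]]
    if (length(js) == 0L) {
      area[i] <- four_pi * rr[i]^2
      next
    }
    pts <- sphere * rr[i]
    pts <- sweep(pts, 2, coords[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in js) {
      if (!any(acc)) break
      d2 <- (pts[acc, 1] - coords[j, 1])^2 + (pts[acc, 2] - coords[j, 2])^2 +
        (pts[acc, 3] - coords[j, 3])^2
      acc[acc] <- d2 >= rr[j]^2
    }
    area[i] <- four_pi * rr[i]^2 * sum(acc) / n_points
  }

  atoms$area <- area
  std <- atoms[atoms$std_aa, , drop = FALSE]
  key <- paste(std$chain, std$resno, std$insert, sep = "|")
  agg <- rowsum(std$area, key, reorder = FALSE)
  first <- !duplicated(key)
  residue <- data.frame(chain = std$chain[first], resno = std$resno[first],
                        insert = std$insert[first], resid = std$resid[first],
                        area = agg[, 1], stringsAsFactors = FALSE,
                        row.names = NULL)
  structure(list(atoms = atoms, residue = residue, total = sum(area),
                 probe = probe, n_points = as.integer(n_points)),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat("sasa_result: ", nrow(x$atoms), " atoms, total SASA ",
      sprintf("%.1f", x$total), " A^2 (probe ", x$probe, " A, ",
      x$n_points, " points)\n", sep = "")
  invisible(x)
}

.gxg_cache <- new.env(parent = emptyenv())

#' Gly-X-Gly reference surface areas
#'
#' SASA of residue X in an extended (phi = psi = 180 degrees) Gly-X-Gly
#' tripeptide, for each of the 20 standard residue types.  Used to
#' normalise per-residue SASA into relative SASA (rSASA).
#'
#' @inheritParams shrake_rupley
#' @return Named numeric vector (Angstrom^2) over the 20 residue types.
#' @export
reference_gxg <- function(probe = 1.4, n_points = 960L, radii = vdw_radii()) {
  key <- paste0("p", probe, "_n", n_points, "_", digest_radii(radii))
  if (!is.null(.gxg_cache[[key]])) return(.gxg_cache[[key]])
  out <- vapply(standard_aa(), function(res) {
    at <- build_peptide(c("GLY", res, "GLY"))
    s <- shrake_rupley(model_from_atoms(at, id = paste0("GX", res)),
                       probe = probe, n_points = n_points, radii = radii)
    s$residue$area[s$residue$resno == 2L]
  }, numeric(1))
  .gxg_cache[[key]] <- out
  out
}

# Stable short key for a radii table (cache invalidation only).
digest_radii <- function(radii) {
  paste0("r", format(sum(radii * seq_along(radii)), digits = 10))
}
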