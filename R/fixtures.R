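# Synthetic structure generators.  These emulate the geometric classes the
# classifier separates -- extended chains, ideal helices, random coils,
# collapsed globules -- plus designed toy complexes with known interface
# geometry, so every analysis in the package is testable without any
# external structure files.  Fixtures are geometric, not energy-minimised.

# Backbone decoration of a CA trace: N, C, O placed in a local frame around
# each CA (tangent along the chain, fixed normal offsets).  Good enough for
# SASA and contact geometry on fixtures.
.complete_backbone <- function(ca, chain_id, resid, resno_start = 1L) {
  n <- nrow(ca)
  rows <- vector("list", n * 4L)
  m <- 0L
  for (i in seq_len(n)) {
    t_ <- if (i < n) ca[i + 1L, ] - ca[i, ] else ca[i, ] - ca[i - 1L, ]
    nt <- sqrt(sum(t_^2))
    t_ <- if (nt > 1e-9) t_ / nt else c(1, 0, 0)
    ref <- if (abs(t_[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
    u <- .cross3(t_, ref)
    u <- u / sqrt(sum(u^2))
    w <- .cross3(t_, u)
    atoms <- list(
      N = ca[i, ] - 1.20 * t_ + 0.80 * u,
      CA = ca[i, ],
      C = ca[i, ] + 1.25 * t_ + 0.80 * u,
      O = ca[i, ] + 1.25 * t_ + 0.80 * u + 1.23 * w)
    for (nm in names(atoms)) {
      m <- m + 1L
      rows[[m]] <- data.frame(
        chain = chain_id, resno = resno_start + i - 1L, insert = "",
        resid = resid[i], elety = nm, elesy = substr(nm, 1L, 1L),
        x = atoms[[nm]][1], y = atoms[[nm]][2], z = atoms[[nm]][3],
        o = 1, het = FALSE, std_aa = TRUE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic protein chain
#'
#' CA-trace generators for the geometric classes relevant to the Rg/N
#' classifier:
#' \describe{
#'   \item{extended}{collinear CA trace at spacing `d` (closed-form
#'     Rg = `d * sqrt((N^2 - 1)/12)`); statistic about 1.1 Angstrom at
#'     d = 3.8, far above threshold.}
#'   \item{helix}{ideal alpha-helix CA geometry (rise 1.5 Angstrom/residue,
#'     radius 2.3 Angstrom, 100 degrees/residue); long helices classify ID,
#'     the geometric reason coiled coils must be excluded from negative
#'     sets.}
#'   \item{random_walk}{fixed-step (`d`) walk with optional direction
#'     persistence; Flory exponent 0.5.}
#'   \item{globule}{random points rescaled so Rg is exactly
#'     `R0 * N^nu_target`; the collapsed-chain class (defaults R0 = 2.2,
#'     nu = 0.35).}
#' }
#'
#' @param kind One of `"extended"`, `"helix"`, `"random_walk"`, `"globule"`.
#' @param n Number of residues (>= 1).
#' @param seed Integer seed for the stochastic kinds; recorded in the PDB
#'   header when the model is written with [write_structure()].
#' @param d CA-CA spacing in Angstrom (extended, random_walk).
#' @param helix_rise,helix_radius,helix_twist Helix geometry (Angstrom,
#'   Angstrom, degrees per residue).
#' @param R0,nu_target Globule scaling targets.
#' @param persistence Direction persistence in \[0, 1) for random walks.
#' @param chain_id Chain identifier.
#' @param backbone Decorate the CA trace with N/C/O backbone atoms.
#' @param residue Residue type used for every position.
#' @return A `structure_model`; attribute `target_rg` holds the exact
#'   generator target for the deterministic kinds, attribute `seed` the
#'   seed used.
#' @export
make_chain <- function(kind = c("extended", "helix", "random_walk", "globule"),
                       n, seed = 1L, d = 3.8, helix_rise = 1.5,
                       helix_radius = 2.3, helix_twist = 100,
                       R0 = 2.2, nu_target = 0.35, persistence = 0,
                       chain_id = "A", backbone = TRUE, residue = "GLY") {
  kind <- match.arg(kind)
  stopifnot(n >= 1, d > 0)
  target_rg <- NA_real_
  if (kind == "extended") {
    ca <- cbind(d * (seq_len(n) - 1), 0, 0)
    target_rg <- d * sqrt((n^2 - 1) / 12)
  } else if (kind == "helix") {
    th <- (seq_len(n) - 1) * helix_twist * pi / 180
    ca <- cbind(helix_radius * cos(th), helix_radius * sin(th),
                helix_rise * (seq_len(n) - 1))
  } else if (kind == "random_walk") {
    stopifnot(persistence >= 0, persistence < 1)
    set.seed(seed)
    ca <- matrix(0, n, 3)
    dir <- c(1, 0, 0)
    for (i in seq_len(n - 1L)) {
      r <- stats::rnorm(3)
      r <- r / sqrt(sum(r^2))
      dir <- persistence * dir + (1 - persistence) * r
      dir <- dir / sqrt(sum(dir^2))
      ca[i + 1L, ] <- ca[i, ] + d * dir
    }
  } else { # globule
    set.seed(seed)
    if (n == 1L) {
      ca <- matrix(0, 1, 3)
      target_rg <- 0
    } else {
      pts <- matrix(numeric(0), 0, 3)
      while (nrow(pts) < n) {
        cand <- matrix(stats::runif(6 * n, -1, 1), ncol = 3)
        pts <- rbind(pts, cand[rowSums(cand^2) <= 1, , drop = FALSE])
      }
      pts <- pts[seq_len(n), , drop = FALSE]
      target_rg <- R0 * n^nu_target
      rg0 <- radius_of_gyration(pts)
      pts <- sweep(pts, 2, colMeans(pts))
      ca <- pts * (target_rg / rg0)
    }
  }
  resid <- rep(toupper(residue), n)
  atoms <- if (backbone) .complete_backbone(ca, chain_id, resid)
  else data.frame(chain = chain_id, resno = seq_len(n), insert = "",
                  resid = resid, elety = "CA", elesy = "C",
                  x = ca[, 1], y = ca[, 2], z = ca[, 3], o = 1, het = FALSE,
                  std_aa = TRUE, stringsAsFactors = FALSE)
  mod <- model_from_atoms(atoms, id = paste0(kind, "_", n, "_s", seed))
  attr(mod, "target_rg") <- target_rg
  attr(mod, "seed") <- as.integer(seed)
  mod
}

#' Default toy-complex recipe
#'
#' A designed two-chain complex exercising the interface machinery:
#' a segment chain A carrying a lysine whose NZ forms a single salt bridge
#' (designed distance `bridge_dist`) with a glutamate on partner chain B,
#' a leucine buried inside a cage of partner alanines (interface core by
#' construction), and a gap-separated control residue pair more than 10
#' Angstrom from everything else (never interface).
#'
#' @param bridge_dist Designed NZ-OE1 distance in Angstrom.
#' @param cage_n Number of alanines in the burial cage.
#' @param cage_radius Cage radius in Angstrom.
#' @return A recipe list understood by [make_toy_complex()].
#' @export
toy_complex_recipe <- function(bridge_dist = 3.5, cage_n = 44L,
                               cage_radius = 6.2) {
  stopifnot(bridge_dist > 0, cage_n >= 4L, cage_radius > 4)
  list(bridge_dist = bridge_dist, cage_n = as.integer(cage_n),
       cage_radius = cage_radius,
       burial_center = c(0, 0, 25), control_a = c(55, 0, 0),
       control_b = c(75, 0, 0))
}

#' Build a designed toy complex
#'
#' Assembles idealised residues (see [build_residue()]) into the two-chain
#' complex described by a [toy_complex_recipe()].
#'
#' @param seed Seed recorded on the model (construction is deterministic).
#' @param recipe Recipe list.
#' @return A `structure_model` with chains A (segment) and B (partner).
#' @export
make_toy_complex <- function(seed = 1L, recipe = toy_complex_recipe()) {
  if (recipe$bridge_dist > 25)
    stop("unsatisfiable recipe: bridge distance places residues outside the design cell")
  rows <- list()
  # chain A: LYS (salt-bridge donor), buried LEU, far control GLY
  lys <- build_residue("LYS", chain_id = "A", resno_start = 1L)
  lys <- .orient_residue(lys, "NZ", c(0, 0, 0), "CE", c(-1, 0.2, 0))
  leu <- build_residue("LEU", chain_id = "A", resno_start = 2L)
  leu <- .orient_residue(leu, "CG", recipe$burial_center)
  ctl_a <- build_residue("GLY", chain_id = "A", resno_start = 3L)
  ctl_a <- .orient_residue(ctl_a, "CA", recipe$control_a)
  # chain B: GLU opposite the LYS, alanine cage, far control GLY
  glu <- build_residue("GLU", chain_id = "B", resno_start = 1L)
  glu <- .orient_residue(glu, "OE1", c(recipe$bridge_dist, 0, 0),
                         "CD", c(1, 0, 0))
  cage_dirs <- fibonacci_sphere(recipe$cage_n)
  cage <- lapply(seq_len(recipe$cage_n), function(k) {
    ala <- build_residue("ALA", chain_id = "B", resno_start = 1L + k)
    pt <- recipe$burial_center + cage_dirs[k, ] * recipe$cage_radius
    .orient_residue(ala, "CB", pt, "CA", cage_dirs[k, ])
  })
  ctl_b <- build_residue("GLY", chain_id = "B",
                         resno_start = recipe$cage_n + 2L)
  ctl_b <- .orient_residue(ctl_b, "CA", recipe$control_b)

  atoms <- do.call(rbind, c(list(lys, leu, ctl_a, glu), cage, list(ctl_b)))
  mod <- model_from_atoms(atoms, id = sprintf("toy_complex_s%d", seed))
  attr(mod, "seed") <- as.integer(seed)
  mod
}

#' Generate the synthetic classifier benchmark
#'
#' Emulates the study conditions of the classifier evaluation: a positive
#' set of bound-ID-like segments (persistent random coils, Flory exponent
#' 0.5 with prefactor near 2.5 Angstrom, lengths 20-150) and a negative set
#' of globular chains (Rg = R0 * N^0.35 with 8% lognormal scatter, lengths
#' 20-500), with the published set sizes (52 positives, 762 negatives) as
#' defaults.
#'
#' @param seed Integer seed.
#' @param n_pos,n_neg Class sizes.
#' @param len_pos,len_neg Length ranges (inclusive).
#' @return Data frame: `class` ("ID"/"structured"), `n`, `rg`, `statistic`
#'   (Rg/N at nu = 1).
#' @export
make_benchmark <- function(seed = 1L, n_pos = 52L, n_neg = 762L,
                           len_pos = c(20L, 150L), len_neg = c(20L, 500L)) {
  set.seed(seed)
  lp <- sample(seq(len_pos[1], len_pos[2]), n_pos, replace = TRUE)
  ln <- sample(seq(len_neg[1], len_neg[2]), n_neg, replace = TRUE)
  seeds <- sample.int(1e6, n_pos + n_neg)
  rg_pos <- vapply(seq_len(n_pos), function(k) {
    m <- make_chain("random_walk", n = lp[k], seed = seeds[k],
                    persistence = 0.5, backbone = FALSE)
    radius_of_gyration(ca_coords(m, "A"))
  }, numeric(1))
  noise <- exp(stats::rnorm(n_neg, 0, 0.08))
  rg_neg <- vapply(seq_len(n_neg), function(k) {
    m <- make_chain("globule", n = ln[k], seed = seeds[n_pos + k],
                    R0 = 2.2 * noise[k], nu_target = 0.35, backbone = FALSE)
    radius_of_gyration(ca_coords(m, "A"))
  }, numeric(1))
  data.frame(
    class = rep(c("ID", "structured"), c(n_pos, n_neg)),
    n = c(lp, ln), rg = c(rg_pos, rg_neg),
    statistic = c(rg_pos / lp, rg_neg / ln),
    stringsAsFactors = FALSE)
}
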