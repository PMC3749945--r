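# Interface definition and core/rim classification.  The interface is the
# set of residues whose SASA drops upon binding (delta-SASA > eps); each
# interface residue is then placed in the Levy scheme using relative SASA
# (residue SASA normalised by its Gly-X-Gly reference): still exposed when
# bound -> rim; buried by binding -> core; buried already when free ->
# support.

#' Map the interface of a complex
#'
#' Runs three SASA calculations with a shared configuration (the complex,
#' the segment side alone, and the partner side alone), computes per-residue
#' delta-SASA = SASA_free - SASA_bound, assigns interface membership
#' (delta-SASA > `eps`) and the core/rim/support region labels, and
#' summarises the interface area as half the total buried area
#' (the average of the two sides).
#'
#' @param partition A [partition_complex()] result.
#' @param probe,n_points,radii,include_hetero,include_ions Passed to
#'   [shrake_rupley()]; one configuration is shared by all three runs.
#' @param eps Minimum delta-SASA (Angstrom^2) for interface membership;
#'   suppresses point-sampling noise.
#' @return An `interface_map`: list with `residues` (per-residue data frame:
#'   `side`, `chain`, `resno`, `insert`, `resid`, `dsasa`, `rsasa_bound`,
#'   `rsasa_free`, `region`) and `summary` (interface area, per-side region
#'   counts and compositions).
#' @export
interface_map <- function(partition, probe = 1.4, n_points = 960L,
                          radii = vdw_radii(), eps = 0.1,
                          include_hetero = FALSE, include_ions = TRUE) {
  stopifnot(inherits(partition, "complex_partition"))
  model <- partition$model
  at <- model$atoms
  seg_atoms <- at[at$chain == partition$segment, , drop = FALSE]
  par_atoms <- at[at$chain %in% partition$partner, , drop = FALSE]
  if (nrow(par_atoms) == 0L) stop("partner group is empty")
  args <- list(probe = probe, n_points = n_points, radii = radii,
               include_hetero = include_hetero, include_ions = include_ions)

  s_complex <- do.call(shrake_rupley, c(list(rbind(seg_atoms, par_atoms)), args))
  s_seg <- do.call(shrake_rupley, c(list(seg_atoms), args))
  s_par <- do.call(shrake_rupley, c(list(par_atoms), args))

  ref <- reference_gxg(probe = probe, n_points = n_points, radii = radii)

  one_side <- function(free, side) {
    fr <- free$residue
    key_f <- paste(fr$chain, fr$resno, fr$insert, sep = "|")
    br <- s_complex$residue
    key_b <- paste(br$chain, br$resno, br$insert, sep = "|")
    bound_area <- br$area[match(key_f, key_b)]
    bound_area[is.na(bound_area)] <- 0
    dsasa <- fr$area - bound_area
    refv <- unname(ref[fr$resid])
    data.frame(side = side, chain = fr$chain, resno = fr$resno,
               insert = fr$insert, resid = fr$resid, dsasa = dsasa,
               rsasa_bound = bound_area / refv, rsasa_free = fr$area / refv,
               stringsAsFactors = FALSE)
  }
  res <- rbind(one_side(s_seg, "segment"), one_side(s_par, "partner"))

  region <- rep("none", nrow(res))
  intf <- res$dsasa > eps
  region[intf & res$rsasa_bound > 0.25] <- "rim"
  region[intf & res$rsasa_bound <= 0.25 & res$rsasa_free > 0.25] <- "core"
  region[intf & res$rsasa_bound <= 0.25 & res$rsasa_free <= 0.25] <- "support"
  res$region <- region

  interface_area <- sum(res$dsasa) / 2

  counts <- table(factor(res$side, c("segment", "partner")),
                  factor(res$region, c("core", "rim", "support", "none")))
  comp <- lapply(c("segment", "partner"), function(s) {
    lapply(c("core", "rim"), function(rg) {
      sel <- res$side == s & res$region == rg
      if (!any(sel)) return(NULL)
      composition_profile(res$resid[sel])
    })
  })
  names(comp) <- c("segment", "partner")
  for (s in names(comp)) names(comp[[s]]) <- c("core", "rim")

  structure(list(residues = res,
                 summary = list(interface_area = interface_area,
                                region_counts = counts,
                                composition = comp,
                                probe = probe, n_points = n_points,
                                eps = eps)),
            class = "interface_map")
}

#' @export
print.interface_map <- function(x, ...) {
  s <- x$summary
  cat("interface_map: area ", sprintf("%.1f", s$interface_area),
      " A^2 (half-sum of two sides)\n", sep = "")
  print(s$region_counts)
  invisible(x)
}

#' Amino-acid composition of a residue set
#'
#' Fractions of each of the 20 standard residue types, ordered by the
#' flexibility ranking used for composition displays (rigid, order-promoting
#' types first).
#'
#' @param res_names Character vector of three-letter residue names.
#' @return Named numeric vector of fractions summing to 1.
#' @export
composition_profile <- function(res_names) {
  res_names <- toupper(res_names)
  res_names <- res_names[res_names %in% standard_aa()]
  if (length(res_names) == 0L)
    stop("composition_profile: empty residue set")
  tab <- table(factor(res_names, levels = flexibility_order()))
  as.numeric(tab) / length(res_names) -> fr
  names(fr) <- flexibility_order()
  fr
}

#' Mean per-complex composition
#'
#' Averages the composition profiles of several complexes (each complex
#' contributes equally regardless of its size), the convention used for
#' dataset-level composition comparisons.
#'
#' @param sets List of residue-name character vectors, one per complex.
#' @return Named numeric vector of mean fractions (flexibility order).
#' @export
average_composition <- function(sets) {
  if (length(sets) == 0L) stop("average_composition: no complexes")
  profs <- vapply(sets, composition_profile,
                  numeric(length(flexibility_order())))
  rowMeans(profs)
}

#' Composition enrichment of one profile over another
#'
#' Per-type difference `profile_a - profile_b`; positive values mean the
#' residue type is enriched in the first set.
#'
#' @param profile_a,profile_b Profiles from [composition_profile()] or
#'   [average_composition()].
#' @return Named numeric vector of differences (flexibility order).
#' @export
composition_enrichment <- function(profile_a, profile_b) {
  ord <- flexibility_order()
  stopifnot(all(ord %in% names(profile_a)), all(ord %in% names(profile_b)))
  profile_a[ord] - profile_b[ord]
}
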