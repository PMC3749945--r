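# Radius of gyration, the Rg/N^nu extendedness statistic, the ID /
# structured decision, and Flory scaling-law fits.
#
# The statistic exploits the geometry of intrinsically disordered segments
# captured in complexes: bound ID segments are extended (large Rg for their
# length), while globular chains are compact, so Rg/N^nu with nu = 1
# separates the two classes at a threshold of 0.26 Angstrom.

#' Radius of gyration of a point set
#'
#' Root-mean-square (optionally mass-weighted) distance of the points from
#' their (weighted) centroid:
#' `Rg = sqrt( sum w_i |r_i - r_com|^2 / sum w_i )`.
#' For chain classification it is applied to alpha-carbon coordinates with
#' equal weights.
#'
#' @param coords Numeric matrix (n x 3) of coordinates in Angstrom.
#' @param weights Optional positive per-point weights (e.g. atomic masses).
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(coords, weights = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1L) stop("radius_of_gyration: empty coordinate set")
  if (ncol(coords) != 3L) stop("coords must have 3 columns")
  if (is.null(weights)) weights <- rep(1, nrow(coords))
  if (length(weights) != nrow(coords) || any(weights <= 0))
    stop("weights must be positive and match the number of points")
  w <- weights / sum(weights)
  com <- colSums(coords * w)
  d2 <- rowSums(sweep(coords, 2, com)^2)
  sqrt(sum(w * d2))
}

#' Extendedness statistic Rg / N^nu
#'
#' @param rg Radius of gyration in Angstrom.
#' @param n Number of observed residues (N >= 1).
#' @param nu Scaling exponent; `nu = 1` gives the plain Rg/N classifier.
#' @return Statistic in Angstrom.
#' @export
rg_statistic <- function(rg, n, nu = 1) {
  if (any(n < 1)) stop("rg_statistic: N must be >= 1")
  rg / n^nu
}

#' Classifier configuration
#'
#' Defaults reproduce the published operating point: threshold 0.26 Angstrom
#' on Rg/N (nu = 1), segments of more than 20 observed residues, and at
#' least one partner chain of more than 70 residues.
#'
#' @param threshold Decision threshold in Angstrom (label ID iff
#'   statistic > threshold, strictly).
#' @param nu Scaling exponent of the statistic.
#' @param min_segment_len Minimum observed length of a classifiable segment.
#' @param min_partner_len Minimum length required of some partner chain.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(threshold = 0.26, nu = 1,
                              min_segment_len = 20L, min_partner_len = 70L) {
  stopifnot(threshold > 0, min_segment_len >= 1, min_partner_len >= 1)
  structure(list(threshold = threshold, nu = nu,
                 min_segment_len = as.integer(min_segment_len),
                 min_partner_len = as.integer(min_partner_len)),
            class = "classifier_config")
}

#' Classify a chain as ID or structured
#'
#' A chain is called intrinsically disordered when its extendedness
#' statistic strictly exceeds the threshold; exact equality is assigned to
#' `structured` (conservative).
#'
#' @param rg Radius of gyration in Angstrom.
#' @param n Observed residue count.
#' @param config A [classifier_config()].
#' @return `"ID"` or `"structured"`.
#' @export
classify_chain <- function(rg, n, config = classifier_config()) {
  stat <- rg_statistic(rg, n, config$nu)
  ifelse(stat > config$threshold, "ID", "structured")
}

#' Per-chain Rg record
#'
#' Computes Rg over the chain's alpha-carbons, the statistic and the label.
#'
#' @param model A `structure_model`.
#' @param chain Chain identifier.
#' @param config A [classifier_config()].
#' @return List with `chain`, `n`, `rg`, `nu`, `statistic`, `label`.
#' @export
chain_rg_record <- function(model, chain, config = classifier_config()) {
  xyz <- ca_coords(model, chain)
  if (nrow(xyz) < 1L) stop("chain '", chain, "' has no CA coordinates")
  rg <- radius_of_gyration(xyz)
  n <- nrow(xyz)
  list(chain = chain, n = n, rg = rg, nu = config$nu,
       statistic = rg_statistic(rg, n, config$nu),
       label = classify_chain(rg, n, config))
}

#' Per-chain classification report
#'
#' @param model A `structure_model`.
#' @param config A [classifier_config()].
#' @return Data frame with one row per polymer chain: `structure_id`,
#'   `chain`, `n`, `rg`, `statistic`, `label`.
#' @export
rg_report <- function(model, config = classifier_config()) {
  chains <- .polymer_chains(model)
  recs <- lapply(chains, function(ch) chain_rg_record(model, ch, config))
  data.frame(structure_id = model$id,
             chain = vapply(recs, `[[`, "", "chain"),
             n = vapply(recs, `[[`, 0L, "n"),
             rg = vapply(recs, `[[`, 0, "rg"),
             statistic = vapply(recs, `[[`, 0, "statistic"),
             label = vapply(recs, `[[`, "", "label"),
             stringsAsFactors = FALSE)
}

#' Fit the Flory scaling law Rg = R0 * N^nu
#'
#' Ordinary least squares of `log(Rg)` on `log(N)`: the slope estimates the
#' scaling exponent nu (about 0.33-0.35 for collapsed globules, 0.5 for
#' random coils, 1 for rods) and `exp(intercept)` the prefactor R0.
#'
#' @param rg Radii of gyration (> 0), Angstrom.
#' @param n Chain lengths (>= 1), at least two distinct values.
#' @return An object of class `flory_fit` with components `R0`, `nu`,
#'   `r_squared`, `n_points` and the underlying `lm` fit.
#' @export
fit_flory <- function(rg, n) {
  if (length(rg) != length(n)) stop("rg and n must have equal length")
  if (length(rg) < 2L || length(unique(n)) < 2L)
    stop("fit_flory: need >= 2 points with distinct N")
  if (any(rg <= 0) || any(n < 1)) stop("fit_flory: rg must be > 0 and n >= 1")
  fit <- stats::lm(log(rg) ~ log(n))
  cf <- stats::coef(fit)
  structure(list(R0 = exp(unname(cf[1])), nu = unname(cf[2]),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 n_points = length(rg), lm = fit),
            class = "flory_fit")
}

#' @export
print.flory_fit <- function(x, digits = 4, ...) {
  cat("Flory scaling fit: Rg = R0 * N^nu\n")
  cat("  R0  =", format(x$R0, digits = digits), "Angstrom\n")
  cat("  nu  =", format(x$nu, digits = digits), "\n")
  cat("  R^2 =", format(x$r_squared, digits = digits),
      " (", x$n_points, " chains )\n")
  invisible(x)
}

#' @export
coef.flory_fit <- function(object, ...) c(R0 = object$R0, nu = object$nu)

#' Predicted Rg at new chain lengths
#' @param object A `flory_fit`.
#' @param newdata Numeric vector of chain lengths N.
#' @param ... Unused.
#' @return Predicted Rg values in Angstrom.
#' @export
predict.flory_fit <- function(object, newdata, ...) {
  if (missing(newdata)) return(exp(stats::fitted(object$lm)))
  object$R0 * newdata^object$nu
}

#' @export
residuals.flory_fit <- function(object, ...) stats::residuals(object$lm)

#' @export
plot.flory_fit <- function(x, ...) {
  dat <- x$lm$model
  graphics::plot(dat[["log(n)"]], dat[["log(rg)"]],
                 xlab = "ln N", ylab = "ln Rg",
                 main = sprintf("Flory fit: nu = %.3f, R0 = %.2f A",
                                x$nu, x$R0), ...)
  graphics::abline(log(x$R0), x$nu, col = 2)
  invisible(x)
}
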