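# Batch orchestration: scan structure files, filter chains, classify each
# eligible chain against the union of the others, and characterise the
# interfaces of ID-labelled chains.

#' Run configuration for batch scanning
#'
#' @param classifier A [classifier_config()].
#' @param filters A [filter_config()].
#' @param probe,n_points SASA parameters shared by all interface runs.
#' @param sb_cutoff Salt-bridge distance cutoff, Angstrom.
#' @param hb_dmax,hb_angle Hydrogen-bond criteria.
#' @param eps Interface-membership delta-SASA tolerance, Angstrom^2.
#' @param external_exclusions Chains excluded by external analyses
#'   (`structure_id:chain` strings).
#' @param characterize Run interface/contact characterisation for
#'   ID-labelled chains.
#' @param seed Seed recorded with the outputs (the scan itself is
#'   deterministic).
#' @return A `run_config` list (serialisable with [jsonlite::toJSON()]).
#' @export
run_config <- function(classifier = classifier_config(),
                       filters = filter_config(),
                       probe = 1.4, n_points = 960L, sb_cutoff = 4.0,
                       hb_dmax = 3.9, hb_angle = 90, eps = 0.1,
                       external_exclusions = character(0),
                       characterize = TRUE, seed = 1L) {
  structure(list(classifier = classifier, filters = filters, probe = probe,
                 n_points = as.integer(n_points), sb_cutoff = sb_cutoff,
                 hb_dmax = hb_dmax, hb_angle = hb_angle, eps = eps,
                 external_exclusions = external_exclusions,
                 characterize = isTRUE(characterize), seed = as.integer(seed)),
            class = "run_config")
}

#' Scan structure files for ID complexes
#'
#' For every readable structure: parse, apply the curation filters,
#' classify each passing chain (against the union of the other polymer
#' chains), and -- for chains labelled ID -- characterise the interface and
#' its contacts.  Unreadable files are skipped and reported.
#'
#' @param paths Character vector of structure files, or a single directory
#'   (scanned for `*.pdb` / `*.cif`).
#' @param config A [run_config()].
#' @return A `scan_result`: list with `reports` (per-structure lists),
#'   `summary` (dataset-level statistics), `skipped` (files that failed to
#'   parse) and `status` (0 ok, 2 partial: some files skipped).
#' @export
scan_structures <- function(paths, config = run_config()) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.(pdb|ent|cif)$",
                        full.names = TRUE)
  if (length(paths) == 0L) stop("no input structures")
  reports <- list()
  skipped <- character(0)
  for (p in sort(paths)) {
    model <- tryCatch(read_structure(p), error = function(e) {
      message("skipping ", p, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(model)) { skipped <- c(skipped, p); next }
    reports[[model$id]] <- .scan_one(model, config)
  }
  if (length(reports) == 0L) stop("no structure could be read")

  chain_tab <- do.call(rbind, lapply(reports, `[[`, "chains"))
  id_rows <- chain_tab[chain_tab$label == "ID" & chain_tab$pass, , drop = FALSE]
  areas <- unlist(lapply(reports, function(r)
    vapply(r$interfaces, function(x) x$summary$interface_area, numeric(1))))
  sbs <- unlist(lapply(reports, function(r)
    vapply(r$contacts, function(x) x$n_salt_bridges, numeric(1))))
  hbs <- unlist(lapply(reports, function(r)
    vapply(r$contacts, function(x) x$n_hbonds, numeric(1))))
  summary <- list(
    n_structures = length(reports),
    n_chains = nrow(chain_tab),
    n_pass = sum(chain_tab$pass),
    n_id = nrow(id_rows),
    n_structured = sum(chain_tab$label == "structured" & chain_tab$pass),
    mean_interface_area = if (length(areas)) mean(areas) else NA_real_,
    mean_salt_bridges = if (length(sbs)) mean(sbs) else NA_real_,
    mean_hbonds = if (length(hbs)) mean(hbs) else NA_real_)
  structure(list(reports = reports, chain_table = chain_tab,
                 summary = summary, skipped = skipped,
                 status = if (length(skipped)) 2L else 0L,
                 config = config),
            class = "scan_result")
}

.scan_one <- function(model, config) {
  fr <- apply_structure_filters(model, config$filters,
                                config$external_exclusions)
  rg <- rg_report(model, config$classifier)
  chains <- merge(rg, fr, by = "chain", sort = FALSE)
  interfaces <- list()
  contacts <- list()
  if (config$characterize) {
    idc <- chains$chain[chains$label == "ID" & chains$pass]
    for (ch in idc) {
      part <- tryCatch(partition_complex(model, ch), error = function(e) NULL)
      if (is.null(part)) next
      im <- interface_map(part, probe = config$probe,
                          n_points = config$n_points, eps = config$eps)
      sb <- find_salt_bridges(part, cutoff = config$sb_cutoff)
      hb <- find_hbonds(part, d_max = config$hb_dmax,
                        angle_min = config$hb_angle)
      interfaces[[ch]] <- im
      contacts[[ch]] <- summarize_contacts(sb, hb,
                                           im$summary$interface_area)
    }
  }
  list(structure_id = model$id, chains = chains, interfaces = interfaces,
       contacts = contacts)
}

#' @export
print.scan_result <- function(x, ...) {
  s <- x$summary
  cat("scan_result: ", s$n_structures, " structures, ", s$n_chains,
      " chains (", s$n_pass, " pass filters)\n", sep = "")
  cat("  ID: ", s$n_id, "   structured: ", s$n_structured, "\n", sep = "")
  if (!is.na(s$mean_interface_area))
    cat(sprintf("  mean interface area %.1f A^2, %.2f salt bridges, %.2f H-bonds\n",
                s$mean_interface_area, s$mean_salt_bridges, s$mean_hbonds))
  if (length(x$skipped))
    cat("  skipped:", paste(basename(x$skipped), collapse = ", "), "\n")
  invisible(x)
}

#' Write scan reports to a directory
#'
#' Emits `chains.tsv` (per-chain classification and filter outcome),
#' `summary.json` (dataset-level statistics plus the configuration), and a
#' per-complex `interfaces.tsv` of interface residues.
#'
#' @param scan A `scan_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scan_reports <- function(scan, dir) {
  stopifnot(inherits(scan, "scan_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(scan$chain_table, file.path(dir, "chains.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ir <- do.call(rbind, unlist(lapply(scan$reports, function(r)
    lapply(names(r$interfaces), function(ch) {
      df <- r$interfaces[[ch]]$residues
      df$structure_id <- r$structure_id
      df$segment <- ch
      df
    })), recursive = FALSE))
  if (!is.null(ir))
    utils::write.table(ir, file.path(dir, "interfaces.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  js <- list(summary = scan$summary, skipped = scan$skipped,
             status = scan$status, config = unclass(scan$config))
  js$config$classifier <- unclass(js$config$classifier)
  js$config$filters <- unclass(js$config$filters)
  jsonlite::write_json(js, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
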