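# Dataset-curation filters: which chains are eligible for classification,
# and redundancy removal with a Rost-curve identity threshold.

#' Filter configuration
#'
#' Defaults reproduce the published curation: segments need more than 20
#' observed residues, some partner chain more than 70; chains shorter than
#' 100 residues with two or more disulfide bonds are excluded
#' (disulfide-rich domains are expanded yet folded); redundancy uses the
#' Rost curve at n = 3.
#'
#' @param min_segment_len,min_partner_len Length gates (strict `>`).
#' @param disulfide_len_cutoff,disulfide_min_bonds Disulfide-rich rule.
#' @param rost_n Offset of the Rost identity curve, percentage points.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_segment_len = 20L, min_partner_len = 70L,
                          disulfide_len_cutoff = 100L,
                          disulfide_min_bonds = 2L, rost_n = 3) {
  stopifnot(min_segment_len > 0, min_partner_len > 0,
            disulfide_len_cutoff > 0, disulfide_min_bonds > 0, rost_n > 0)
  structure(list(min_segment_len = as.integer(min_segment_len),
                 min_partner_len = as.integer(min_partner_len),
                 disulfide_len_cutoff = as.integer(disulfide_len_cutoff),
                 disulfide_min_bonds = as.integer(disulfide_min_bonds),
                 rost_n = rost_n),
            class = "filter_config")
}

#' Apply curation filters to the chains of a structure
#'
#' A chain passes when (i) it has more than `min_segment_len` observed
#' residues, (ii) at least one other polymer chain has more than
#' `min_partner_len` residues, (iii) it is not a disulfide-rich short chain
#' (fewer than `disulfide_len_cutoff` residues with at least
#' `disulfide_min_bonds` disulfides), and (iv) it is not on the external
#' exclusion list (e.g. coiled-coil or transmembrane chains detected by
#' external tools, given as `structure_id:chain` strings or bare chain ids).
#'
#' @param model A `structure_model`.
#' @param config A [filter_config()].
#' @param external_exclusions Character vector of excluded chains.
#' @return Data frame (`filter_report`): `chain`, `n`, `n_disulfides`,
#'   `pass`, `failed_rules` (comma-separated rule names, empty if passed).
#' @export
apply_structure_filters <- function(model, config = filter_config(),
                                    external_exclusions = character(0)) {
  no <- n_observed(model)
  chains <- names(no)
  ss_n <- vapply(chains, function(ch)
    nrow(find_disulfides(model, chain = ch)), integer(1))
  rows <- lapply(chains, function(ch) {
    fails <- character(0)
    if (no[[ch]] <= config$min_segment_len) fails <- c(fails, "min_segment_len")
    partners <- setdiff(chains, ch)
    if (length(partners) == 0L || !any(no[partners] > config$min_partner_len))
      fails <- c(fails, "min_partner_len")
    if (no[[ch]] < config$disulfide_len_cutoff &&
        ss_n[[ch]] >= config$disulfide_min_bonds)
      fails <- c(fails, "disulfide_rich")
    if (ch %in% external_exclusions ||
        paste(model$id, ch, sep = ":") %in% external_exclusions)
      fails <- c(fails, "external_exclusion")
    data.frame(chain = ch, n = no[[ch]], n_disulfides = ss_n[[ch]],
               pass = length(fails) == 0L,
               failed_rules = paste(fails, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("filter_report", class(out))
  out
}

#' Rost sequence-identity threshold
#'
#' Length-dependent percent-identity threshold above which two aligned
#' sequences are considered homologous:
#' `n + 480 * L^(-0.32 * (1 + exp(-L/1000)))`, capped at 100.  Longer
#' alignments tolerate lower identity; the curve decays towards the offset
#' `n` for very long alignments.
#'
#' @param L Alignment length (>= 1).
#' @param n Offset in percentage points above the default curve.
#' @return Percent identity threshold in (n, 100].
#' @export
rost_threshold <- function(L, n = 3) {
  if (any(L < 1)) stop("rost_threshold: alignment length must be >= 1")
  pmin(100, n + 480 * L^(-0.32 * (1 + exp(-L / 1000))))
}

#' Pairwise global sequence identity
#'
#' Needleman-Wunsch global alignments (BLOSUM62, gap open 10, gap extend
#' 0.5, via Biostrings) for every sequence pair; identity is the percentage
#' of identical aligned positions over the alignment length.
#'
#' @param seqs Named character vector of one-letter sequences.
#' @return List with matrices `identity` (percent) and `length` (alignment
#'   length), both `n x n` and symmetric.
#' @export
pairwise_identity <- function(seqs) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("pairwise_identity requires the Biostrings package")
  n <- length(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  id <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  len <- matrix(0, n, n, dimnames = dimnames(id))
  diag(len) <- nchar(seqs)
  if (n < 2L) return(list(identity = id, length = len))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      aln <- Biostrings::pairwiseAlignment(
        seqs[[i]], seqs[[j]], type = "global",
        substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
      L <- Biostrings::nchar(Biostrings::alignedPattern(aln))
      id[i, j] <- id[j, i] <- Biostrings::pid(aln, type = "PID1")
      len[i, j] <- len[j, i] <- L
    }
  }
  list(identity = id, length = len)
}

#' Redundancy clustering with a Rost-curve threshold
#'
#' Two chains are redundant when their percent identity exceeds the Rost
#' threshold at their alignment length.  Connected components of the
#' redundancy graph are reduced to one representative each: the chain from
#' the highest-resolution structure, ties broken by longest chain, then
#' lexicographic identifier.
#'
#' @param identity Symmetric matrix of percent identities.
#' @param length Matrix of pairwise alignment lengths.
#' @param resolution Named numeric vector of structure resolutions
#'   (Angstrom; smaller is better).  Missing entries rank last.
#' @param chain_len Named integer vector of chain lengths.
#' @param n Rost offset (see [rost_threshold()]).
#' @return List with `representatives` (character vector), `component`
#'   (named integer component membership), `edges` (data frame of redundant
#'   pairs).
#' @export
redundancy_cluster <- function(identity, length, resolution = NULL,
                               chain_len = NULL, n = 3) {
  ids <- rownames(identity)
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(identity)))
  m <- nrow(identity)
  if (!isTRUE(all.equal(identity, t(identity), tolerance = 1e-8)))
    stop("identity matrix must be symmetric")
  if (is.null(resolution)) resolution <- stats::setNames(rep(NA_real_, m), ids)
  if (is.null(chain_len)) chain_len <- stats::setNames(diag(as.matrix(length)), ids)

  # union-find over redundant pairs
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  edges <- list()
  for (i in seq_len(max(0L, m - 1L))) {
    for (j in seq(i + 1L, m)) {
      L <- max(1, length[i, j])
      if (identity[i, j] > rost_threshold(L, n)) {
        pi_ <- find(i); pj <- find(j)
        if (pi_ != pj) parent[pj] <- pi_
        edges[[length(edges) + 1L]] <- data.frame(
          a = ids[i], b = ids[j], identity = identity[i, j],
          threshold = rost_threshold(L, n), stringsAsFactors = FALSE)
      }
    }
  }
  comp <- vapply(seq_len(m), find, integer(1))
  comp <- match(comp, unique(comp))
  names(comp) <- ids

  reps <- vapply(split(seq_len(m), comp), function(members) {
    res <- resolution[ids[members]]
    res[is.na(res)] <- Inf
    len <- chain_len[ids[members]]
    len[is.na(len)] <- 0
    ord <- order(res, -len, ids[members])
    ids[members[ord[1]]]
  }, character(1))
  list(representatives = unname(reps), component = comp,
       edges = if (length(edges)) do.call(rbind, edges) else
         data.frame(a = character(0), b = character(0),
                    identity = numeric(0), threshold = numeric(0)))
}
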