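# Structure input/output.  Parsing of PDB/mmCIF files is delegated to
# bio3d; on top of that the package resolves alternate locations, drops
# waters, maps modified residues to their parents, and presents a uniform
# multi-chain model.

#' Construct a structure model from an atom table
#'
#' The in-memory representation of a structure is a flat atom data frame
#' plus metadata, wrapped in class `structure_model`.  Required columns:
#' `chain`, `resno`, `insert`, `resid`, `elety`, `elesy`, `x`, `y`, `z`,
#' `o` (occupancy) and `het` (HETATM flag).  A `std_aa` column (standard
#' amino-acid flag, after modified-residue mapping) is added if absent.
#'
#' @param atoms Atom data frame.
#' @param id Structure identifier.
#' @param model_index Which coordinate model the atoms came from.
#' @return A `structure_model` object.
#' @export
model_from_atoms <- function(atoms, id = "model", model_index = 1L) {
  need <- c("chain", "resno", "insert", "resid", "elety", "elesy",
            "x", "y", "z", "o", "het")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty structure: no atoms")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (any(atoms$o < 0 | atoms$o > 1, na.rm = TRUE))
    stop("occupancy outside [0, 1]")
  if (!"std_aa" %in% names(atoms))
    atoms$std_aa <- atoms$resid %in% standard_aa()
  atoms$insert[is.na(atoms$insert)] <- ""
  structure(list(id = id, atoms = atoms, model_index = as.integer(model_index)),
            class = "structure_model")
}

#' Read a macromolecular structure file
#'
#' Reads a PDB or mmCIF file into a [model_from_atoms()] structure model.
#' One coordinate model is selected; alternate locations are resolved to the
#' highest-occupancy copy (first encountered on ties); waters are removed;
#' common modified residues (e.g. MSE) are renamed to their parent type and
#' treated as standard; remaining hetero ligands are retained but flagged.
#'
#' @param path Path to the file.
#' @param format `"pdb"`, `"cif"`, or `"auto"` (from the file extension).
#' @param model_index Coordinate model to read (1 = first; NMR ensembles).
#' @return A `structure_model`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif"),
                           model_index = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    else suppressWarnings(bio3d::read.cif(path, multi = TRUE,
                                          verbose = FALSE)),
    error = function(e) stop("cannot parse ", format, " file '", path,
                             "': ", conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("empty structure: ", path)

  nmodels <- if (!is.null(pdb$xyz) && is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model_index < 1L || model_index > nmodels)
    stop("model_index ", model_index, " out of range (file has ",
         nmodels, " model(s))")
  if (model_index > 1L) {
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }

  atoms <- data.frame(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resid = toupper(as.character(at$resid)),
    elety = as.character(at$elety),
    elesy = toupper(ifelse(is.na(at$elesy) | at$elesy == "",
                           NA_character_, as.character(at$elesy))),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt) | at$alt == "", "", as.character(at$alt)),
    het = at$type == "HETATM",
    stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- " "
  bad <- is.na(atoms$elesy)
  atoms$elesy[bad] <- .element_from_name(atoms$elety[bad], atoms$resid[bad])

  # waters out
  atoms <- atoms[!(atoms$resid %in% .water_names), , drop = FALSE]
  if (nrow(atoms) == 0L) stop("empty structure after water removal: ", path)

  # altloc resolution: keep highest occupancy per (chain, residue, atom name),
  # first encountered on ties
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "|")
  ord <- order(factor(key, levels = unique(key)), -atoms$o)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$insert,
                                   atoms$elety, sep = "|")), , drop = FALSE]
  atoms$alt <- NULL

  # modified residues -> parent type, counted as standard
  mapped <- map_modified_residue(atoms$resid)
  was_mod <- mapped != atoms$resid
  atoms$resid <- mapped
  atoms$std_aa <- atoms$resid %in% standard_aa() & (!atoms$het | was_mod)
  atoms$het[was_mod] <- FALSE

  id <- sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path), ignore.case = TRUE)
  model_from_atoms(atoms, id = id, model_index = model_index)
}

#' Write a structure model to a PDB file
#'
#' @param model A `structure_model`.
#' @param path Output file path.
#' @param remarks Optional character vector written as REMARK records.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, remarks = NULL) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = ifelse(at$het, "HETATM", "ATOM"),
                   resno = at$resno, resid = at$resid, chain = at$chain,
                   insert = ifelse(at$insert == "", NA, at$insert),
                   elety = at$elety, o = at$o, b = rep(0, nrow(at)),
                   elesy = at$elesy)
  if (!is.null(remarks)) {
    lines <- readLines(path)
    writeLines(c(sprintf("REMARK 250 %s", remarks), lines), path)
  }
  invisible(path)
}

#' @export
print.structure_model <- function(x, ...) {
  no <- n_observed(x)
  cat("structure_model '", x$id, "': ", nrow(x$atoms), " atoms, ",
      length(no), " chain(s)\n", sep = "")
  for (ch in names(no))
    cat("  chain ", ch, ": ", no[[ch]], " observed residues\n", sep = "")
  invisible(x)
}

#' Chain identifiers of a model
#' @param model A `structure_model`.
#' @return Character vector of chain ids, in file order.
#' @export
chain_ids <- function(model) unique(model$atoms$chain)

#' Number of observed residues per chain
#'
#' Counts, for each chain, the standard amino-acid residues that have an
#' alpha-carbon with coordinates — the chain length N entering the Rg/N
#' statistic.
#'
#' @param model A `structure_model`.
#' @return Named integer vector, one entry per chain.
#' @export
n_observed <- function(model) {
  at <- model$atoms
  ca <- at[at$std_aa & at$elety == "CA" & !at$het, , drop = FALSE]
  out <- integer(0)
  for (ch in chain_ids(model)) {
    sub <- ca[ca$chain == ch, , drop = FALSE]
    out[ch] <- length(unique(paste(sub$resno, sub$insert)))
  }
  out
}

#' Alpha-carbon coordinates of one chain
#'
#' @param model A `structure_model`.
#' @param chain Chain identifier.
#' @return Matrix (N x 3) of CA coordinates of standard residues, in
#'   residue order.
#' @export
ca_coords <- function(model, chain) {
  at <- model$atoms
  sel <- at$chain == chain & at$std_aa & at$elety == "CA" & !at$het
  sub <- at[sel, , drop = FALSE]
  sub <- sub[!duplicated(paste(sub$resno, sub$insert)), , drop = FALSE]
  as.matrix(sub[, c("x", "y", "z")])
}

#' One-letter sequence of the observed residues of a chain
#' @param model A `structure_model`.
#' @param chain Chain identifier.
#' @return Single string of one-letter codes (residues with a CA atom).
#' @export
chain_sequence <- function(model, chain) {
  at <- model$atoms
  sel <- at$chain == chain & at$std_aa & at$elety == "CA" & !at$het
  sub <- at[sel, , drop = FALSE]
  sub <- sub[!duplicated(paste(sub$resno, sub$insert)), , drop = FALSE]
  paste(aa_one_letter()[sub$resid], collapse = "")
}

# Chains qualifying as polymer: >= 1 standard residue with a CA atom.
.polymer_chains <- function(model) {
  no <- n_observed(model)
  names(no)[no >= 1L]
}

#' Split a complex into a segment and its binding partner
#'
#' Defines the two sides used throughout the interface analysis: the chain
#' of interest (`segment`) versus the union of all other polymer chains,
#' treated as one rigid binding-partner group.
#'
#' @param model A `structure_model`.
#' @param segment_chain Chain id of the segment side.
#' @return A `complex_partition` (list with `model`, `segment`, `partner`).
#' @export
partition_complex <- function(model, segment_chain) {
  stopifnot(inherits(model, "structure_model"))
  poly <- .polymer_chains(model)
  if (!segment_chain %in% poly)
    stop("chain '", segment_chain, "' is not a polymer chain of the model")
  partner <- setdiff(poly, segment_chain)
  if (length(partner) == 0L)
    stop("no binding partner: structure has a single polymer chain")
  structure(list(model = model, segment = segment_chain, partner = partner),
            class = "complex_partition")
}

#' @export
print.complex_partition <- function(x, ...) {
  cat("complex_partition: segment chain ", x$segment, " vs partner {",
      paste(x$partner, collapse = ", "), "}\n", sep = "")
  invisible(x)
}
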