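#' Multi-chain coordinate models
#'
#' A `structure_model` holds the parsed contents of one coordinate file:
#' polymer chains with per-residue C-alpha coordinates under both author
#' and label numbering, plus non-polymer (ligand) components.  It is the
#' input container for subunit assignment, atom selection, and all
#' conformational metrics.
#'
#' @name structure_model
NULL

#' Construct a structure model from an atom table
#'
#' @param entry_id Accession or fixture identifier (non-empty string).
#' @param atoms data.frame with columns `type` ("ATOM"/"HETATM"), `chain`,
#'   `resid` (3-letter component id), `resno` (author residue number),
#'   `label_resno` (label numbering; may be NA), `elety` (atom name),
#'   `x`, `y`, `z` (Angstrom).
#' @return A `structure_model`.
#' @export
structure_model <- function(entry_id, atoms) {
  if (!is.character(entry_id) || length(entry_id) != 1 || !nzchar(entry_id))
    stop("entry_id must be a non-empty string")
  need <- c("type", "chain", "resid", "resno", "label_resno", "elety",
            "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ",
                         paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms)[, need]
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in atom table")
  pol <- atoms[atoms$type == "ATOM", ]
  if (nrow(pol) == 0) stop("empty structure: no polymer chains")
  # invariant: one CA per resolved residue
  ca <- pol[pol$elety == "CA", ]
  if (anyDuplicated(ca[, c("chain", "resno")]))
    stop("duplicate C-alpha records for a (chain, residue) pair")
  obj <- list(entry_id = entry_id, atoms = atoms)
  class(obj) <- "structure_model"
  obj
}

#' Read a coordinate file (mmCIF or PDB)
#'
#' Parses a macromolecular coordinate file into a [structure_model()].
#' mmCIF is parsed with `bio3d::read.cif()`; because bio3d reports author
#' numbering only, the `_atom_site.label_seq_id` column is read directly
#' from the file so both numbering schemes are retained.  PDB files carry
#' a single numbering, used for both.
#'
#' @param source Path to a `.cif`/`.mmcif` or `.pdb`/`.ent` file.
#' @param format "auto" (default, from extension), "mmcif" or "pdb".
#' @param entry_id Identifier to record; default: file name stem.
#' @return A `structure_model`.
#' @export
load_structure <- function(source, format = c("auto", "mmcif", "pdb"),
                           entry_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(source)) stop("file not found: ", source)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", source, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  if (is.null(entry_id)) {
    entry_id <- if (format == "mmcif") {
      first <- grep("^data_", readLines(source, n = 50, warn = FALSE),
                    value = TRUE)
      if (length(first)) sub("^data_", "", first[1]) else NA
    } else NA
    if (is.na(entry_id) || !nzchar(entry_id))
      entry_id <- sub("\\.[A-Za-z]+$", "", basename(source))
  }
  pdb <- tryCatch(
    if (format == "mmcif")
      suppressWarnings(bio3d::read.cif(source))
    else
      suppressWarnings(bio3d::read.pdb(source)),
    error = function(e) stop("parse error in ", basename(source), ": ",
                             conditionMessage(e)))
  at <- pdb$atom
  label_resno <- if (format == "mmcif") {
    lab <- .read_cif_label_seq(source)
    if (length(lab) == nrow(at)) lab else rep(NA_integer_, nrow(at))
  } else at$resno
  atoms <- data.frame(
    type = at$type, chain = at$chain, resid = at$resid, resno = at$resno,
    label_resno = label_resno, elety = at$elety,
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  structure_model(entry_id, atoms)
}

# Supplemental scan of the _atom_site loop for label_seq_id (bio3d keeps
# author numbering only).  Returns integer vector, or integer(0) on failure.
.read_cif_label_seq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^_atom_site\\.", lines)
  if (!length(hdr)) return(integer(0))
  cols <- sub("^_atom_site\\.", "", trimws(lines[hdr]))
  i <- which(cols == "label_seq_id")
  if (!length(i)) return(integer(0))
  body <- lines[seq(max(hdr) + 1L, length(lines))]
  rows <- grep("^(ATOM|HETATM)\\s", body, value = TRUE)
  vals <- vapply(strsplit(rows, "\\s+"), function(f)
    if (length(f) >= i) f[[i]] else NA_character_, character(1))
  suppressWarnings(as.integer(ifelse(vals %in% c(".", "?"), NA, vals)))
}

#' @export
print.structure_model <- function(x, ...) {
  pol <- polymer_chains(x)
  lig <- ligand_components(x)
  cat(sprintf("structure_model '%s': %d polymer chain(s) [%s]",
              x$entry_id, length(pol), paste(pol, collapse = ",")))
  if (nrow(lig))
    cat(sprintf(", %d ligand component(s) [%s]", nrow(lig),
                paste(unique(lig$resid), collapse = ",")))
  cat("\n")
  invisible(x)
}

#' Polymer chain identifiers of a model
#' @param model A `structure_model`.
#' @return Character vector of chain ids.
#' @export
polymer_chains <- function(model) {
  sort(unique(model$atoms$chain[model$atoms$type == "ATOM"]))
}

#' Ligand (non-polymer, non-water) components of a model
#' @param model A `structure_model`.
#' @return data.frame with one row per ligand instance (chain, resid, resno,
#'   n_atoms).
#' @export
ligand_components <- function(model) {
  h <- model$atoms[model$atoms$type == "HETATM" &
                     !model$atoms$resid %in% c("HOH", "WAT"), ]
  if (!nrow(h))
    return(data.frame(chain = character(), resid = character(),
                      resno = integer(), n_atoms = integer()))
  key <- paste(h$chain, h$resid, h$resno)
  agg <- h[!duplicated(key), c("chain", "resid", "resno")]
  agg$n_atoms <- as.integer(table(key)[paste(agg$chain, agg$resid,
                                             agg$resno)])
  rownames(agg) <- NULL
  agg
}

#' C-alpha records of one chain, in residue order
#' @param model A `structure_model`.
#' @param chain Chain id.
#' @return data.frame (resno, label_resno, resid, x, y, z).
#' @export
chain_calpha <- function(model, chain) {
  ca <- model$atoms[model$atoms$type == "ATOM" &
                      model$atoms$chain == chain &
                      model$atoms$elety == "CA", ]
  ca <- ca[order(ca$resno), c("resno", "label_resno", "resid",
                              "x", "y", "z")]
  rownames(ca) <- NULL
  ca
}

#' One-letter sequence of a polymer chain
#' @param model A `structure_model`.
#' @param chain Chain id.
#' @return Single string (unknown residues as "X").
#' @export
chain_sequence <- function(model, chain) {
  ca <- chain_calpha(model, chain)
  paste(bio3d::aa321(ca$resid), collapse = "")
}

#' Apply a rigid transform to selected chains of a model
#'
#' @param model A `structure_model`.
#' @param tr A `rigid_transform`.
#' @param chains Chain ids to move (default: all).
#' @return Transformed `structure_model`.
#' @export
transform_model <- function(model, tr, chains = NULL) {
  sel <- if (is.null(chains)) rep(TRUE, nrow(model$atoms))
         else model$atoms$chain %in% chains
  xyz <- as.matrix(model$atoms[sel, c("x", "y", "z")])
  model$atoms[sel, c("x", "y", "z")] <- apply_transform(xyz, tr)
  model
}

#' Write a structure model as mmCIF
#'
#' Emits a minimal but standard `_atom_site` loop (author and label
#' numbering, occupancy 1, B 0) so that models round-trip through
#' [load_structure()].
#'
#' @param model A `structure_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mmcif <- function(model, path) {
  a <- model$atoms
  hdr <- c(paste0("data_", model$entry_id), "#", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  ent <- as.integer(factor(a$chain, levels = unique(a$chain)))
  lab <- ifelse(is.na(a$label_resno), ".", as.character(a$label_resno))
  elem <- substr(gsub("[^A-Za-z]", "", a$elety), 1, 1)
  rows <- sprintf(
    "%s %d %s %s . %s %s %d %s ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
    a$type, seq_len(nrow(a)), elem, a$elety, a$resid, a$chain, ent, lab,
    a$x, a$y, a$z, a$resno, a$resid, a$chain, a$elety)
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}
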