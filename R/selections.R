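#' Declarative atom selections
#'
#' A `selection_spec` names a set of atoms by biological role and residue
#' range (author numbering by default) rather than by chain id, so the
#' same spec resolves consistently across different deposited entries.
#' A spec may instead be a *shell*: all C-alpha atoms within a radius of
#' a ligand, computed once in a designated reference entry and then
#' transferred to other entries by residue identity (the apo and
#' phosphorylated complexes lack the ligand).
#'
#' @name selections
NULL

#' Build a selection spec
#'
#' @param role Subunit role(s) (from [EIF2B_ROLES]); a multi-role spec
#'   (e.g. beta plus delta C-terminal domains) selects across roles.
#' @param resno Integer vector of author residue numbers (e.g.
#'   `247:267`), a named list with one range per role, or NULL for all
#'   resolved residues of the role.
#' @param atoms Atom-name filter; default "CA".
#' @param shell Optional shell definition:
#'   `list(ligand = <role or comp id>, radius = <Angstrom>)`.  When given,
#'   `role`/`resno` are ignored and membership comes from the reference
#'   entry passed to [resolve_selection()].
#' @param numbering "auth" (default) or "label".
#' @return A `selection_spec`.
#' @export
selection_spec <- function(role = NULL, resno = NULL, atoms = "CA",
                           shell = NULL, numbering = c("auth", "label")) {
  numbering <- match.arg(numbering)
  if (is.null(shell)) {
    if (is.null(role)) stop("role is required for a range selection")
    if (!is.null(resno) && length(resno) == 0)
      stop("resno range must be non-empty")
    if (is.list(resno) && !all(role %in% names(resno)))
      stop("per-role resno list must name every role in the spec")
  } else {
    if (is.null(shell$radius) || shell$radius <= 0)
      stop("shell radius must be > 0")
    if (is.null(shell$ligand)) stop("shell must name a ligand")
  }
  structure(list(role = role, resno = resno, atoms = atoms, shell = shell,
                 numbering = numbering),
            class = "selection_spec")
}

#' Resolve a selection to coordinates
#'
#' Returns only residues actually resolved in `model`.  For shell specs,
#' membership is computed in `reference` (which must contain the ligand)
#' and transferred by (role, protomer, residue number).
#'
#' @param model A [structure_model()] with assignment attached or passed.
#' @param assignment [assign_subunits()] result for `model`.
#' @param spec A [selection_spec()].
#' @param protomer "unit1", "unit2" or "both".
#' @param reference,reference_assignment Reference entry (and its
#'   assignment) defining shell membership; required for shell specs.
#' @return An `atom_set`: list with `atoms` data.frame (role, protomer,
#'   chain, resno, elety, x, y, z) in canonical (role, protomer, resno)
#'   order, plus provenance (entry id, spec, coverage warnings).
#' @export
resolve_selection <- function(model, assignment, spec,
                              protomer = "both",
                              reference = NULL,
                              reference_assignment = NULL) {
  stopifnot(inherits(spec, "selection_spec"))
  if (!is.null(spec$shell)) {
    if (is.null(reference))
      stop("shell selections need a reference entry containing the ligand")
    if (is.null(reference_assignment))
      stop("shell selections need the reference entry's assignment")
    members <- shell_membership(reference, reference_assignment, spec)
    return(.atoms_by_identity(model, assignment, members, spec, protomer))
  }
  rows <- list()
  n_requested <- 0L
  for (role in spec$role) {
    chains <- role_chains(assignment, role, protomer)
    if (!length(chains))
      stop("role ", role, " not present in assignment")
    rng <- if (is.list(spec$resno)) spec$resno[[role]] else spec$resno
    if (!is.null(rng))
      n_requested <- n_requested + length(rng) * length(chains) *
        length(spec$atoms)
    for (ch in chains) {
      a <- model$atoms[model$atoms$chain == ch &
                         model$atoms$elety %in% spec$atoms &
                         model$atoms$type == "ATOM", ]
      num <- if (spec$numbering == "label") a$label_resno else a$resno
      if (!is.null(rng)) a <- a[num %in% rng, ]
      if (!nrow(a)) next
      rows[[length(rows) + 1L]] <- data.frame(
        role = role,
        protomer = assignment$protomer[assignment$chain == ch][1],
        chain = ch, resno = a$resno, elety = a$elety,
        x = a$x, y = a$y, z = a$z)
    }
  }
  atoms <- do.call(rbind, rows)
  if (is.null(atoms) || !nrow(atoms))
    stop("selection resolves to zero atoms in ", model$entry_id)
  warn <- NULL
  if (n_requested > 0 && nrow(atoms) / n_requested < 0.5)
    warn <- sprintf("low coverage: %.0f%% of requested range resolved",
                    100 * nrow(atoms) / n_requested)
  .atom_set(atoms, model$entry_id, spec, warn)
}

.atom_set <- function(atoms, entry_id, spec, warn = NULL) {
  atoms$protomer[is.na(atoms$protomer)] <- "na"
  atoms <- atoms[order(atoms$role, atoms$protomer, atoms$resno,
                       atoms$elety), ]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms,
                 provenance = list(entry_id = entry_id, spec = spec,
                                   warnings = warn)),
            class = "atom_set")
}

#' @export
print.atom_set <- function(x, ...) {
  cat(sprintf("atom_set: %d atoms from %s\n", nrow(x$atoms),
              x$provenance$entry_id))
  if (!is.null(x$provenance$warnings))
    cat("  !", x$provenance$warnings, "\n")
  invisible(x)
}

#' Shell membership around a ligand in a reference entry
#'
#' All polymer C-alpha atoms of assigned tetramer subunits within
#' `spec$shell$radius` of any ligand atom.
#'
#' @param reference A [structure_model()] containing the ligand.
#' @param assignment Its [assign_subunits()] result.
#' @param spec A shell [selection_spec()].
#' @return data.frame (role, protomer, resno) identifying member residues.
#' @export
shell_membership <- function(reference, assignment, spec) {
  lig_chain <- role_chains(assignment, spec$shell$ligand)
  lig <- reference$atoms[reference$atoms$chain %in% lig_chain &
                           reference$atoms$type == "HETATM", ]
  if (!nrow(lig)) # allow naming a raw component id
    lig <- reference$atoms[reference$atoms$resid == spec$shell$ligand &
                             reference$atoms$type == "HETATM", ]
  if (!nrow(lig))
    stop("shell-resolution error: ligand ", spec$shell$ligand,
         " absent from reference ", reference$entry_id)
  L <- as.matrix(lig[, c("x", "y", "z")])
  assigned <- assignment[!is.na(assignment$role) &
                           assignment$role %in% EIF2B_ROLES, ]
  rows <- lapply(seq_len(nrow(assigned)), function(i) {
    ca <- chain_calpha(reference, assigned$chain[i])
    if (!nrow(ca)) return(NULL)
    X <- as.matrix(ca[, c("x", "y", "z")])
    d2 <- apply(X, 1, function(p) min(colSums((t(L) - p)^2)))
    keep <- d2 <= spec$shell$radius^2
    if (!any(keep)) return(NULL)
    data.frame(role = assigned$role[i], protomer = assigned$protomer[i],
               resno = ca$resno[keep])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("empty shell: no C-alpha within radius")
  out
}

# resolve a (role, protomer, resno) membership table in another entry
.atoms_by_identity <- function(model, assignment, members, spec, protomer) {
  if (protomer != "both")
    members <- members[members$protomer %in% c(protomer, NA), ]
  rows <- lapply(seq_len(nrow(members)), function(i) {
    chs <- role_chains(assignment, members$role[i],
                       if (is.na(members$protomer[i])) "both"
                       else members$protomer[i])
    for (ch in chs) {
      a <- model$atoms[model$atoms$chain == ch &
                         model$atoms$resno == members$resno[i] &
                         model$atoms$elety %in% spec$atoms &
                         model$atoms$type == "ATOM", ]
      if (nrow(a))
        return(data.frame(role = members$role[i],
                          protomer = members$protomer[i], chain = ch,
                          resno = a$resno[1], elety = a$elety[1],
                          x = a$x[1], y = a$y[1], z = a$z[1]))
    }
    NULL
  })
  atoms <- do.call(rbind, rows)
  if (is.null(atoms) || !nrow(atoms))
    stop("no-overlap: shell transfers to zero residues in ",
         model$entry_id)
  cov <- nrow(atoms) / nrow(members)
  warn <- if (cov < 0.5)
    sprintf("low coverage: shell transfer covers %.0f%% of residues",
            100 * cov)
  .atom_set(atoms, model$entry_id, spec, warn)
}

#' Pair two atom sets by residue identity
#'
#' Keeps the intersection of (role, protomer, resno, atom name) present in
#' both sets, in canonical order, so the two returned sets are matched
#' row-for-row.  Pairing is symmetric: `pair(A,B)` and `pair(B,A)` keep
#' the same residue identities.
#'
#' @param a,b `atom_set`s.
#' @return List with paired `a` and `b` atom sets of equal length.
#' @export
pair_atom_sets <- function(a, b) {
  stopifnot(inherits(a, "atom_set"), inherits(b, "atom_set"))
  key <- function(s) paste(s$atoms$role, s$atoms$protomer, s$atoms$resno,
                           s$atoms$elety)
  ka <- key(a); kb <- key(b)
  common <- intersect(ka, kb)
  if (!length(common)) stop("no-overlap: paired selections share no atoms")
  a$atoms <- a$atoms[match(common, ka), ]
  b$atoms <- b$atoms[match(common, kb), ]
  rownames(a$atoms) <- rownames(b$atoms) <- NULL
  list(a = a, b = b)
}
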