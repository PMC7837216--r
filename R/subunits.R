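#' Subunit-role assignment for eIF2B complexes
#'
#' eIF2B is a two-fold pseudo-symmetric decamer: two copies each of the
#' alpha, beta, gamma, delta and epsilon subunits.  Complexes may
#' additionally contain one or two phosphorylated eIF2 trimers (of which
#' the alpha and sometimes gamma subunits are resolved) and the small
#' molecule ISRIB at the central beta/delta-beta'/delta' interface.
#' `assign_subunits()` maps chain ids to these biological roles by
#' sequence identity against a per-role reference library and tags each
#' beta/delta/gamma/epsilon chain with the protomer ("unit1"/"unit2") it
#' belongs to.
#'
#' @name subunit_assignment
NULL

#' Roles recognised by the assignment
#' @export
EIF2B_ROLES <- c("eIF2B_alpha", "eIF2B_beta", "eIF2B_gamma",
                 "eIF2B_delta", "eIF2B_eps", "eIF2_alpha", "eIF2_gamma")

.TETRAMER_ROLES <- c("eIF2B_beta", "eIF2B_gamma", "eIF2B_delta", "eIF2B_eps")

#' Assign chains to subunit roles
#'
#' Each polymer chain is compared against every reference sequence and
#' assigned the best-matching role, provided the identity exceeds
#' `min_identity`; chains below threshold for all roles are left
#' unassigned with a warning.  beta/delta/gamma/epsilon chains are then
#' split into two protomers by distance of their C-alpha centroid to the
#' nearest eIF2B alpha chain (falling back to 2-means clustering of the
#' centroids when fewer than two alpha chains are resolved); "unit1" is
#' the group whose member set contains the lexicographically smallest
#' chain id, making the assignment deterministic.
#'
#' @param model A [structure_model()].
#' @param references Named list of one-letter reference sequences, one per
#'   role in [EIF2B_ROLES] (roles absent from the complex may be omitted).
#' @param min_identity Minimum fractional sequence identity for an
#'   assignment (default 0.6).
#' @param isrib_components Chemical component ids treated as the ISRIB
#'   ligand.
#' @return A `subunit_assignment`: data.frame with columns `chain`, `role`,
#'   `protomer` ("unit1"/"unit2"/NA), `identity`; ligand chains carry role
#'   "ISRIB".
#' @export
assign_subunits <- function(model, references,
                            min_identity = 0.6,
                            isrib_components = c("ISR", "ISB", "FAM")) {
  stopifnot(inherits(model, "structure_model"))
  if (is.null(names(references)) || !all(nzchar(names(references))))
    stop("references must be a named list of sequences")
  unknown <- setdiff(names(references), EIF2B_ROLES)
  if (length(unknown))
    stop("unknown roles in reference library: ",
         paste(unknown, collapse = ", "))
  chains <- polymer_chains(model)
  rows <- lapply(chains, function(ch) {
    sq <- chain_sequence(model, ch)
    ids <- vapply(references, function(ref) .seq_identity(sq, ref),
                  numeric(1))
    best <- which.max(ids)
    if (ids[best] < min_identity) {
      warning("chain ", ch, " below identity threshold for all roles ",
              "(best ", sprintf("%.2f", ids[best]), "); left unassigned")
      data.frame(chain = ch, role = NA_character_,
                 protomer = NA_character_, identity = ids[best])
    } else {
      data.frame(chain = ch, role = names(references)[best],
                 protomer = NA_character_, identity = ids[best])
    }
  })
  asg <- do.call(rbind, rows)

  # ligands
  lig <- ligand_components(model)
  if (nrow(lig)) {
    isr <- lig[lig$resid %in% isrib_components, , drop = FALSE]
    if (nrow(isr))
      asg <- rbind(asg, data.frame(chain = unique(isr$chain), role = "ISRIB",
                                   protomer = NA_character_, identity = NA_real_))
  }

  asg <- .tag_protomers(model, asg)
  class(asg) <- c("subunit_assignment", "data.frame")
  asg
}

# fractional identity between a chain sequence and a reference.
# A cheap ungapped sliding comparison is tried first (exact for
# substring matches, as in the synthetic library, and a reliable
# rejector for clear non-matches); borderline scores are refined with a
# Biostrings global-local alignment when available, which handles the
# gapped chains of real deposited models.
.seq_identity <- function(seq, ref) {
  if (!nzchar(seq) || !nzchar(ref)) return(0)
  quick <- .sliding_identity(seq, ref)
  if (quick >= 0.95 || quick < 0.25) return(quick)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    al <- Biostrings::pairwiseAlignment(seq, ref, type = "global-local",
                                        gapOpening = 10, gapExtension = 0.5)
    return(Biostrings::nmatch(al) / nchar(seq))
  }
  quick
}

.sliding_identity <- function(seq, ref) {
  s <- strsplit(seq, "")[[1]]; r <- strsplit(ref, "")[[1]]
  if (length(s) > length(r)) { tmp <- s; s <- r; r <- tmp }
  best <- 0L
  for (off in 0:(length(r) - length(s)))
    best <- max(best, sum(s == r[seq_along(s) + off]))
  best / nchar(seq)
}

.tag_protomers <- function(model, asg) {
  tet <- which(asg$role %in% .TETRAMER_ROLES)
  if (!length(tet)) return(asg)
  cent <- t(vapply(asg$chain[tet], function(ch) {
    ca <- chain_calpha(model, ch)
    c(mean(ca$x), mean(ca$y), mean(ca$z))
  }, numeric(3)))
  alph <- asg$chain[asg$role %in% "eIF2B_alpha"]
  if (length(alph) >= 2) {
    acent <- t(vapply(alph, function(ch) {
      ca <- chain_calpha(model, ch)
      c(mean(ca$x), mean(ca$y), mean(ca$z))
    }, numeric(3)))
    d <- vapply(seq_len(nrow(acent)), function(i)
      sqrt(rowSums(sweep(cent, 2, acent[i, ])^2)),
      numeric(nrow(cent)))
    d <- matrix(d, nrow = nrow(cent))
    grp <- apply(d, 1, which.min)
  } else {
    if (nrow(cent) < 2)
      stop("cannot split fewer than two tetramer chains into protomers")
    grp <- stats::cutree(stats::hclust(stats::dist(cent),
                                       method = "average"), k = 2)
  }
  # deterministic labels: unit1 holds the lexicographically smallest chain
  g1 <- grp[which(asg$chain[tet] == min(asg$chain[tet]))[1]]
  asg$protomer[tet] <- ifelse(grp == g1, "unit1", "unit2")
  # sanity: the two protomers must partition roles (<=1 delta per unit etc.)
  for (role in .TETRAMER_ROLES) {
    pr <- asg$protomer[tet][asg$role[tet] == role]
    if (any(table(pr) > 1))
      stop("assignment error: two ", role,
           " chains fell in one protomer group")
  }
  asg
}

#' Chains playing a role (optionally restricted to one protomer)
#' @param assignment A `subunit_assignment`.
#' @param role One of [EIF2B_ROLES] or "ISRIB".
#' @param protomer "unit1", "unit2" or "both" (default).
#' @return Character vector of chain ids.
#' @export
role_chains <- function(assignment, role, protomer = "both") {
  sel <- assignment$role %in% role
  if (protomer != "both" && role %in% .TETRAMER_ROLES)
    sel <- sel & assignment$protomer %in% protomer
  assignment$chain[sel]
}
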