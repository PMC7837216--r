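#' Conformational-change metrics between complex structures
#'
#' Binding of phosphorylated eIF2 remodels eIF2B: the beta/delta cleft
#' that productively engages the eIF2alpha N-terminal domain widens
#' (displacing delta helix alpha3, residues 247-267, and tilting its
#' axis away from eIF2B beta), and the two beta-delta heterodimeric
#' units forming the central ISRIB pocket move apart.  The functions
#' here quantify those motions: structure pairs are first superposed on
#' a user-specified *frame* (by default the four C-terminal domains of
#' the beta and delta subunits) and the probe displacement, helix-axis
#' rotation and pocket deformation are measured in that common frame.
#'
#' @name conformetrics
NULL

.paired_frames <- function(ref, ref_asg, target, target_asg, frame,
                           reference_entry = NULL, reference_asg = NULL) {
  fa <- resolve_selection(ref, ref_asg, frame, "both",
                          reference_entry, reference_asg)
  fb <- resolve_selection(target, target_asg, frame, "both",
                          reference_entry, reference_asg)
  pair_atom_sets(fb, fa) # mobile = target, reference = ref
}

#' Mean probe displacement after frame superposition
#'
#' Superposes `target` onto `ref` using the frame atoms, then reports the
#' mean Euclidean displacement over paired probe C-alpha atoms, per
#' protomer and overall.
#'
#' @param ref,target [structure_model()]s.
#' @param ref_asg,target_asg Their [assign_subunits()] results.
#' @param frame [selection_spec()] defining the alignment frame.
#' @param probe [selection_spec()] defining the probe atoms.
#' @param protomers Protomers to report (default both).
#' @return List with `per_protomer` (named numeric, Angstrom), `mean`,
#'   `rmsd_fit` of the frame alignment, and `n` probe atoms used.
#' @export
mean_displacement <- function(ref, target, frame, probe,
                              ref_asg = attr(ref, "assignment"),
                              target_asg = attr(target, "assignment"),
                              protomers = c("unit1", "unit2")) {
  fr <- .paired_frames(ref, ref_asg, target, target_asg, frame)
  sup <- kabsch_superpose(fr$a, fr$b)
  per <- rms <- stats::setNames(rep(NA_real_, length(protomers)),
                                protomers)
  for (u in protomers) {
    pa <- tryCatch(resolve_selection(ref, ref_asg, probe, u),
                   error = function(e) NULL)
    pb <- tryCatch(resolve_selection(target, target_asg, probe, u),
                   error = function(e) NULL)
    if (is.null(pa) || is.null(pb)) next
    pp <- pair_atom_sets(pb, pa)
    moved <- apply_transform(coords_of(pp$a), sup$transform)
    d2 <- rowSums((moved - coords_of(pp$b))^2)
    per[u] <- mean(sqrt(d2))
    rms[u] <- sqrt(mean(d2))
  }
  if (all(is.na(per))) stop("no-overlap: probe resolves in no protomer")
  list(per_protomer = per, mean = mean(per, na.rm = TRUE),
       rmsd_probe = rms, rmsd_probe_mean = mean(rms, na.rm = TRUE),
       rmsd_fit = sup$rmsd_fit, n = sup$n_atoms)
}

#' Helix-axis rotation between two entries
#'
#' After frame superposition, measures the angle between the probe-helix
#' axes of the two entries (per protomer), in [0, 180] degrees, and
#' labels the direction of motion: "toward_beta" if the helix centroid
#' moves closer to the same-protomer eIF2B beta C-alpha centroid,
#' "away_from_beta" if farther, "n/a" if essentially unmoved.
#'
#' @inheritParams mean_displacement
#' @param helix [selection_spec()] for the helix (>= 7 consecutive CA).
#' @param beta_role Role providing the direction reference (default
#'   "eIF2B_beta").
#' @param direction_tol Centroid-distance change (Angstrom) below which
#'   the direction is labelled "n/a" (default 0.05).
#' @return List with `per_protomer` angles (degrees), `mean`, `direction`
#'   per protomer, `rmsd_fit`.
#' @export
axis_rotation <- function(ref, target, frame, helix,
                          ref_asg = attr(ref, "assignment"),
                          target_asg = attr(target, "assignment"),
                          beta_role = "eIF2B_beta",
                          protomers = c("unit1", "unit2"),
                          direction_tol = 0.05) {
  fr <- .paired_frames(ref, ref_asg, target, target_asg, frame)
  sup <- kabsch_superpose(fr$a, fr$b)
  ang <- dir <- stats::setNames(rep(NA_real_, length(protomers)), protomers)
  dir <- stats::setNames(rep(NA_character_, length(protomers)), protomers)
  for (u in protomers) {
    ha <- tryCatch(resolve_selection(ref, ref_asg, helix, u),
                   error = function(e) NULL)
    hb <- tryCatch(resolve_selection(target, target_asg, helix, u),
                   error = function(e) NULL)
    if (is.null(ha) || is.null(hb)) next
    pp <- pair_atom_sets(hb, ha)
    gx_ref <- helix_axis(coords_of(pp$b))
    moved <- apply_transform(coords_of(pp$a), sup$transform)
    gx_tgt <- helix_axis(moved)
    ang[u] <- angle_between(gx_ref$axis, gx_tgt$axis)
    # direction: centroid distance to same-protomer beta centroid (in ref
    # frame) before vs after
    bc <- tryCatch({
      bsel <- selection_spec(beta_role)
      bset <- resolve_selection(ref, ref_asg, bsel, u)
      colMeans(coords_of(bset))
    }, error = function(e) NULL)
    if (!is.null(bc)) {
      d_ref <- sqrt(sum((gx_ref$centroid - bc)^2))
      d_tgt <- sqrt(sum((gx_tgt$centroid - bc)^2))
      dir[u] <- if (abs(d_tgt - d_ref) < direction_tol) "n/a"
      else if (d_tgt < d_ref) "toward_beta" else "away_from_beta"
    }
  }
  if (all(is.na(ang))) stop("helix resolves in no protomer")
  list(per_protomer = ang, mean = mean(ang, na.rm = TRUE),
       direction = dir, rmsd_fit = sup$rmsd_fit)
}

#' Relative displacement of the two halves of the ISRIB pocket
#'
#' The pocket shell (C-alpha atoms within `radius` of the ligand) is
#' computed in `shell_ref` (the entry containing the ligand), split by
#' protomer, and transferred to `ref` and `target` by residue identity.
#' Structures are superposed on the shell atoms of `frame_unit`; the mean
#' displacement of the *other* unit's shell atoms measures how far the
#' two beta-delta units have moved apart.
#'
#' @param ref,target [structure_model()]s to compare.
#' @param shell_ref Entry containing the ligand (e.g. the ISRIB
#'   co-structure); defaults to `ref`.
#' @param frame_unit "unit1" or "unit2": the unit aligned on.
#' @param ligand Ligand role or component id (default "ISRIB").
#' @param radius Shell radius in Angstrom (default 10).
#' @param ref_asg,target_asg,shell_ref_asg Assignments.
#' @return List with `displacement` (Angstrom), `rmsd_fit`, `n_frame`,
#'   `n_probe`, `frame_unit`.
#' @export
pocket_displacement <- function(ref, target,
                                shell_ref = ref,
                                frame_unit = c("unit1", "unit2"),
                                ligand = "ISRIB", radius = 10,
                                ref_asg = attr(ref, "assignment"),
                                target_asg = attr(target, "assignment"),
                                shell_ref_asg = if (identical(shell_ref, ref))
                                  ref_asg else attr(shell_ref, "assignment")) {
  frame_unit <- match.arg(frame_unit)
  other_unit <- setdiff(c("unit1", "unit2"), frame_unit)
  spec <- selection_spec(shell = list(ligand = ligand, radius = radius))
  sel <- function(model, asg, unit)
    resolve_selection(model, asg, spec, unit, shell_ref, shell_ref_asg)
  fa <- sel(ref, ref_asg, frame_unit)
  fb <- sel(target, target_asg, frame_unit)
  fp <- pair_atom_sets(fb, fa)
  cov <- nrow(fp$a$atoms)
  sup <- kabsch_superpose(fp$a, fp$b)
  pa <- sel(ref, ref_asg, other_unit)
  pb <- sel(target, target_asg, other_unit)
  pp <- pair_atom_sets(pb, pa)
  for (s in list(fa, fb, pa, pb))
    if (!is.null(s$provenance$warnings)) stop(s$provenance$warnings)
  moved <- apply_transform(coords_of(pp$a), sup$transform)
  disp <- mean(sqrt(rowSums((moved - coords_of(pp$b))^2)))
  list(displacement = disp, rmsd_fit = sup$rmsd_fit,
       n_frame = cov, n_probe = nrow(pp$a$atoms), frame_unit = frame_unit)
}

#' Run a batch of configured structure comparisons
#'
#' Each comparison names a reference entry, a target entry, and a metric
#' type; failures are recorded per comparison and the batch continues.
#'
#' @param models Named list of [structure_model()]s (with assignments
#'   attached as `attr(,"assignment")`).
#' @param comparisons List of comparison specs; each a list with `id`,
#'   `ref`, `target`, `type` ("displacement", "rotation", or "pocket"),
#'   plus `frame`/`probe` ([selection_spec()]s) for displacement and
#'   rotation, or `shell_ref`/`frame_unit`/`ligand`/`radius` for pocket.
#' @return A `conformational_metrics_report` data.frame: one row per
#'   comparison x metric with columns id, ref, target, metric, unit1,
#'   unit2, mean, direction, rmsd_fit, n, error.
#' @export
compare_complexes <- function(models, comparisons) {
  rows <- lapply(comparisons, function(cmp) {
    out <- data.frame(id = cmp$id, ref = cmp$ref, target = cmp$target,
                      metric = cmp$type, unit1 = NA_real_, unit2 = NA_real_,
                      mean = NA_real_, direction = NA_character_,
                      rmsd_fit = NA_real_, n = NA_integer_,
                      error = NA_character_)
    res <- tryCatch({
      ref <- models[[cmp$ref]]; tgt <- models[[cmp$target]]
      if (is.null(ref) || is.null(tgt)) stop("entry not loaded")
      switch(cmp$type,
        displacement = {
          m <- mean_displacement(ref, tgt, cmp$frame, cmp$probe)
          out$unit1 <- m$per_protomer[["unit1"]]
          out$unit2 <- m$per_protomer[["unit2"]]
          out$mean <- m$mean; out$rmsd_fit <- m$rmsd_fit; out$n <- m$n
          out
        },
        probe_rmsd = {
          m <- mean_displacement(ref, tgt, cmp$frame, cmp$probe)
          out$unit1 <- m$rmsd_probe[["unit1"]]
          out$unit2 <- m$rmsd_probe[["unit2"]]
          out$mean <- m$rmsd_probe_mean
          out$rmsd_fit <- m$rmsd_fit; out$n <- m$n
          out
        },
        rotation = {
          m <- axis_rotation(ref, tgt, cmp$frame, cmp$probe)
          out$unit1 <- m$per_protomer[["unit1"]]
          out$unit2 <- m$per_protomer[["unit2"]]
          out$mean <- m$mean; out$rmsd_fit <- m$rmsd_fit
          out$direction <- paste(stats::na.omit(unique(m$direction)),
                                 collapse = "|")
          out
        },
        pocket = {
          sref <- if (!is.null(cmp$shell_ref)) models[[cmp$shell_ref]]
                  else ref
          m <- pocket_displacement(
            ref, tgt, shell_ref = sref,
            frame_unit = if (is.null(cmp$frame_unit)) "unit1"
                         else cmp$frame_unit,
            ligand = if (is.null(cmp$ligand)) "ISRIB" else cmp$ligand,
            radius = if (is.null(cmp$radius)) 10 else cmp$radius,
            shell_ref_asg = attr(sref, "assignment"))
          out$mean <- m$displacement; out$rmsd_fit <- m$rmsd_fit
          out$n <- m$n_probe
          out
        },
        stop("unknown comparison type: ", cmp$type))
    }, error = function(e) {
      out$error <- conditionMessage(e)
      out
    })
    res
  })
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  class(rep) <- c("conformational_metrics_report", "data.frame")
  rep
}

#' Attach a subunit assignment to a model
#'
#' @param model A [structure_model()].
#' @param references Reference sequence library for [assign_subunits()].
#' @param ... Passed to [assign_subunits()].
#' @return The model with `attr(, "assignment")` set.
#' @export
annotate_structure <- function(model, references, ...) {
  attr(model, "assignment") <- assign_subunits(model, references, ...)
  model
}
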