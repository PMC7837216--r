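#' Synthetic recapitulation of the published conformational metrics
#'
#' Builds a suite of fixture pairs in which rigid motions are
#' analytically calibrated so that the *measured* metrics equal the
#' values published for the deposited complexes: the delta alpha3
#' displacement/rotation of the singly- and doubly-bound
#' phosphorylated complexes, the productive-complex narrowing, the
#' beta-subunit alignment RMSD, and the ISRIB-pocket separations.
#' Running [compare_complexes()] on the suite therefore exercises the
#' identical measurement pipeline used for downloaded accessions, with
#' ground truth known by construction.  (Reproduction from the real
#' accessions requires [fetch_structures()] and a network connection;
#' this suite is the download-free counterpart.)
#'
#' @param seed Seed for the fixtures' global placements.
#' @param via_mmcif Write every model to mmCIF and re-read it, so the
#'   parser sits in the loop (coordinates then carry the format's
#'   3-decimal rounding).
#' @return List with `models` (named [structure_model()]s, reference
#'   entry "REF"), `comparisons` (for [compare_complexes()]), and
#'   `targets` ([published_targets()] with entry names remapped to the
#'   suite's).
#' @export
synthetic_target_suite <- function(seed = 1, via_mmcif = FALSE) {
  ref <- make_decamer_fixture(seed = seed, entry_id = "REF")
  asg <- attr(ref, "assignment")
  delta1 <- role_chains(asg, "eIF2B_delta", "unit1")
  beta1 <- role_chains(asg, "eIF2B_beta", "unit1")
  unit2 <- asg$chain[asg$protomer %in% "unit2"]
  bset <- resolve_selection(ref, asg, selection_spec("eIF2B_beta"),
                            "unit1")
  bc <- colMeans(as.matrix(bset$atoms[, c("x", "y", "z")]))

  helix_motion <- function(disp, rot, away, id)
    motion_for_metrics(ref, chains = delta1, resno = 247:267,
                       displacement_A = disp, rotation_deg = rot,
                       id = id, away = away, toward_point = bc)
  models <- list(REF = ref)
  add <- function(name, motions) {
    pr <- perturb_fixture(ref, motions)
    pr$model$entry_id <- name
    models[[name]] <<- pr$model
  }
  add("APG", list(helix_motion(3.2, 7.9, TRUE, "da3")))   # two trimers
  add("AP2", list(helix_motion(2.8, 8.1, TRUE, "da3")))   # alpha-only x2
  add("PROD", list(helix_motion(1.1, 2.3, FALSE, "da3"))) # productive
  add("ISOAP", list(helix_motion(2.4, 0, TRUE, "da3")))   # isolated aP
  add("AP1", list(helix_motion(0.6, 0, TRUE, "da3")))     # one trimer
  # beta alignment RMSD: deform the non-frame half of one beta copy;
  # rmsd over the 40-residue chain is t/sqrt(2)
  add("BRMSD", list(list(id = "bshift", chains = beta1, resno = 1:20,
                         shift = c(0.7 * sqrt(2), 0, 0))))
  # pocket separations: translate the whole second tetramer unit
  add("POCKL", list(list(id = "sep", chains = unit2,
                         shift = c(2.2, 0, 0))))
  add("POCKM", list(list(id = "sep", chains = unit2,
                         shift = c(0.4, 0, 0))))
  add("POCKS", list(list(id = "sep", chains = unit2,
                         shift = c(0.3, 0, 0))))

  if (via_mmcif) {
    models <- lapply(models, function(m) {
      path <- tempfile(fileext = ".cif")
      write_mmcif(m, path)
      m2 <- load_structure(path, entry_id = m$entry_id)
      unlink(path)
      annotate_structure(m2, fixture_references())
    })
  }

  remap <- c("7D43" = "APG", "7D44" = "AP2", "6O81" = "PROD",
             "6O9Z" = "ISOAP", "7D45" = "AP1", "7D46" = "REF",
             "6CAJ" = "REF")
  tg <- published_targets()
  frame <- fixture_frame_spec()
  probe <- fixture_probe_spec()
  beta <- selection_spec("eIF2B_beta")
  comparisons <- lapply(seq_len(nrow(tg)), function(i) {
    type <- tg$metric[i]
    target <- switch(tg$id[i],
      apo_vs_aPg_beta_rmsd = "BRMSD",
      isrib_vs_aPg_pocket = "POCKL",
      isrib_vs_aP1_pocket = "POCKM",
      apo_vs_isrib_pocket = "POCKS",
      remap[[tg$target[i]]])
    cmp <- list(id = tg$id[i], ref = "REF", target = target, type = type)
    if (type %in% c("displacement", "rotation")) {
      cmp$frame <- frame; cmp$probe <- probe
    } else if (type == "probe_rmsd") {
      cmp$frame <- frame; cmp$probe <- beta
    } else {
      cmp$shell_ref <- "REF"; cmp$frame_unit <- "unit1"
    }
    cmp
  })
  list(models = models, comparisons = comparisons, targets = tg)
}
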