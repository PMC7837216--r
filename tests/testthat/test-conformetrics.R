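# superposition, helix geometry, and the structural metrics

test_that("superposition recovers known transforms exactly", {
  set.seed(11)
  P <- random_cloud(12)
  s0 <- kabsch_superpose(P, P)
  expect_equal(s0$rmsd_fit, 0, tolerance = 1e-12)
  expect_equal(s0$transform$R, diag(3), tolerance = 1e-9)
  R <- rotation_about_axis(c(0, 0, 1), 25)
  Q <- sweep(P %*% R, 2, -c(1, 2, 3))
  s <- kabsch_superpose(P, Q)
  expect_equal(s$rmsd_fit, 0, tolerance = 1e-10)
  expect_equal(s$transform$R, R, tolerance = 1e-9)
  # recovered angle is 25 degrees
  ang <- acos((sum(diag(s$transform$R)) - 1) / 2) * 180 / pi
  expect_equal(ang, 25, tolerance = 1e-9)
  expect_equal(apply_transform(P, s$transform), Q, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("degenerate alignments are refused", {
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)),
               "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "collinear")
})

test_that("superposition RMSD matches the quaternion oracle on random pairs", {
  set.seed(42)
  for (i in 1:100) {
    P <- random_cloud(10)
    Q <- transformed_cloud(P, noise_sd = stats::runif(1, 0, 2))
    expect_equal(kabsch_superpose(P, Q)$rmsd_fit, quaternion_rmsd(P, Q),
                 tolerance = 1e-8)
  }
})

test_that("helix axis is recovered for ideal and noisy helices", {
  H <- ideal_helix(21)
  g <- helix_axis(H)
  expect_equal(sqrt(sum(g$axis^2)), 1, tolerance = 1e-9)
  expect_lt(angle_between(g$axis, c(0, 0, 1)), 0.5)
  # rotated helix: axis follows
  R <- rotation_about_axis(c(1, 0, 0), 30)
  g2 <- helix_axis(H %*% R)
  expect_lt(angle_between(g2$axis, as.numeric(c(0, 0, 1) %*% R)), 0.5)
  # N->C orientation: reversing the trace flips the axis
  g3 <- helix_axis(H[21:1, ])
  expect_gt(angle_between(g$axis, g3$axis), 179)
  expect_error(helix_axis(H[1:6, ]), "insufficient")
  # noisy replicates stay within 2 degrees of the generator axis
  set.seed(9)
  errs <- replicate(100, {
    angle_between(helix_axis(H + matrix(rnorm(63, 0, 0.3), 21, 3))$axis,
                  c(0, 0, 1))
  })
  expect_lt(max(errs), 2)
})

test_that("self-comparison yields zero displacement and rotation", {
  m <- make_decamer_fixture(seed = 5)
  md <- mean_displacement(m, m, fixture_frame_spec(), fixture_probe_spec())
  expect_equal(unname(md$per_protomer), c(0, 0), tolerance = 1e-9)
  ar <- axis_rotation(m, m, fixture_frame_spec(), fixture_probe_spec())
  expect_equal(unname(ar$per_protomer), c(0, 0), tolerance = 1e-6)
  expect_true(all(ar$direction == "n/a"))
  pd <- pocket_displacement(m, m, frame_unit = "unit1")
  expect_equal(pd$displacement, 0, tolerance = 1e-9)
})

test_that("injected probe translations and rotations are recovered", {
  m <- make_decamer_fixture(seed = 1)
  delta1 <- role_chains(attr(m, "assignment"), "eIF2B_delta", "unit1")
  for (t_A in c(0.5, 1, 2, 4)) {
    mo <- motion_for_metrics(m, chains = delta1, resno = 247:267,
                             displacement_A = t_A, id = "t")
    pr <- perturb_fixture(m, list(mo))
    md <- mean_displacement(m, pr$model, fixture_frame_spec(),
                            fixture_probe_spec())
    u <- pr$ledger$id
    expect_equal(md$per_protomer[["unit1"]], t_A, tolerance = 1e-6)
    expect_equal(md$per_protomer[["unit1"]],
                 pr$ledger$expected_mean_displacement, tolerance = 1e-6)
  }
  for (theta in c(2, 8, 15)) {
    mo <- motion_for_metrics(m, chains = delta1, resno = 247:267,
                             displacement_A = 10, rotation_deg = theta,
                             id = "r")
    pr <- perturb_fixture(m, list(mo))
    ar <- axis_rotation(m, pr$model, fixture_frame_spec(),
                        fixture_probe_spec())
    expect_equal(ar$per_protomer[["unit1"]], theta, tolerance = 1e-6)
    expect_equal(ar$per_protomer[["unit1"]],
                 pr$ledger$expected_axis_rotation, tolerance = 1e-6)
  }
})

test_that("direction labels follow the imposed motion relative to beta", {
  m <- make_decamer_fixture(seed = 1)
  asg <- attr(m, "assignment")
  delta1 <- role_chains(asg, "eIF2B_delta", "unit1")
  beta1 <- resolve_selection(m, asg, selection_spec("eIF2B_beta"), "unit1")
  bc <- colMeans(as.matrix(beta1$atoms[, c("x", "y", "z")]))
  for (away in c(TRUE, FALSE)) {
    mo <- motion_for_metrics(m, chains = delta1, resno = 247:267,
                             displacement_A = 3, rotation_deg = 8,
                             away = away, toward_point = bc)
    pr <- perturb_fixture(m, list(mo))
    ar <- axis_rotation(m, pr$model, fixture_frame_spec(),
                        fixture_probe_spec())
    expect_equal(ar$direction[["unit1"]],
                 if (away) "away_from_beta" else "toward_beta")
  }
})

test_that("metrics are invariant under a global rigid motion of the target", {
  m <- make_decamer_fixture(seed = 6)
  mo <- motion_for_metrics(m, chains = role_chains(attr(m, "assignment"),
                                                   "eIF2B_delta", "unit1"),
                           resno = 247:267, displacement_A = 2.5,
                           rotation_deg = 5)
  pr <- perturb_fixture(m, list(mo))
  tr <- rigid_transform(rotation_about_axis(c(2, -1, 4), 123),
                        c(30, -12, 7))
  moved <- transform_model(pr$model, tr)
  attr(moved, "assignment") <- attr(pr$model, "assignment")
  md1 <- mean_displacement(m, pr$model, fixture_frame_spec(),
                           fixture_probe_spec())
  md2 <- mean_displacement(m, moved, fixture_frame_spec(),
                           fixture_probe_spec())
  expect_equal(md1$per_protomer, md2$per_protomer, tolerance = 1e-6)
  ar1 <- axis_rotation(m, pr$model, fixture_frame_spec(),
                       fixture_probe_spec())
  ar2 <- axis_rotation(m, moved, fixture_frame_spec(),
                       fixture_probe_spec())
  expect_equal(ar1$per_protomer, ar2$per_protomer, tolerance = 1e-6)
  pd1 <- pocket_displacement(m, pr$model, frame_unit = "unit1")
  pd2 <- pocket_displacement(m, moved, shell_ref = m,
                             frame_unit = "unit1",
                             ref_asg = attr(m, "assignment"),
                             target_asg = attr(moved, "assignment"),
                             shell_ref_asg = attr(m, "assignment"))
  expect_equal(pd1$displacement, pd2$displacement, tolerance = 1e-6)
})

test_that("pocket metric reports the separation of the two half-shells", {
  m <- make_decamer_fixture(seed = 1)
  asg <- attr(m, "assignment")
  unit2 <- asg$chain[asg$protomer %in% "unit2"]
  pr <- perturb_fixture(m, list(list(id = "sep", chains = unit2,
                                     shift = c(1.5, 0, 0))))
  # alignment on either unit sees the same relative motion
  for (fu in c("unit1", "unit2")) {
    pd <- pocket_displacement(m, pr$model, shell_ref = m, frame_unit = fu)
    expect_equal(pd$displacement, 1.5, tolerance = 1e-6)
  }
})

test_that("batch comparisons produce one report row each and survive failures", {
  m <- make_decamer_fixture(seed = 1)
  mo <- motion_for_metrics(m, chains = role_chains(attr(m, "assignment"),
                                                   "eIF2B_delta", "unit1"),
                           resno = 247:267, displacement_A = 3.2,
                           rotation_deg = 7.9)
  pr <- perturb_fixture(m, list(mo))
  models <- list(apo = m, holo = pr$model)
  cfg <- list(
    list(id = "self", ref = "apo", target = "apo", type = "displacement",
         frame = fixture_frame_spec(), probe = fixture_probe_spec()),
    list(id = "disp", ref = "apo", target = "holo",
         type = "displacement", frame = fixture_frame_spec(),
         probe = fixture_probe_spec()),
    list(id = "rot", ref = "apo", target = "holo", type = "rotation",
         frame = fixture_frame_spec(), probe = fixture_probe_spec()),
    list(id = "broken", ref = "apo", target = "missing",
         type = "displacement", frame = fixture_frame_spec(),
         probe = fixture_probe_spec()))
  rep <- compare_complexes(models, cfg)
  expect_equal(nrow(rep), 4)
  expect_equal(rep$mean[rep$id == "self"], 0, tolerance = 1e-9)
  expect_equal(rep$unit1[rep$id == "disp"], 3.2, tolerance = 1e-6)
  expect_equal(rep$unit1[rep$id == "rot"], 7.9, tolerance = 1e-6)
  expect_match(rep$error[rep$id == "broken"], "not loaded")
  expect_true(all(is.na(rep$error[rep$id != "broken"])))
})
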