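#' Synthetic decamer fixtures with a known motion ledger
#'
#' Download-free validation of the structural pipeline uses a toy
#' two-protomer assembly: ten "subunit" chains built from ideal
#' alpha-helices placed with two-fold pseudo-symmetry, a delta chain
#' that carries an "alpha3" helix at residues 247-267, and a dummy
#' ligand at the protomer interface standing in for ISRIB.  The
#' geometry is deliberately non-physical - it exercises parsing,
#' assignment, selection, superposition and metric code, not biology.
#' [perturb_fixture()] applies rigid motions to named chain groups and
#' records the *analytically expected* metric values in a motion
#' ledger, against which the measurement pipeline can be closed.
#'
#' @name synthetic_structures
NULL

# evaluate expr with a local RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# ideal alpha-helix C-alpha trace: rise 1.5 A, 100 deg twist, radius 2.3 A,
# axis +z from the origin
.ideal_helix <- function(n, phase = 0) {
  i <- seq_len(n) - 1
  ang <- (phase + 100 * i) * pi / 180
  cbind(x = 2.3 * cos(ang), y = 2.3 * sin(ang), z = 1.5 * i)
}

#' Generate an ideal helix along an arbitrary axis
#'
#' @param n Number of residues (C-alpha positions).
#' @param origin Start point (length 3, Angstrom).
#' @param dir Axis direction (length 3; normalized internally).
#' @param phase Helical phase offset in degrees.
#' @return n x 3 coordinate matrix.
#' @export
ideal_helix <- function(n, origin = c(0, 0, 0), dir = c(0, 0, 1),
                        phase = 0) {
  H <- .ideal_helix(n, phase)
  d <- dir / sqrt(sum(dir^2))
  z <- c(0, 0, 1)
  R <- if (max(abs(d - z)) < 1e-12) diag(3)
  else if (max(abs(d + z)) < 1e-12) rotation_about_axis(c(1, 0, 0), 180)
  else rotation_about_axis(pracma_cross(z, d),
                           acos(sum(z * d)) * 180 / pi)
  sweep(H %*% t(R), 2, -as.numeric(origin))
}

pracma_cross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

# per-role synthetic sequences; fixed internal seed so the library is
# stable across fixture seeds
.role_sequence <- function(role, n) {
  idx <- match(role, EIF2B_ROLES)
  with_seed(5000 + idx, paste(sample(.AA1, n, replace = TRUE),
                              collapse = ""))
}

# chain blueprints for one protomer (unit2 is a 180 deg rotation about z)
.FIXTURE_PLAN <- list(
  list(role = "eIF2B_beta",  chain = "A", resno = 1:40,
       origin = c(6, -4, -4), dir = c(0.6, 0.8, -0.3), phase = 0),
  list(role = "eIF2B_delta", chain = "B",
       segments = list(list(resno = 240:270, origin = c(5, 5, 0),
                            dir = c(0.25, 1, 0.3), phase = 30),
                       list(resno = 275:300, origin = c(16, 26, 6),
                            dir = c(1, 0.3, -0.2), phase = 60))),
  list(role = "eIF2B_gamma", chain = "C", resno = 1:30,
       origin = c(25, -15, 10), dir = c(1, -0.5, 0.5), phase = 90),
  list(role = "eIF2B_eps",   chain = "D", resno = 1:30,
       origin = c(30, 10, -10), dir = c(0.5, 1, -0.5), phase = 120)
)

.ALPHA_PLAN <- list(role = "eIF2B_alpha", resno = 1:25,
                    origin = c(14, 28, 18), dir = c(1, 0.2, 0.2),
                    phase = 45)

#' Build the synthetic two-protomer decamer fixture
#'
#' Ten polymer chains (A-J) plus a five-atom dummy ligand ("ISR",
#' chain X) at the protomer interface.  The seed draws a random global
#' rigid placement of the whole assembly, so different seeds give
#' different coordinates but identical topology and internal geometry.
#'
#' @param seed Integer seed for the global placement (default 1).
#' @param entry_id Identifier for the fixture model.
#' @return A [structure_model()] with the fixture's subunit assignment
#'   pre-attached (`attr(, "assignment")`).
#' @export
make_decamer_fixture <- function(seed = 1, entry_id = "SYNTH1") {
  chains <- list()
  add_chain <- function(chain, role, segments) {
    seqlen <- sum(vapply(segments, function(s) length(s$resno),
                         integer(1)))
    sq <- strsplit(.role_sequence(role, seqlen), "")[[1]]
    pos <- 0L
    rows <- lapply(segments, function(s) {
      X <- ideal_helix(length(s$resno), s$origin, s$dir, s$phase)
      aa <- sq[pos + seq_along(s$resno)]
      pos <<- pos + length(s$resno)
      data.frame(type = "ATOM", chain = chain,
                 resid = bio3d::aa123(aa), resno = s$resno,
                 label_resno = s$resno - min(s$resno) + 1L, elety = "CA",
                 x = X[, 1], y = X[, 2], z = X[, 3])
    })
    do.call(rbind, rows)
  }
  unit1 <- lapply(.FIXTURE_PLAN, function(p) {
    segs <- if (!is.null(p$segments)) p$segments
    else list(list(resno = p$resno, origin = p$origin, dir = p$dir,
                   phase = p$phase))
    add_chain(p$chain, p$role, segs)
  })
  flip <- rotation_about_axis(c(0, 0, 1), 180)
  unit2 <- lapply(seq_along(unit1), function(i) {
    df <- unit1[[i]]
    df$chain <- c(A = "E", B = "F", C = "G", D = "H")[df$chain]
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(flip)
    df[, c("x", "y", "z")] <- xyz
    df
  })
  a1 <- add_chain("I", "eIF2B_alpha",
                  list(list(resno = .ALPHA_PLAN$resno,
                            origin = .ALPHA_PLAN$origin,
                            dir = .ALPHA_PLAN$dir,
                            phase = .ALPHA_PLAN$phase)))
  a2 <- a1
  a2$chain <- "J"
  a2[, c("x", "y", "z")] <-
    as.matrix(a1[, c("x", "y", "z")]) %*% t(flip)
  lig <- data.frame(type = "HETATM", chain = "X", resid = "ISR",
                    resno = 501L, label_resno = NA_integer_,
                    elety = paste0("C", 1:5),
                    x = c(0, 1, -1, 0, 0), y = c(0, 0, 0, 1, -1),
                    z = c(0, 0.5, 0.5, -0.5, -0.5))
  atoms <- do.call(rbind, c(unit1, unit2, list(a1, a2, lig)))
  # seeded global placement: random rotation + translation
  tr <- with_seed(seed, {
    ax <- stats::rnorm(3)
    rigid_transform(rotation_about_axis(ax, stats::runif(1, 0, 360)),
                    stats::runif(3, -10, 10))
  })
  xyz <- apply_transform(as.matrix(atoms[, c("x", "y", "z")]), tr)
  atoms[, c("x", "y", "z")] <- xyz
  m <- structure_model(entry_id, atoms)
  attr(m, "assignment") <- assign_subunits(m, fixture_references())
  m
}

#' Reference sequence library of the synthetic fixture
#' @return Named list of one-letter sequences per role.
#' @export
fixture_references <- function() {
  lens <- c(eIF2B_alpha = 25L, eIF2B_beta = 40L, eIF2B_gamma = 30L,
            eIF2B_delta = 57L, eIF2B_eps = 30L)
  stats::setNames(lapply(names(lens), function(r)
    .role_sequence(r, lens[[r]])), names(lens))
}

#' Default alignment frame of the fixture: the "C-terminal domains" of
#' beta (residues 21-40) and delta (residues 275-300) in both protomers
#' @return A [selection_spec()].
#' @export
fixture_frame_spec <- function()
  selection_spec(role = c("eIF2B_beta", "eIF2B_delta"),
                 resno = list(eIF2B_beta = 21:40, eIF2B_delta = 275:300))

#' The fixture's delta "alpha3" probe helix (residues 247-267)
#' @return A [selection_spec()].
#' @export
fixture_probe_spec <- function()
  selection_spec(role = "eIF2B_delta", resno = 247:267)

#' Apply rigid motions to chain groups and record the expected metrics
#'
#' Each motion acts on a group of chains (optionally restricted to a
#' residue range) as `x' = (x - center) %*% R + center + shift`.  The
#' returned ledger holds, per motion, the analytically expected mean
#' C-alpha displacement of the group (closed-form mean of
#' `|R(x-c)+c+shift-x|` over group atoms) and, when the group is a
#' single helix of >= 7 residues, the expected axis rotation (the angle
#' between the group's helix axis and its image under R) - computed
#' from the injected transform and the generator's own coordinates,
#' never from a structure comparison.
#'
#' @param model A [structure_model()] (typically [make_decamer_fixture()]).
#' @param motions List of motions; each a list with `id`, `chains`,
#'   optional `resno`, optional `R` (3x3 rotation), optional `center`
#'   (default: group C-alpha centroid), optional `shift` (length 3).
#' @return List with `model` (perturbed, assignment re-attached) and
#'   `ledger` (data.frame: id, n_atoms, translation, rotation_deg,
#'   expected_mean_displacement, expected_axis_rotation).
#' @export
perturb_fixture <- function(model, motions) {
  seen <- character(0)
  led <- list()
  for (mo in motions) {
    if (is.null(mo$chains)) stop("motion must name chains")
    sel <- model$atoms$chain %in% mo$chains
    if (!any(sel)) stop("motion references absent chains: ",
                        paste(mo$chains, collapse = ","))
    if (!is.null(mo$resno)) sel <- sel & model$atoms$resno %in% mo$resno
    keys <- paste(model$atoms$chain[sel], model$atoms$resno[sel],
                  model$atoms$elety[sel])
    if (any(keys %in% seen))
      stop("specification error: motion groups overlap")
    seen <- c(seen, keys)
    X <- as.matrix(model$atoms[sel, c("x", "y", "z")])
    R <- if (is.null(mo$R)) diag(3) else mo$R
    ca <- sel & model$atoms$elety == "CA"
    Xca <- as.matrix(model$atoms[ca, c("x", "y", "z")])
    center <- if (is.null(mo$center)) colMeans(Xca) else mo$center
    shift <- if (is.null(mo$shift)) c(0, 0, 0) else mo$shift
    tr <- transform_about_center(R, center, shift)
    Xnew <- apply_transform(X, tr)
    model$atoms[sel, c("x", "y", "z")] <- Xnew
    # analytic expectations over the group's C-alpha atoms
    disp <- mean(sqrt(rowSums((apply_transform(Xca, tr) - Xca)^2)))
    ang <- rot_deg <- NA_real_
    if (!identical(R, diag(3))) {
      rot_deg <- acos(min(1, max(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
      if (nrow(Xca) >= 7 && length(unique(model$atoms$chain[ca])) == 1) {
        ax <- helix_axis(Xca)$axis
        ang <- angle_between(ax, as.numeric(ax %*% R))
      }
    }
    led[[length(led) + 1L]] <- data.frame(
      id = if (is.null(mo$id)) paste(mo$chains, collapse = "+") else mo$id,
      n_atoms = nrow(Xca), translation = sqrt(sum(shift^2)),
      rotation_deg = rot_deg,
      expected_mean_displacement = disp,
      expected_axis_rotation = ang)
  }
  attr(model, "assignment") <- assign_subunits(model, fixture_references())
  list(model = model, ledger = do.call(rbind, led))
}

#' Build a motion that yields prescribed displacement and rotation
#'
#' Constructs a rigid motion of a helix group whose *measured* metrics
#' equal the requested values exactly: the helix is tilted by
#' `rotation_deg` about an axis through its centroid chosen
#' perpendicular to the helix axis, then translated along that tilt
#' axis; because the tilt axis is perpendicular to every rotational
#' displacement, the per-atom displacement is
#' `sqrt(t^2 + |(R-I)(x-c)|^2)` and the translation magnitude `t`
#' solving `mean = displacement_A` is found by bisection.  Returns NULL
#' geometry errors if the rotation alone already displaces the group
#' more than requested.
#'
#' @param model Fixture model.
#' @param chains,resno Group definition (e.g. the delta alpha3 helix).
#' @param displacement_A Target mean C-alpha displacement (Angstrom).
#' @param rotation_deg Target helix-axis rotation (degrees; 0 for pure
#'   translation).
#' @param id Motion id.
#' @param away From the group centroid, translate away from (TRUE) or
#'   toward (FALSE) the origin-side reference point `toward_point`;
#'   used to set the direction label of the motion.
#' @param toward_point Reference point for the sign convention (default:
#'   centroid of the same-model eIF2B beta C-alphas of the group's
#'   protomer is not needed here; any point works since only the sign
#'   along the tilt axis changes).
#' @return A motion list suitable for [perturb_fixture()].
#' @export
motion_for_metrics <- function(model, chains, resno = NULL,
                               displacement_A = 0, rotation_deg = 0,
                               id = "motion", away = TRUE,
                               toward_point = c(0, 0, 0)) {
  sel <- model$atoms$chain %in% chains & model$atoms$elety == "CA"
  if (!is.null(resno)) sel <- sel & model$atoms$resno %in% resno
  Xca <- as.matrix(model$atoms[sel, c("x", "y", "z")])
  center <- colMeans(Xca)
  if (rotation_deg == 0) {
    dirv <- center - toward_point
    dirv <- dirv / sqrt(sum(dirv^2))
    if (!away) dirv <- -dirv
    return(list(id = id, chains = chains, resno = resno, R = NULL,
                center = center, shift = displacement_A * dirv))
  }
  ax <- helix_axis(Xca)$axis
  # tilt axis: perpendicular to the helix axis and maximally aligned
  # with the centroid -> toward_point direction, so that translating
  # along it moves the group cleanly toward/away from the reference
  dirv <- center - toward_point
  u <- dirv - sum(dirv * ax) * ax
  if (sqrt(sum(u^2)) < 1e-6) {
    refv <- if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- pracma_cross(ax, refv)
  }
  u <- u / sqrt(sum(u^2))
  if (!away) u <- -u
  R <- rotation_about_axis(u, rotation_deg)
  drot <- sqrt(rowSums((sweep(Xca, 2, center) %*% R -
                          sweep(Xca, 2, center))^2))
  base <- mean(drot)
  if (displacement_A < base)
    stop("infeasible: rotation alone displaces the group ",
         sprintf("%.2f", base), " A on average, more than the ",
         "requested ", displacement_A, " A")
  t_mag <- if (displacement_A == base) 0 else
    stats::uniroot(function(t) mean(sqrt(t^2 + drot^2)) - displacement_A,
                   c(0, displacement_A + 1), tol = 1e-12)$root
  list(id = id, chains = chains, resno = resno, R = R, center = center,
       shift = t_mag * u)
}
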