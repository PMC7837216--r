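#' Equilibrium linkage model of ISRIB / eIF2(alphaP) antagonism
#'
#' eIF2B carries one central ISRIB site and two symmetry-related
#' regulatory sites for phosphorylated eIF2.  The occupancy states are
#' indexed (i, j) with i in {0,1} ISRIB molecules and j in {0,1,2}
#' eIF2(alphaP) molecules bound.  Each state's statistical weight is a
#' term of the binding polynomial:
#'
#'   w(i, j) = (K_I * I)^i * B_j(P) * g1^(i * \[j==1\]) * g2^(i * \[j==2\])
#'
#' with B_0 = 1, B_1 = 2 * K_P1 * P (factor 2 for the two equivalent
#' sites), and B_2 = K_P1 * K_P2 * c_P * P^2.  Coupling factors g1, g2
#' below 1 encode antagonism between ISRIB and one or two bound
#' eIF2(alphaP); c_P above 1 encodes positive cooperativity between the
#' two regulatory sites.  Fractional populations are the normalized
#' weights; GEF activity is the population-weighted sum of per-state
#' activities (ground state = 1).  The kinetic parameters of this
#' antagonism have not been measured, so defaults are illustrative,
#' not fitted.
#'
#' @name allostery
NULL

#' Linkage-model parameters
#'
#' @param K_I ISRIB association constant, per nM (default 0.1, i.e.
#'   Kd 10 nM, the reported affinity scale of ISRIB for eIF2B).
#' @param K_P1,K_P2 Association constants of the first and second
#'   eIF2(alphaP) regulatory sites, per uM (default 4, Kd 0.25 uM).
#' @param c_P Cooperativity factor between the two alphaP sites
#'   (unitless; > 1 = positive; default 20).
#' @param g1,g2 Coupling factors of ISRIB with one / two bound alphaP
#'   (unitless; < 1 = antagonism; defaults 0.5 and 0.01; whether the
#'   doubly-inhibited ISRIB-bound state is rare or strictly forbidden is
#'   an open question, corresponding to small-g2 versus g2 = 0).
#' @param activity Named activities of states ground, I, II, III, IV
#'   (relative GEF activity; ground must be 1; all in \[0, 1\]).  The
#'   ISRIB-only state shares the ground-state activity.
#' @return A `linkage_parameters` list.
#' @export
linkage_parameters <- function(K_I = 0.1, K_P1 = 4, K_P2 = 4, c_P = 20,
                               g1 = 0.5, g2 = 0.01,
                               activity = c(ground = 1, I = 0.5,
                                            II = 0.05, III = 0.5,
                                            IV = 0.05)) {
  for (v in c(K_I = K_I, K_P1 = K_P1, K_P2 = K_P2, c_P = c_P, g1 = g1))
    if (!is.finite(v) || v <= 0)
      stop("all equilibrium constants and couplings must be > 0")
  if (!is.finite(g2) || g2 < 0) stop("g2 must be >= 0")
  need <- c("ground", "I", "II", "III", "IV")
  if (!all(need %in% names(activity)))
    stop("activity must name states ", paste(need, collapse = ", "))
  if (activity[["ground"]] != 1) stop("a_ground must equal 1")
  if (any(activity < 0 | activity > 1)) stop("activities must lie in [0,1]")
  structure(list(K_I = K_I, K_P1 = K_P1, K_P2 = K_P2, c_P = c_P,
                 g1 = g1, g2 = g2, activity = activity[need]),
            class = "linkage_parameters")
}

# the 6 occupancy states in fixed order
.STATES <- data.frame(
  state = c("ground", "I_isrib", "I", "III", "II", "IV"),
  i = c(0L, 1L, 0L, 1L, 0L, 1L),
  j = c(0L, 0L, 1L, 1L, 2L, 2L))

#' Fractional state populations at given free ligand concentrations
#'
#' @param p A [linkage_parameters()] set.
#' @param isrib_nM Free ISRIB concentration (nM, >= 0).
#' @param alphaP_uM Free eIF2(alphaP) concentration (uM, >= 0);
#'   ligand depletion is ignored (probe concentrations are far below
#'   Kd in the assays this emulates).
#' @return A `species_distribution`: data.frame with columns `state`,
#'   `i` (ISRIB bound), `j` (alphaP bound), `population` (sums to 1).
#' @export
species_distribution <- function(p, isrib_nM, alphaP_uM) {
  stopifnot(inherits(p, "linkage_parameters"))
  if (isrib_nM < 0 || alphaP_uM < 0)
    stop("concentrations must be >= 0")
  w <- .state_weights(p, isrib_nM, alphaP_uM)
  out <- .STATES
  out$population <- w / sum(w)
  class(out) <- c("species_distribution", "data.frame")
  out
}

.state_weights <- function(p, I, P) {
  B <- c(1, 2 * p$K_P1 * P, p$K_P1 * p$K_P2 * p$c_P * P^2)
  g <- c(1, p$g1, p$g2)
  vapply(seq_len(nrow(.STATES)), function(k) {
    i <- .STATES$i[k]; j <- .STATES$j[k]
    (p$K_I * I)^i * B[j + 1] * (if (i == 1) g[j + 1] else 1)
  }, numeric(1))
}

#' Fraction of eIF2B with ISRIB bound
#' @inheritParams species_distribution
#' @return Scalar in \[0, 1\].
#' @export
isrib_occupancy <- function(p, isrib_nM, alphaP_uM) {
  d <- species_distribution(p, isrib_nM, alphaP_uM)
  sum(d$population[d$i == 1])
}

#' Simulated competition curve: ISRIB occupancy versus \[alphaP\]
#'
#' Emulates the steady-state fluorescence-polarization competition
#' readout: at fixed probe ISRIB concentration, increasing eIF2(alphaP)
#' displaces ISRIB through the allosteric coupling.  The returned trace
#' (fraction ISRIB-bound vs log10 alphaP) can be fitted downstream with
#' the four-parameter logistic model to give an apparent IC50 and Hill
#' slope.
#'
#' @param p A [linkage_parameters()] set.
#' @param probe_isrib_nM Probe ISRIB concentration (nM).
#' @param alphaP_uM Titration of alphaP concentrations (uM, >= 6 points).
#' @return A [kinetic_trace()] with `x` = log10(alphaP, uM) and `y` =
#'   fraction ISRIB-bound; a `flat_curve` flag is attached when no
#'   transition occurs in range.
#' @export
competition_curve <- function(p, probe_isrib_nM = 2.5,
                              alphaP_uM = 10^seq(-3, 1.5, length.out = 12)) {
  if (length(alphaP_uM) < 6)
    stop("titration needs >= 6 points spanning the transition")
  alphaP_uM <- sort(alphaP_uM)
  y <- vapply(alphaP_uM, function(P)
    isrib_occupancy(p, probe_isrib_nM, P), numeric(1))
  tr <- kinetic_trace(log10(alphaP_uM), y, x_unit = "log10(uM)",
                      y_unit = "fraction bound",
                      meta = list(probe_isrib_nM = probe_isrib_nM))
  if (diff(range(y)) < 0.05 * max(y, 1e-12))
    attr(tr, "flags") <- "flat_curve"
  tr
}

#' Desensitized ("ISR-insensitive mutant") parameter transform
#'
#' Models eIF2B delta-subunit mutations that weaken eIF2(alphaP) binding
#' at the regulatory sites while leaving ISRIB affinity unchanged:
#' both alphaP association constants are divided by the desensitization
#' factor `d`.
#'
#' @param p A [linkage_parameters()] set.
#' @param d Desensitization factor (> 0; d = 1 is the identity;
#'   d > 1 weakens alphaP binding).
#' @return Transformed `linkage_parameters`.
#' @export
mutant_transform <- function(p, d) {
  stopifnot(inherits(p, "linkage_parameters"))
  if (!is.finite(d) || d <= 0) stop("desensitization factor d must be > 0")
  linkage_parameters(K_I = p$K_I, K_P1 = p$K_P1 / d, K_P2 = p$K_P2 / d,
                     c_P = p$c_P, g1 = p$g1, g2 = p$g2,
                     activity = p$activity)
}

#' Relative GEF activity at given ligand concentrations
#'
#' Population-weighted mean of per-state activities; 1 with no ligands.
#'
#' @inheritParams species_distribution
#' @return Scalar in \[0, 1\].
#' @export
gef_activity <- function(p, isrib_nM, alphaP_uM) {
  d <- species_distribution(p, isrib_nM, alphaP_uM)
  a <- p$activity
  amap <- c(ground = a[["ground"]], I_isrib = a[["ground"]], I = a[["I"]],
            III = a[["III"]], II = a[["II"]], IV = a[["IV"]])
  sum(d$population * amap[d$state])
}

#' Quasi-equilibrium phosphorylation time course
#'
#' Emulates introducing an eIF2alpha kinase at t = 0: the phosphorylated
#' pool grows as \[alphaP\](t) = total * (1 - exp(-k_phos * t)), and at
#' each time the binding equilibrium is assumed fast relative to
#' phosphorylation, so the probe signal is the instantaneous fraction of
#' ISRIB-bound eIF2B.
#'
#' @param p A [linkage_parameters()] set.
#' @param k_phos Kinase rate constant, per minute (>= 0).
#' @param total_eIF2_uM Total eIF2 pool (uM).
#' @param probe_isrib_nM Probe ISRIB concentration (nM).
#' @param times_min Time grid in minutes.
#' @return A [kinetic_trace()] of fraction ISRIB-bound versus time.
#' @export
phosphorylation_timecourse <- function(p, k_phos, total_eIF2_uM = 0.6,
                                       probe_isrib_nM = 2.5,
                                       times_min = seq(0, 60,
                                                       length.out = 61)) {
  if (k_phos < 0) stop("k_phos must be >= 0")
  aP <- total_eIF2_uM * (1 - exp(-k_phos * times_min))
  y <- vapply(aP, function(P) isrib_occupancy(p, probe_isrib_nM, P),
              numeric(1))
  kinetic_trace(times_min, y, x_unit = "min", y_unit = "fraction bound",
                meta = list(k_phos = k_phos,
                            total_eIF2_uM = total_eIF2_uM))
}

#' Depletion-aware species distribution
#'
#' Solves the conservation equations for free ligand concentrations by
#' bisection when probe or receptor depletion cannot be neglected, then
#' evaluates [species_distribution()] at the free concentrations.
#'
#' @param p A [linkage_parameters()] set.
#' @param total_isrib_nM,total_alphaP_uM Total ligand concentrations.
#' @param eIF2B_nM Total eIF2B concentration (nM).
#' @return A `species_distribution` with attributes `free_isrib_nM`,
#'   `free_alphaP_uM`.
#' @export
species_distribution_depleted <- function(p, total_isrib_nM,
                                          total_alphaP_uM, eIF2B_nM) {
  stopifnot(inherits(p, "linkage_parameters"))
  bound_I <- function(I_free, P_free)
    eIF2B_nM * {
      w <- .state_weights(p, I_free, P_free)
      sum(w[.STATES$i == 1]) / sum(w)
    }
  bound_P_uM <- function(I_free, P_free)
    (eIF2B_nM / 1000) * {
      w <- .state_weights(p, I_free, P_free)
      sum(w * .STATES$j) / sum(w)
    }
  I_free <- total_isrib_nM; P_free <- total_alphaP_uM
  for (iter in 1:200) {
    I_new <- if (total_isrib_nM == 0) 0 else
      stats::uniroot(function(I) I + bound_I(I, P_free) - total_isrib_nM,
                     c(0, total_isrib_nM), tol = 1e-12)$root
    P_new <- if (total_alphaP_uM == 0) 0 else
      stats::uniroot(function(P) P + bound_P_uM(I_new, P) - total_alphaP_uM,
                     c(0, total_alphaP_uM), tol = 1e-12)$root
    if (abs(I_new - I_free) < 1e-10 && abs(P_new - P_free) < 1e-10) {
      I_free <- I_new; P_free <- P_new
      break
    }
    I_free <- I_new; P_free <- P_new
  }
  d <- species_distribution(p, I_free, P_free)
  attr(d, "free_isrib_nM") <- I_free
  attr(d, "free_alphaP_uM") <- P_free
  d
}
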