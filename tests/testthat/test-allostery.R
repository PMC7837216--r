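# the equilibrium linkage model of ISRIB / eIF2(alphaP) antagonism

# direct enumeration oracle: rebuild the six unnormalized state weights
# from first principles, independently of the package's vectorized path
enumerate_populations <- function(p, I, P) {
  w <- c()
  for (i in 0:1) for (j in 0:2) {
    Bj <- switch(j + 1, 1, 2 * p$K_P1 * P, p$K_P1 * p$K_P2 * p$c_P * P^2)
    gij <- if (i == 1 && j == 1) p$g1 else if (i == 1 && j == 2) p$g2
           else 1
    w <- c(w, stats::setNames((p$K_I * I)^i * Bj * gij,
                              paste0("i", i, "j", j)))
  }
  w / sum(w)
}

test_that("parameter validation enforces the model's domain", {
  expect_error(linkage_parameters(K_I = 0), "> 0")
  expect_error(linkage_parameters(g2 = -0.1), "g2")
  expect_error(linkage_parameters(activity = c(ground = 0.9, I = 1,
                                               II = 0, III = 0, IV = 0)),
               "a_ground")
  p <- linkage_parameters()
  expect_error(species_distribution(p, -1, 0), ">= 0")
  expect_error(mutant_transform(p, 0), "d must be > 0")
})

test_that("populations are a probability distribution at all inputs", {
  set.seed(21)
  for (i in 1:50) {
    p <- linkage_parameters(K_I = runif(1, 0.001, 1),
                            K_P1 = runif(1, 0.1, 50),
                            K_P2 = runif(1, 0.1, 50),
                            c_P = runif(1, 0.05, 100),
                            g1 = runif(1, 0.01, 2),
                            g2 = runif(1, 0, 2))
    I <- runif(1, 0, 1000); P <- runif(1, 0, 100)
    d <- species_distribution(p, I, P)
    expect_true(all(d$population >= 0))
    expect_equal(sum(d$population), 1, tolerance = 1e-9)
    # matches the brute-force enumeration oracle
    ref <- enumerate_populations(p, I, P)
    expect_equal(unname(d$population[order(d$i, d$j)]),
                 unname(ref[order(names(ref))]), tolerance = 1e-12)
  }
})

test_that("zero ligand leaves the complex entirely in the ground state", {
  d <- species_distribution(linkage_parameters(), 0, 0)
  expect_equal(d$population[d$state == "ground"], 1)
  expect_equal(gef_activity(linkage_parameters(), 0, 0), 1)
})

test_that("with all couplings 1 ISRIB occupancy factorizes exactly", {
  p <- linkage_parameters(g1 = 1, g2 = 1, c_P = 1)
  for (I in c(0, 1, 5, 50)) for (P in c(0, 0.1, 1, 10)) {
    expect_equal(isrib_occupancy(p, I, P),
                 p$K_I * I / (1 + p$K_I * I), tolerance = 1e-12)
  }
  # and the competition curve is flat
  cc <- competition_curve(p, 2.5)
  expect_identical(attr(cc, "flags"), "flat_curve")
})

test_that("state weights are path-independent (detailed balance)", {
  p <- linkage_parameters()
  for (I in c(1, 20)) for (P in c(0.1, 2)) {
    # factorization order 1: fill the two alphaP sites stepwise (the
    # statistical factor 2 of the first binding cancels against the 1/2
    # double-counting of the second), then add ISRIB with coupling g2
    w_state_IV_a <- (2 * p$K_P1 * P) * (p$K_P2 * p$c_P * P / 2) *
      (p$K_I * I) * p$g2
    # factorization order 2: bind ISRIB first, then the two alphaP
    w_state_IV_b <- (p$K_I * I) * (2 * p$K_P1 * P) *
      (p$K_P2 * p$c_P * P / 2) * p$g2
    expect_equal(w_state_IV_a, w_state_IV_b, tolerance = 1e-12)
    d <- species_distribution(p, I, P)
    expect_equal(d$population[d$state == "IV"] /
                   d$population[d$state == "ground"],
                 w_state_IV_a, tolerance = 1e-9)
  }
})

test_that("strong second-site antagonism steepens the competition curve", {
  p <- linkage_parameters(g1 = 0.5, g2 = 0.001, c_P = 20)
  cc <- competition_curve(p, 2.5, 10^seq(-3, 1.5, length.out = 16))
  fit <- fit_model("fourpl_inhibition", cc)
  expect_gt(abs(fit$estimate[["HillSlope"]]), 1.5)
  # but never above 2 (+ numerical slack): only two alphaP sites exist
  expect_lt(abs(fit$estimate[["HillSlope"]]), 2.05)
  # weak coupling difference gives a shallower, near-hyperbolic curve
  p0 <- linkage_parameters(g1 = 0.5, g2 = 0.25, c_P = 1)
  f0 <- fit_model("fourpl_inhibition",
                  competition_curve(p0, 2.5,
                                    10^seq(-3, 3, length.out = 16)))
  expect_lt(abs(f0$estimate[["HillSlope"]]), 1.2)
})

test_that("raising alphaP affinity lowers the apparent IC50 monotonically", {
  base <- linkage_parameters()
  ic50 <- vapply(c(1, 10), function(f) {
    p <- linkage_parameters(K_P1 = base$K_P1 * f, K_P2 = base$K_P2 * f)
    fit_model("fourpl_inhibition",
              competition_curve(p, 2.5,
                                10^seq(-4, 2, length.out = 16)))$
      derived$IC50
  }, numeric(1))
  expect_gt(ic50[1] / ic50[2], 5)
  expect_lt(ic50[1] / ic50[2], 20)
})

test_that("the desensitized mutant right-shifts the competition curve", {
  p <- linkage_parameters()
  expect_equal(mutant_transform(p, 1), p)
  grid <- 10^seq(-3, 3, length.out = 16)
  ic_wt <- fit_model("fourpl_inhibition",
                     competition_curve(p, 2.5, grid))$derived$IC50
  ic_mut <- fit_model("fourpl_inhibition",
                      competition_curve(mutant_transform(p, 10), 2.5,
                                        grid))$derived$IC50
  expect_gt(ic_mut / ic_wt, 5)
  # extreme desensitization abolishes the transition in range
  flat <- competition_curve(mutant_transform(p, 1e8), 2.5, grid)
  expect_identical(attr(flat, "flags"), "flat_curve")
})

test_that("GEF activity reflects the antagonistic allostery", {
  p <- linkage_parameters()
  # saturating alphaP drives activity to the strongly inhibited state's
  expect_equal(gef_activity(p, 0, 1e7), p$activity[["II"]],
               tolerance = 1e-4)
  # ISRIB raises activity at sub-saturating alphaP when g2 << g1
  a_no <- gef_activity(p, 0, 0.3)
  a_isrib <- gef_activity(p, 500, 0.3)
  expect_gt(a_isrib, a_no)
})

test_that("phosphorylation time courses decay and are slowed by the mutant", {
  p <- linkage_parameters()
  flat <- phosphorylation_timecourse(p, k_phos = 0)
  expect_equal(diff(range(flat$y)), 0, tolerance = 1e-12)
  wt <- phosphorylation_timecourse(p, k_phos = 0.1)
  expect_true(all(diff(wt$y) <= 1e-12))       # monotone decay
  mut <- phosphorylation_timecourse(mutant_transform(p, 30),
                                    k_phos = 0.1)
  expect_true(all(mut$y >= wt$y - 1e-12))     # shallower everywhere
  expect_gt(mut$y[length(mut$y)], wt$y[length(wt$y)] + 0.05)
})

test_that("the depletion-aware solver conserves mass and matches the
          no-depletion limit at trace receptor concentration", {
  p <- linkage_parameters()
  d <- species_distribution_depleted(p, total_isrib_nM = 20,
                                     total_alphaP_uM = 1, eIF2B_nM = 1e-6)
  d0 <- species_distribution(p, 20, 1)
  expect_equal(d$population, d0$population, tolerance = 1e-6)
  # with appreciable receptor, free ligand is depleted
  d2 <- species_distribution_depleted(p, 20, 1, eIF2B_nM = 50)
  expect_lt(attr(d2, "free_isrib_nM"), 20)
  expect_equal(sum(d2$population), 1, tolerance = 1e-9)
})
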