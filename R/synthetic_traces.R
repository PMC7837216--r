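#' Simulated signal traces from the printed regression models
#'
#' Generates noisy traces Y = model(X; true parameters) + N(0, sigma)
#' with a seeded generator, recording the generating model, parameters,
#' noise level and seed in a trace ledger so fits can be checked
#' against ground truth.  Regeneration with the same seed is
#' bit-identical, and the global RNG state is left untouched.
#'
#' @param model Model id (see [model_ids()]).
#' @param params Named true parameter vector for the model.
#' @param X X grid (time, concentration, or log10 concentration for
#'   `fourpl_inhibition`).
#' @param sigma Gaussian noise standard deviation in Y units (0 gives
#'   the noiseless curve, identical to [evaluate_model()]).
#' @param seed Integer seed.
#' @param replicate Replicate id recorded in the trace.
#' @param x_unit,y_unit Units recorded in the trace.
#' @return A [kinetic_trace()] with attribute `ledger` (a `trace_ledger`
#'   list: model, params, sigma, seed).
#' @export
simulate_trace <- function(model, params, X, sigma = 0, seed = 1,
                           replicate = 1L, x_unit = "min",
                           y_unit = "AU") {
  mu <- evaluate_model(model, params, X)
  y <- if (sigma > 0)
    mu + with_seed(seed, stats::rnorm(length(X), 0, sigma))
  else mu
  tr <- kinetic_trace(X, y, replicate = replicate, x_unit = x_unit,
                      y_unit = y_unit)
  attr(tr, "ledger") <- structure(
    list(model = model, params = unlist(params), sigma = sigma,
         seed = seed),
    class = "trace_ledger")
  tr
}

#' Simulate a dose series of biphasic dissociation traces
#'
#' Emulates the BLI experiment in which dissociation is measured at a
#' range of ISRIB concentrations and the fast-phase fraction
#' (PercentFast) grows hyperbolically with concentration: for each
#' concentration, PercentFast is set from the agonist-response curve
#' (Bottom to Top with the given EC50) and a noisy two-phase decay
#' trace is generated.
#'
#' @param concentrations Agonist concentrations (nM).
#' @param ec50,bottom,top Agonist-response truth: EC50 (nM) and the
#'   PercentFast plateaus (%).
#' @param decay Named parameters shared by all traces: Y0, Plateau,
#'   KFast, KSlow.
#' @param X Time grid (minutes).
#' @param sigma Noise SD in signal units.
#' @param seed Integer seed (one sub-seed per concentration).
#' @return List with `traces` (list of [kinetic_trace()]), `truth`
#'   (data.frame concentration, PercentFast), and the generating
#'   parameters.
#' @export
simulate_percent_fast_series <- function(concentrations,
                                         ec50 = 1.8, bottom = 50,
                                         top = 75,
                                         decay = c(Y0 = 1, Plateau = 0.2,
                                                   KFast = 2,
                                                   KSlow = 0.1),
                                         X = seq(0, 30, by = 0.25),
                                         sigma = 0, seed = 1) {
  pf <- evaluate_model("agonist_response",
                       c(Bottom = bottom, Top = top, EC50 = ec50),
                       concentrations)
  traces <- lapply(seq_along(concentrations), function(i) {
    simulate_trace("two_phase_decay",
                   c(decay, PercentFast = pf[i]), X, sigma,
                   seed = seed * 1000L + i, y_unit = "nm")
  })
  list(traces = traces,
       truth = data.frame(concentration = concentrations,
                          PercentFast = pf),
       params = list(ec50 = ec50, bottom = bottom, top = top,
                     decay = decay, sigma = sigma, seed = seed))
}
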