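#' Regression models for nucleotide-exchange and ligand-binding assays
#'
#' The seven standard models used to analyse the fluorescence-based
#' nucleotide exchange assay, fluorescence-polarization ISRIB binding,
#' and biolayer-interferometry (BLI) association/dissociation traces:
#'
#' * `one_phase_decay`: Y = (Y0 - Plateau) * exp(-K*X) + Plateau
#' * `one_site_total`: Y = Bmax*X/(Kd+X) + NS*X + Background
#' * `fourpl_inhibition` (log\[inhibitor\] vs response, variable slope):
#'   Y = Bottom + (Top-Bottom) / (1 + 10^((LogIC50 - X)*HillSlope))
#' * `two_phase_association`: SpanFast = (Plateau-Y0)*PercentFast*.01,
#'   SpanSlow = (Plateau-Y0)*(100-PercentFast)*.01,
#'   Y = Y0 + SpanFast*(1-exp(-KFast*X)) + SpanSlow*(1-exp(-KSlow*X))
#' * `two_phase_decay`: SpanFast = (Y0-Plateau)*PercentFast*.01,
#'   SpanSlow = (Y0-Plateau)*(100-PercentFast)*.01,
#'   Y = Plateau + SpanFast*exp(-KFast*X) + SpanSlow*exp(-KSlow*X)
#' * `one_site_specific` (Hill slope = 1): Y = Bmax*X/(Kd + X)
#' * `agonist_response` (Hill slope = 1):
#'   Y = Bottom + X*(Top-Bottom)/(EC50 + X)
#'
#' X is time (typically minutes) for the kinetic models, concentration
#' for the binding models, and log10(concentration) for
#' `fourpl_inhibition`.  K rate constants are in reciprocal X units.
#'
#' @name binding_models
NULL

.MODELS <- list(
  one_phase_decay = list(
    params = c("Y0", "Plateau", "K"),
    fn = function(p, X) (p[["Y0"]] - p[["Plateau"]]) * exp(-p[["K"]] * X) +
      p[["Plateau"]],
    lower = c(Y0 = -Inf, Plateau = -Inf, K = 1e-9),
    rate = "K"),
  one_site_total = list(
    params = c("Bmax", "Kd", "NS", "Background"),
    fn = function(p, X) p[["Bmax"]] * X / (p[["Kd"]] + X) +
      p[["NS"]] * X + p[["Background"]],
    lower = c(Bmax = 0, Kd = 1e-6, NS = -Inf, Background = -Inf)),
  fourpl_inhibition = list(
    params = c("Bottom", "Top", "LogIC50", "HillSlope"),
    fn = function(p, X) p[["Bottom"]] + (p[["Top"]] - p[["Bottom"]]) /
      (1 + 10^((p[["LogIC50"]] - X) * p[["HillSlope"]])),
    lower = c(Bottom = -Inf, Top = -Inf, LogIC50 = -Inf, HillSlope = -Inf)),
  two_phase_association = list(
    params = c("Y0", "Plateau", "KFast", "KSlow", "PercentFast"),
    fn = function(p, X) {
      span_fast <- (p[["Plateau"]] - p[["Y0"]]) * p[["PercentFast"]] * .01
      span_slow <- (p[["Plateau"]] - p[["Y0"]]) *
        (100 - p[["PercentFast"]]) * .01
      p[["Y0"]] + span_fast * (1 - exp(-p[["KFast"]] * X)) +
        span_slow * (1 - exp(-p[["KSlow"]] * X))
    },
    lower = c(Y0 = -Inf, Plateau = -Inf, KFast = 1e-9, KSlow = 1e-9,
              PercentFast = 0),
    upper = c(Y0 = Inf, Plateau = Inf, KFast = Inf, KSlow = Inf,
              PercentFast = 100)),
  two_phase_decay = list(
    params = c("Y0", "Plateau", "KFast", "KSlow", "PercentFast"),
    fn = function(p, X) {
      span_fast <- (p[["Y0"]] - p[["Plateau"]]) * p[["PercentFast"]] * .01
      span_slow <- (p[["Y0"]] - p[["Plateau"]]) *
        (100 - p[["PercentFast"]]) * .01
      p[["Plateau"]] + span_fast * exp(-p[["KFast"]] * X) +
        span_slow * exp(-p[["KSlow"]] * X)
    },
    lower = c(Y0 = -Inf, Plateau = -Inf, KFast = 1e-9, KSlow = 1e-9,
              PercentFast = 0),
    upper = c(Y0 = Inf, Plateau = Inf, KFast = Inf, KSlow = Inf,
              PercentFast = 100)),
  one_site_specific = list(
    params = c("Bmax", "Kd"),
    fn = function(p, X) p[["Bmax"]] * X / (p[["Kd"]] + X),
    lower = c(Bmax = 0, Kd = 1e-6)),
  agonist_response = list(
    params = c("Bottom", "Top", "EC50"),
    fn = function(p, X) p[["Bottom"]] + X * (p[["Top"]] - p[["Bottom"]]) /
      (p[["EC50"]] + X),
    lower = c(Bottom = -Inf, Top = -Inf, EC50 = 1e-6))
)

#' Names of the available regression models
#' @return Character vector of model ids.
#' @export
model_ids <- function() names(.MODELS)

#' Parameter names of a model
#' @param model Model id (see [model_ids()]).
#' @return Character vector of parameter names.
#' @export
model_params <- function(model) .model(model)$params

.model <- function(model) {
  m <- .MODELS[[model]]
  if (is.null(m)) stop("unknown model: ", model)
  m
}

#' Evaluate a regression model pointwise
#'
#' @param model Model id.
#' @param params Named numeric vector or list with every parameter of the
#'   model.
#' @param X Numeric vector (time, concentration, or log10 concentration
#'   for `fourpl_inhibition`).
#' @return Numeric Y values.
#' @export
evaluate_model <- function(model, params, X) {
  m <- .model(model)
  params <- unlist(params)
  miss <- setdiff(m$params, names(params))
  if (length(miss))
    stop("missing parameter(s) for ", model, ": ",
         paste(miss, collapse = ", "))
  if (model %in% c("one_site_total", "one_site_specific",
                   "agonist_response") && any(X < 0))
    stop("concentration X must be >= 0 for ", model)
  if (model %in% c("one_site_total", "one_site_specific") &&
      any(params[["Kd"]] + X == 0))
    stop("domain error: Kd + X = 0")
  m$fn(as.list(params), X)
}

#' Construct a kinetic/equilibrium trace
#'
#' @param X Numeric x values (strictly increasing within a replicate).
#' @param Y Numeric signal values.
#' @param replicate Replicate id (recycled).
#' @param x_unit,y_unit Unit strings (e.g. "min", "mP", "nm", "nM").
#' @param meta Optional named list (entity, condition, ...).
#' @return A `kinetic_trace` data.frame with attributes.
#' @export
kinetic_trace <- function(X, Y, replicate = 1L, x_unit = "min",
                          y_unit = "AU", meta = list()) {
  if (length(X) != length(Y)) stop("X and Y lengths differ")
  df <- data.frame(x = X, y = Y, replicate = replicate)
  for (r in unique(df$replicate)) {
    xs <- df$x[df$replicate == r]
    if (any(diff(xs) <= 0))
      stop("X must be strictly increasing within replicate ", r)
  }
  attr(df, "x_unit") <- x_unit
  attr(df, "y_unit") <- y_unit
  attr(df, "meta") <- meta
  class(df) <- c("kinetic_trace", "data.frame")
  df
}

#' Read / write traces as CSV
#'
#' CSV with header `x,y,replicate` plus unit columns `x_unit`,`y_unit`
#' (constant), the on-disk format shared by the simulator and the
#' fitting functions.
#'
#' @param path File path.
#' @return A `kinetic_trace` (for read).
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  kinetic_trace(df$x, df$y,
                replicate = if ("replicate" %in% names(df)) df$replicate
                            else 1L,
                x_unit = if ("x_unit" %in% names(df)) df$x_unit[1] else "min",
                y_unit = if ("y_unit" %in% names(df)) df$y_unit[1] else "AU")
}

#' @rdname read_trace
#' @param trace A `kinetic_trace`.
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  df$x_unit <- attr(trace, "x_unit")
  df$y_unit <- attr(trace, "y_unit")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# data-driven starting values, per model
.init_params <- function(model, X, Y) {
  y0 <- Y[which.min(X)]; yn <- Y[which.max(X)]
  span <- max(Y) - min(Y)
  rng <- diff(range(X))
  k0 <- {
    # log-linearized decay rate from first/last thirds of the trace
    n <- length(X)
    i1 <- seq_len(max(2, floor(n / 3)))
    i2 <- seq(n - max(2, floor(n / 3)) + 1, n)
    m1 <- mean(Y[i1]); m2 <- mean(Y[i2])
    dy <- abs(m1 - m2)
    if (dy > 0 && rng > 0) max(1e-3, -log(max(0.05, 1 - dy /
      max(span, 1e-12))) / (rng / 2)) else 1 / max(rng, 1)
  }
  switch(model,
    one_phase_decay = c(Y0 = y0, Plateau = yn, K = k0),
    one_site_total = c(Bmax = span, Kd = stats::median(X[X > 0]),
                       NS = 0, Background = min(Y)),
    fourpl_inhibition = c(Bottom = min(Y), Top = max(Y),
                          LogIC50 = X[which.min(abs(Y - (max(Y) +
                            min(Y)) / 2))],
                          HillSlope = 1),
    two_phase_association = c(Y0 = y0, Plateau = yn, KFast = 3 * k0,
                              KSlow = k0 / 3, PercentFast = 50),
    two_phase_decay = c(Y0 = y0, Plateau = yn, KFast = 3 * k0,
                        KSlow = k0 / 3, PercentFast = 50),
    one_site_specific = c(Bmax = max(Y),
                          Kd = stats::median(X[X > 0])),
    agonist_response = c(Bottom = y0, Top = yn,
                         EC50 = stats::median(X[X > 0])))
}

#' Fit a regression model to a trace
#'
#' Nonlinear least squares (Levenberg-Marquardt via
#' `minpack.lm::nlsLM`) with data-driven starting values and
#' `n_restarts` jittered restarts, keeping the best-converged fit.
#' 95% confidence intervals are t-based on the asymptotic standard
#' errors from the parameter covariance at the optimum.  For the
#' biphasic models the fast/slow labels are normalized so that
#' KFast >= KSlow.
#'
#' @param model Model id (see [model_ids()]).
#' @param trace A [kinetic_trace()], or anything with `x` and `y`
#'   columns.
#' @param window Optional X interval `c(min, max)` restricting the fit
#'   (e.g. the first minutes of a dissociation).
#' @param n_restarts Jittered restarts (default 5).
#' @param log10_x For `fourpl_inhibition`: set TRUE if the trace X is a
#'   linear concentration that must be log10-transformed first.
#' @return A `fit_result`: list with `model`, `estimate` (named),
#'   `se`, `ci` (2-column matrix), `r_squared`, `residuals`, `fitted`,
#'   `converged`, `flags`, `n`, and `derived` (e.g. `half_life`,
#'   `IC50`).
#' @export
fit_model <- function(model, trace, window = NULL, n_restarts = 5,
                      log10_x = FALSE) {
  m <- .model(model)
  df <- as.data.frame(trace)[, c("x", "y")]
  if (log10_x) {
    if (model != "fourpl_inhibition")
      stop("log10_x only applies to fourpl_inhibition")
    df <- df[df$x > 0, ]
    df$x <- log10(df$x)
  }
  if (!is.null(window)) df <- df[df$x >= window[1] & df$x <= window[2], ]
  df <- df[order(df$x), ]
  X <- df$x; Y <- df$y
  npar <- length(m$params)
  if (length(X) < npar + 2)
    stop("need at least ", npar + 2, " points to fit ", model)
  start0 <- .init_params(model, X, Y)
  lower <- m$lower[m$params]
  upper <- if (!is.null(m$upper)) m$upper[m$params]
           else rep(Inf, npar)
  fnw <- function(x, ...) {
    p <- list(...)
    names(p) <- m$params
    m$fn(p, x)
  }
  form <- stats::as.formula(
    paste("y ~ fnw(x,", paste(m$params, collapse = ", "), ")"),
    env = environment())
  best <- NULL
  set_seedless_jitter <- function(i, p) {
    if (i == 1) return(p)
    # deterministic jitter pattern, no RNG side effects
    f <- 1 + 0.5 * sin(seq_along(p) * i * 1.7)
    pmin(pmax(p * f + 1e-6 * (i - 1), lower + 1e-12), upper - 1e-12)
  }
  for (i in seq_len(n_restarts)) {
    st <- set_seedless_jitter(i, start0)
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        form, data = data.frame(x = X, y = Y),
        start = as.list(st), lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      s <- sum(stats::residuals(fit)^2)
      if (is.null(best) || s < best$ssq) best <- list(fit = fit, ssq = s)
    }
  }
  if (is.null(best))
    stop("fit-failure: ", model, " did not converge after ", n_restarts,
         " restarts (n = ", length(X), ")")
  fit <- best$fit
  est <- stats::coef(fit)
  # biphasic label convention: KFast >= KSlow
  if (model %in% c("two_phase_association", "two_phase_decay") &&
      est[["KFast"]] < est[["KSlow"]]) {
    est[c("KFast", "KSlow")] <- est[c("KSlow", "KFast")]
    est[["PercentFast"]] <- 100 - est[["PercentFast"]]
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        form, data = data.frame(x = X, y = Y), start = as.list(est),
        lower = lower, upper = upper)),
      error = function(e) fit)
    est <- stats::coef(fit)
  }
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    rep(NA_real_, npar))
  dof <- length(X) - npar
  tq <- stats::qt(0.975, max(dof, 1))
  ci <- cbind(lower = est - tq * se, upper = est + tq * se)
  fitted <- m$fn(as.list(est), X)
  resid <- Y - fitted
  sst <- sum((Y - mean(Y))^2)
  r2 <- if (sst > 0) 1 - sum(resid^2) / sst else NA_real_
  flags <- character(0)
  if (!is.na(r2) && r2 < 0) flags <- c(flags, "negative_r_squared")
  if (sst == 0) flags <- c(flags, "degenerate_flat_data")
  derived <- list()
  if (!is.null(m$rate)) {
    derived$half_life <- log(2) / est[[m$rate]]
    derived$half_life_ci <- sort(log(2) / ci[m$rate, ])
  }
  if (model == "fourpl_inhibition") {
    derived$IC50 <- 10^est[["LogIC50"]]
    derived$IC50_ci <- 10^ci["LogIC50", ]
  }
  if (model == "agonist_response") {
    derived$EC50 <- est[["EC50"]]
    derived$EC50_ci <- ci["EC50", ]
  }
  structure(list(model = model, estimate = est, se = se, ci = ci,
                 r_squared = r2, residuals = resid, fitted = fitted,
                 converged = TRUE, flags = flags, n = length(X),
                 derived = derived),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: %s (n = %d, R^2 = %.4f)\n", x$model, x$n,
              x$r_squared))
  tab <- data.frame(estimate = x$estimate, se = x$se,
                    ci_lower = x$ci[, 1], ci_upper = x$ci[, 2])
  print(round(tab, 5))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Half-life from a fitted single rate constant
#'
#' t1/2 = ln(2)/K, with the CI propagated from K's confidence interval.
#'
#' @param fit A `fit_result` from a model with a single rate `K`, or a
#'   bare positive rate constant.
#' @return List with `half_life` (in reciprocal-K units, e.g. minutes)
#'   and `ci` when available.
#' @export
half_life <- function(fit) {
  if (is.numeric(fit)) {
    if (fit <= 0) stop("undefined half-life: K must be > 0")
    return(list(half_life = log(2) / fit, ci = NULL))
  }
  stopifnot(inherits(fit, "fit_result"))
  if (!"K" %in% names(fit$estimate))
    stop("model ", fit$model, " has no single rate constant K")
  K <- fit$estimate[["K"]]
  if (K <= 0) stop("undefined half-life: K must be > 0")
  list(half_life = log(2) / K,
       ci = sort(log(2) / fit$ci["K", ]))
}

#' EC50 of %Fast versus agonist concentration
#'
#' Collects the PercentFast estimates of a series of biphasic
#' dissociation fits performed at different ISRIB concentrations and
#' fits the hyperbolic agonist-response model (Hill slope = 1),
#' returning the EC50 with its CI.
#'
#' @param fits List of `fit_result`s from `two_phase_decay` (or
#'   `two_phase_association`), one per concentration.
#' @param concentrations Numeric vector of agonist concentrations, same
#'   length as `fits`.
#' @return A `fit_result` for `agonist_response` over (concentration,
#'   PercentFast).
#' @export
percent_fast_dose_response <- function(fits, concentrations) {
  if (length(fits) != length(concentrations))
    stop("fits and concentrations lengths differ")
  if (length(fits) < 4) stop("need >= 4 concentrations")
  pf <- vapply(fits, function(f) {
    stopifnot(inherits(f, "fit_result"))
    if (!"PercentFast" %in% names(f$estimate))
      stop("fit has no PercentFast parameter (model ", f$model, ")")
    f$estimate[["PercentFast"]]
  }, numeric(1))
  if (any(pf < 0 | pf > 100))
    stop("PercentFast outside [0, 100] in input fits")
  if (stats::sd(pf) == 0) {
    res <- structure(list(model = "agonist_response",
                          estimate = c(Bottom = pf[1], Top = pf[1],
                                       EC50 = NA_real_),
                          se = rep(NA_real_, 3),
                          ci = matrix(NA_real_, 3, 2), r_squared = NA_real_,
                          residuals = rep(0, length(pf)), fitted = pf,
                          converged = FALSE,
                          flags = "degenerate_flat_dose_response",
                          n = length(pf), derived = list()),
                     class = "fit_result")
    return(res)
  }
  ord <- order(concentrations)
  tr <- kinetic_trace(concentrations[ord], pf[ord], x_unit = "nM",
                      y_unit = "%")
  fit_model("agonist_response", tr)
}
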