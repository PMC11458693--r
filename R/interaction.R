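#' Convert a mass concentration to molar
#'
#' `ug/mL -> uM` via `conc / molar_mass * 1000`.  The exact value is
#' returned; displays conventionally round half-even to 2 decimals
#' (e.g. 24 ug/mL of resveratrol, 228.25 g/mol -> 105.15 uM).
#'
#' @param conc Concentration in ug/mL (>= 0).
#' @param molar_mass Molar mass in g/mol (> 0).
#' @return Concentration in uM.
#' @export
mass_to_molar <- function(conc, molar_mass) {
  if (any(conc < 0)) stop("concentration must be >= 0", call. = FALSE)
  if (any(molar_mass <= 0)) stop("molar mass must be > 0", call. = FALSE)
  conc / molar_mass * 1000
}

#' Single-dose-pair combination measurement
#'
#' The three responses feeding the interaction models: `pa` and `pb` are
#' the responses to each single agent alone, `pab` the response to the
#' combination, all fractions in `[0, 1]` and all of the same kind —
#' `"viability"` (surviving fraction) or `"inhibition"` (killed
#' fraction).
#'
#' @param pa,pb,pab Response fractions in `[0, 1]`.
#' @param response_kind `"viability"` or `"inhibition"`.
#' @param labels Optional character vector describing drugs and doses.
#' @return An object of class `ir_combination`.
#' @export
combination_measurement <- function(pa, pb, pab,
                                    response_kind = c("inhibition",
                                                      "viability"),
                                    labels = NULL) {
  response_kind <- match.arg(response_kind)
  r <- c(pa, pb, pab)
  if (length(r) != 3L || any(r < 0) || any(r > 1))
    stop("pa, pb, pab must be scalars in [0, 1]", call. = FALSE)
  structure(list(pa = pa, pb = pb, pab = pab,
                 response_kind = response_kind, labels = labels),
            class = "ir_combination")
}

#' Complement a combination measurement
#'
#' Replaces each response by `1 - response` and flips the response kind
#' (viability <-> inhibition).  Applying it twice is the identity.
#'
#' @param m An `ir_combination`.
#' @return The complemented `ir_combination`.
#' @export
to_inhibition <- function(m) {
  stopifnot(inherits(m, "ir_combination"))
  kind <- if (m$response_kind == "viability") "inhibition" else "viability"
  combination_measurement(1 - m$pa, 1 - m$pb, 1 - m$pab, kind, m$labels)
}

interaction_result <- function(model, statistic, expected, call, tolerance) {
  structure(list(model = model, statistic = statistic, expected = expected,
                 call = call, tolerance = tolerance),
            class = "ir_interaction_result")
}

#' @export
print.ir_interaction_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g", x$model, x$statistic))
  if (!is.null(x$expected) && !is.na(x$expected))
    cat(sprintf(" (expected %.4g)", x$expected))
  cat(" ->", x$call, "\n")
  invisible(x)
}

#' Coefficient of drug interaction (additivity model)
#'
#' `CDI = P(a+b) / (Pa * Pb)`: the combined response over the product of
#' the single-agent responses.  `CDI < 1` is synergy, `CDI = 1`
#' additivity, `CDI > 1` antagonism; a tolerance band around 1 absorbs
#' assay noise in the boundary call.  The ratio is evaluated on the
#' response kind supplied — no silent rescaling or kind conversion is
#' performed, because the statistic is not invariant under
#' `p -> 1 - p`.
#'
#' @param m An `ir_combination` with `pa * pb > 0`.
#' @param tolerance Half-width of the additivity band around 1,
#'   default 0.05.
#' @return An `ir_interaction_result` with model `"additivity_cdi"`.
#' @export
cdi_additivity <- function(m, tolerance = 0.05) {
  stopifnot(inherits(m, "ir_combination"))
  if (m$pa * m$pb <= 0)
    stop("CDI undefined: Pa * Pb = 0", call. = FALSE)
  cdi <- m$pab / (m$pa * m$pb)
  call <- if (cdi < 1 - tolerance) "synergy"
  else if (cdi > 1 + tolerance) "antagonism"
  else "additivity"
  interaction_result("additivity_cdi", cdi, 1, call, tolerance)
}

#' Bliss statistical-independence model
#'
#' Under statistical independence of the two kill probabilities the
#' expected combined inhibition is `1 - (1 - Pa)(1 - Pb)`.  The Bliss
#' excess `P(a+b) - expected` is positive for synergy and negative for
#' antagonism; `|excess| <= tolerance` is called no-interaction.
#' Requires inhibition-kind responses; convert viability data with
#' [to_inhibition()].
#'
#' @param m An `ir_combination` of kind `"inhibition"`.
#' @param tolerance No-interaction band half-width, default 0.01.
#' @return An `ir_interaction_result` with model
#'   `"statistical_independence"`.
#' @export
bliss_independence <- function(m, tolerance = 0.01) {
  stopifnot(inherits(m, "ir_combination"))
  if (m$response_kind != "inhibition")
    stop("Bliss independence needs inhibition fractions; ",
         "convert with to_inhibition()", call. = FALSE)
  expected <- 1 - (1 - m$pa) * (1 - m$pb)
  excess <- m$pab - expected
  call <- if (excess > tolerance) "synergy"
  else if (excess < -tolerance) "antagonism"
  else "no-interaction"
  interaction_result("statistical_independence", excess, expected, call,
                     tolerance)
}

#' Highest-single-agent (pharmacological independence) model
#'
#' The combination is expected to do no better than the better single
#' agent: expected inhibition `max(Pa, Pb)`.  The HSA excess
#' `P(a+b) - max(Pa, Pb)` is positive for synergy, negative for
#' antagonism.  Requires inhibition-kind responses.
#'
#' @param m An `ir_combination` of kind `"inhibition"`.
#' @param tolerance No-interaction band half-width, default 0.01.
#' @return An `ir_interaction_result` with model
#'   `"pharmacological_independence"`.
#' @export
hsa_independence <- function(m, tolerance = 0.01) {
  stopifnot(inherits(m, "ir_combination"))
  if (m$response_kind != "inhibition")
    stop("HSA needs inhibition fractions; convert with to_inhibition()",
         call. = FALSE)
  expected <- max(m$pa, m$pb)
  excess <- m$pab - expected
  call <- if (excess > tolerance) "synergy"
  else if (excess < -tolerance) "antagonism"
  else "no-interaction"
  interaction_result("pharmacological_independence", excess, expected, call,
                     tolerance)
}

#' Three-model interaction report with majority consensus
#'
#' Runs all three interaction models on one dose-pair measurement: the
#' CDI ratio on the response kind supplied, and the Bliss and HSA models
#' on the inhibition kind (converting automatically when the input is
#' viability).  The consensus is the 2-of-3 majority call; when all three
#' calls differ the consensus is `"discordant"`.
#'
#' @param m An `ir_combination`.
#' @param cdi_tolerance,excess_tolerance Boundary tolerances passed to
#'   the individual models.
#' @return List with elements `additivity_cdi`,
#'   `statistical_independence`, `pharmacological_independence` (each an
#'   `ir_interaction_result`) and `consensus` (character).
#' @export
interaction_report <- function(m, cdi_tolerance = 0.05,
                               excess_tolerance = 0.01) {
  stopifnot(inherits(m, "ir_combination"))
  inh <- if (m$response_kind == "inhibition") m else to_inhibition(m)
  res <- list(
    additivity_cdi = cdi_additivity(m, cdi_tolerance),
    statistical_independence = bliss_independence(inh, excess_tolerance),
    pharmacological_independence = hsa_independence(inh, excess_tolerance))
  calls <- vapply(res, `[[`, "", "call")
  calls[calls %in% c("additivity", "no-interaction")] <- "no-interaction"
  tab <- sort(table(calls), decreasing = TRUE)
  res$consensus <- if (tab[1] >= 2L) names(tab)[1] else "discordant"
  res
}

#' Dose-response table
#'
#' Rows of (concentration, response fraction, replicate) for one drug,
#' as produced by a viability assay over a dilution series.
#'
#' @param concentration Doses (>= 0), in `unit`.
#' @param response Response fractions in `[0, 1]`.
#' @param replicate Replicate identifiers (default all 1).
#' @param unit Concentration unit label, `"ug/mL"` or `"uM"`.
#' @return A data.frame of class `ir_dose_response`.
#' @export
dose_response_table <- function(concentration, response,
                                replicate = 1L, unit = c("ug/mL", "uM")) {
  unit <- match.arg(unit)
  if (any(concentration < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (any(response < -0.25) || any(response > 1.25))
    stop("responses must be fractions (roughly in [0, 1])", call. = FALSE)
  df <- data.frame(concentration = concentration,
                   response = response,
                   replicate = rep_len(replicate, length(concentration)))
  attr(df, "unit") <- unit
  class(df) <- c("ir_dose_response", "data.frame")
  df
}

#' Four-parameter logistic IC50 fit
#'
#' Least-squares fit of the 4PL dose-response model
#' `response = bottom + (top - bottom) / (1 + (c / IC50)^hill)`
#' (responses falling with dose, e.g. viability), returning the relative
#' IC50 — the concentration at the inflection of the fitted curve.
#' Fitting is multi-start: a grid of Hill slopes `{0.5, 1, 2, 4}` (plus
#' optional seeded random restarts) with box constraints
#' `bottom in [0, 0.5]`, `top in [0.5, 1.1]`, keeping the start with the
#' smallest residual sum of squares.
#'
#' @param table An `ir_dose_response` with at least 4 distinct
#'   concentrations.
#' @param n_random_starts Extra random multi-starts, default 0.
#' @param seed Seed for the random starts.
#' @return List with `ic50` (in the table's unit), `hill`, `top`,
#'   `bottom`, `sse`, `residuals`, `unit` and `spearman_rho` (dose-response
#'   monotonicity; a warning is raised when `|rho| < 0.5`).
#' @export
fit_ic50_4pl <- function(table, n_random_starts = 0L, seed = 1L) {
  stopifnot(inherits(table, "ir_dose_response"))
  conc <- table$concentration
  resp <- table$response
  if (length(unique(conc)) < 4L)
    stop("IC50 fitting needs >= 4 distinct concentrations", call. = FALSE)
  if (stats::sd(resp) < 1e-8)
    stop("degenerate dose-response: responses are constant", call. = FALSE)
  rho <- suppressWarnings(
    stats::cor(conc, resp, method = "spearman"))
  if (is.na(rho) || abs(rho) < 0.5)
    warning("dose-response is weakly monotone (|spearman rho| < 0.5); ",
            "the IC50 may be unreliable")
  pos <- conc > 0
  lc_range <- range(log(conc[pos]))
  model <- function(par, c) {
    # par = (log_ic50, hill, top, bottom); c = 0 maps to the top plateau
    ratio <- ifelse(c > 0, exp(par[2] * (log(c) - par[1])), 0)
    par[4] + (par[3] - par[4]) / (1 + ratio)
  }
  lower <- c(lc_range[1] - 5, 0.1, 0.5, 0)
  upper <- c(lc_range[2] + 5, 10, 1.1, 0.5)
  starts <- lapply(c(0.5, 1, 2, 4), function(h)
    c(stats::median(log(conc[pos])), h, max(min(max(resp), 1.1), 0.5),
      min(max(min(resp), 0), 0.5)))
  if (n_random_starts > 0L) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
    starts <- c(starts, lapply(seq_len(n_random_starts), function(i)
      stats::runif(4, lower, upper)))
  }
  best <- NULL
  for (st in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = st,
      fn = function(par) resp - model(par, conc),
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse)
      best <- list(par = fit$par, sse = sse)
  }
  if (is.null(best))
    stop("4PL fit failed to converge from every start", call. = FALSE)
  par <- best$par
  list(ic50 = exp(par[1]), hill = par[2], top = par[3], bottom = par[4],
       sse = best$sse, residuals = resp - model(par, conc),
       unit = attr(table, "unit"), spearman_rho = rho)
}
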