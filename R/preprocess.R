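#' Preprocessing configuration
#'
#' Bundles the parameters of the standard single-cell FTIR preprocessing
#' chain: 9-point moving-average smoothing, linear automatic baseline
#' correction, Savitzky-Golay second differentiation, and Mie-scattering
#' EMSC.  Defaults follow common practice for spectra digitised at ~2 cm-1
#' spacing.
#'
#' @param smooth_points Odd moving-average width (points), default 9.
#' @param sg_window Odd Savitzky-Golay window (points), default 9.
#' @param sg_polyorder Savitzky-Golay polynomial order, default 3
#'   (must be >= 2, the derivative order, and < `sg_window`).
#' @param emsc_poly_order Polynomial order of the EMSC baseline terms,
#'   default 2.
#' @param emsc_n_mie_curves Number of van de Hulst extinction curves in the
#'   EMSC interferent basis (a diameter x index grid), default 9.
#' @param emsc_iterations EMSC passes; after each pass the corrected cohort
#'   mean becomes the new reference.  Default 1.
#' @param reference_choice Reference spectrum rule: `"cohort_mean"`
#'   (default) or `"explicit"` (supply `reference` to
#'   [emsc_mie_correct()]).
#' @return An object of class `ir_preprocess_config`.
#' @export
preprocess_config <- function(smooth_points = 9L, sg_window = 9L,
                              sg_polyorder = 3L, emsc_poly_order = 2L,
                              emsc_n_mie_curves = 9L, emsc_iterations = 1L,
                              reference_choice = c("cohort_mean", "explicit")) {
  reference_choice <- match.arg(reference_choice)
  if (smooth_points < 3L || smooth_points %% 2L == 0L)
    stop("smooth_points must be odd and >= 3", call. = FALSE)
  if (sg_window %% 2L == 0L || sg_polyorder < 2L || sg_window <= sg_polyorder)
    stop("need odd sg_window > sg_polyorder >= 2", call. = FALSE)
  if (emsc_poly_order < 0L || emsc_n_mie_curves < 0L || emsc_iterations < 1L)
    stop("invalid EMSC configuration", call. = FALSE)
  structure(
    list(smooth_points = as.integer(smooth_points),
         sg_window = as.integer(sg_window),
         sg_polyorder = as.integer(sg_polyorder), sg_deriv = 2L,
         emsc_poly_order = as.integer(emsc_poly_order),
         emsc_n_mie_curves = as.integer(emsc_n_mie_curves),
         emsc_iterations = as.integer(emsc_iterations),
         reference_choice = reference_choice),
    class = "ir_preprocess_config")
}

# Apply a column-wise kernel to either a single spectrum or a set,
# appending a provenance tag.
apply_columns <- function(x, fun, tag) {
  if (inherits(x, "ir_spectrum")) {
    out <- x
    out$absorbance <- fun(matrix(x$absorbance, ncol = 1), x$wavenumbers)[, 1]
    out$provenance <- c(x$provenance, tag)
    out
  } else if (inherits(x, "ir_spectrum_set")) {
    out <- x
    out$absorbance <- fun(x$absorbance, x$wavenumbers)
    dimnames(out$absorbance) <- list(NULL, x$cell_ids)
    out$provenance <- c(x$provenance, tag)
    out
  } else stop("expected an ir_spectrum or ir_spectrum_set", call. = FALSE)
}

#' Moving-average smoothing
#'
#' Centered moving average of odd width.  Near the edges the window
#' shrinks symmetrically (width `2*min(h, i-1, n-i) + 1`), so end points
#' are left unchanged and a constant spectrum maps to itself.
#'
#' @param x A `ir_spectrum` or `ir_spectrum_set`.
#' @param points Odd window width in points, default 9.
#' @return Smoothed object of the same class, provenance tag appended.
#' @export
smooth_spectra <- function(x, points = 9L) {
  n <- if (inherits(x, "ir_spectrum")) length(x$wavenumbers)
  else length(x$wavenumbers)
  if (points %% 2L == 0L || points < 3L || points >= n)
    stop("smoothing window must be odd, >= 3 and smaller than the grid",
         call. = FALSE)
  h <- (points - 1L) %/% 2L
  apply_columns(x, function(m, wn) {
    nr <- nrow(m)
    cs <- apply(m, 2L, function(col) cumsum(c(0, col)))
    out <- m
    for (i in seq_len(nr)) {
      hi <- min(h, i - 1L, nr - i)
      out[i, ] <- (cs[i + hi + 1L, ] - cs[i - hi, ]) / (2L * hi + 1L)
    }
    out
  }, sprintf("smooth[%d]", points))
}

#' Linear automatic baseline correction
#'
#' Subtracts the straight line through two anchor points: the minimum of
#' the first and of the last 5% of the grid.  Anchor selection and
#' subtraction are iterated to a fixed point (almost always reached in one
#' or two passes), at which both end-segment minima are exactly zero; the
#' operation is therefore exactly idempotent and removes any purely linear
#' baseline completely.
#'
#' @param x A `ir_spectrum` or `ir_spectrum_set`.
#' @param anchor_fraction Fraction of the grid at each end searched for
#'   the anchor minimum, default 0.05.
#' @return Baseline-corrected object, provenance tag appended.
#' @export
baseline_linear <- function(x, anchor_fraction = 0.05) {
  apply_columns(x, function(m, wn) {
    n <- nrow(m)
    seg <- max(2L, round(anchor_fraction * n))
    lo_idx <- seq_len(seg)
    hi_idx <- seq(n - seg + 1L, n)
    for (j in seq_len(ncol(m))) {
      y <- m[, j]
      for (it in 1:50) {
        i1 <- lo_idx[which.min(y[lo_idx])]
        i2 <- hi_idx[which.min(y[hi_idx])]
        slope <- (y[i2] - y[i1]) / (wn[i2] - wn[i1])
        line <- y[i1] + slope * (wn - wn[i1])
        if (max(abs(line)) == 0) break
        y <- y - line
      }
      m[, j] <- y
    }
    m
  }, "baseline_linear")
}

#' Savitzky-Golay second derivative
#'
#' Second derivative with respect to wavenumber by local least-squares
#' polynomial (Savitzky-Golay) filtering, scaled by the grid spacing so
#' the result is in absorbance units per cm^2 and independent of the
#' digital point spacing.  Edge points come from the one-sided polynomial
#' fits of the Savitzky-Golay projection matrix.  Absorption band maxima
#' in the input become sharp negative minima in the output.
#'
#' @param x A `ir_spectrum` or `ir_spectrum_set`.
#' @param window Odd window width in points, default 9.
#' @param polyorder Polynomial order, default 3 (>= 2, < window).
#' @return Differentiated object, provenance tag `"second_derivative"`.
#' @export
second_derivative <- function(x, window = 9L, polyorder = 3L) {
  if (window %% 2L == 0L || polyorder < 2L || window <= polyorder)
    stop("need odd window > polyorder >= 2", call. = FALSE)
  apply_columns(x, function(m, wn) {
    dw <- abs(stats::median(diff(wn)))
    apply(m, 2L, function(col)
      signal::sgolayfilt(col, p = polyorder, n = window, m = 2L, ts = dw))
  }, sprintf("second_derivative[%d,%d]", window, polyorder))
}

# van de Hulst interferent basis: curves over a diameter x index grid,
# each normalised to unit max absolute value.
mie_basis <- function(grid, n_curves) {
  if (n_curves < 1L) return(NULL)
  k <- ceiling(sqrt(n_curves))
  ds <- seq(5, 20, length.out = k)
  ns <- seq(1.2, 1.45, length.out = ceiling(n_curves / k))
  combos <- expand.grid(d = ds, n = ns)[seq_len(n_curves), , drop = FALSE]
  vapply(seq_len(nrow(combos)), function(i)
    mie_artifact(grid, 1, combos$d[i], combos$n[i]),
    numeric(length(grid)))
}

#' Mie-scattering extended multiplicative signal correction
#'
#' Removes multiplicative scaling, polynomial baselines and Mie-type
#' scattering baselines by regressing each cell's spectrum on a design
#' matrix of the reference spectrum, polynomial terms, and a grid of van
#' de Hulst extinction curves.  The corrected spectrum is
#' `(raw - fitted interferents) / b`, where `b` is the fitted reference
#' coefficient.  With `iterations > 1` the corrected cohort mean replaces
#' the reference between passes.  The interferent basis uses the
#' non-resonant van de Hulst curve family; peak positions, which drive the
#' downstream feature matrix, are preserved.
#'
#' @param set A `ir_spectrum_set` with at least 2 cells (for the
#'   cohort-mean reference) or an explicit `reference`.
#' @param config A [preprocess_config()].
#' @param reference Optional explicit reference spectrum (numeric vector on
#'   the set grid); required when `config$reference_choice = "explicit"`.
#' @return The corrected `ir_spectrum_set`, provenance tag appended.
#' @export
emsc_mie_correct <- function(set, config = preprocess_config(),
                             reference = NULL) {
  stopifnot(inherits(set, "ir_spectrum_set"),
            inherits(config, "ir_preprocess_config"))
  if (config$reference_choice == "explicit" && is.null(reference))
    stop("reference_choice = 'explicit' requires a reference", call. = FALSE)
  if (is.null(reference) && n_cells(set) < 2L)
    stop("cohort-mean reference needs at least 2 cells", call. = FALSE)
  grid <- set$wavenumbers
  ref <- if (is.null(reference)) rowMeans(set$absorbance)
  else as.numeric(reference)
  if (length(ref) != length(grid))
    stop("reference must be on the set grid", call. = FALSE)
  w01 <- 2 * (grid - min(grid)) / (max(grid) - min(grid)) - 1
  poly_terms <- vapply(0:config$emsc_poly_order, function(p) w01^p,
                       numeric(length(grid)))
  mie_terms <- mie_basis(grid, config$emsc_n_mie_curves)
  out <- set$absorbance
  for (it in seq_len(config$emsc_iterations)) {
    X <- cbind(ref, poly_terms, mie_terms)
    qr_x <- qr(X)
    for (j in seq_len(ncol(out))) {
      y <- set$absorbance[, j]
      beta <- qr.coef(qr_x, y)
      beta[is.na(beta)] <- 0
      b <- beta[1]
      if (abs(b) <= 1e-6)
        stop("degenerate EMSC fit (reference coefficient ~ 0) for cell ",
             set$cell_ids[j], call. = FALSE)
      interferents <- drop(X[, -1, drop = FALSE] %*% beta[-1])
      out[, j] <- (y - interferents) / b
    }
    ref <- rowMeans(out)
  }
  structure(
    list(wavenumbers = grid, absorbance = out, cell_ids = set$cell_ids,
         groups = set$groups,
         provenance = c(set$provenance,
                        sprintf("emsc_mie[poly%d,mie%d,it%d]",
                                config$emsc_poly_order,
                                config$emsc_n_mie_curves,
                                config$emsc_iterations))),
    class = "ir_spectrum_set")
}

#' Standard preprocessing chain
#'
#' Applies the full chain in fixed order: optional Mie-EMSC on the raw
#' absorbance, moving-average smoothing, linear automatic baseline
#' correction, and (optionally) the Savitzky-Golay second derivative.
#' Returns both the processed absorbance spectra and their
#' second-derivative counterpart, the two inputs of
#' [build_feature_matrix()].
#'
#' @param set A `ir_spectrum_set` of raw absorbance spectra.
#' @param config A [preprocess_config()].
#' @param emsc Logical: apply Mie-EMSC first (default `FALSE`; turn on for
#'   cohorts with scattering artifacts).
#' @return A list with elements `absorbance` (smoothed, baseline-corrected
#'   set) and `derivative` (its Savitzky-Golay second derivative).
#' @export
preprocess_set <- function(set, config = preprocess_config(), emsc = FALSE) {
  stopifnot(inherits(set, "ir_spectrum_set"))
  if (emsc) set <- emsc_mie_correct(set, config)
  ab <- baseline_linear(smooth_spectra(set, config$smooth_points))
  deriv <- second_derivative(ab, config$sg_window, config$sg_polyorder)
  list(absorbance = ab, derivative = deriv)
}
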