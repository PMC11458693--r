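#' Default mid-infrared wavenumber grid
#'
#' Descending grid over the mid-infrared range, 4,000 to 650 cm-1.  The
#' default 2 cm-1 point spacing corresponds to a typical digital grid for
#' spectra acquired at 4 cm-1 optical resolution.
#'
#' @param from,to Grid end points, cm-1 (`from > to`).
#' @param by Point spacing, cm-1.
#' @return Numeric vector, strictly descending.
#' @export
default_grid <- function(from = 4000, to = 650, by = 2) {
  stopifnot(from > to, by > 0)
  seq(from, to, by = -by)
}

#' Absorption band table for the synthetic generator
#'
#' An ordered table of Gaussian absorption bands (center, full width at
#' half maximum, mean amplitude, region label) used by [simulate_cohort()].
#' The default has exactly 14 bands at canonical cell-FTIR positions:
#' four CH stretching bands in the fatty-acid region, seven bands in the
#' protein (amide) region including amide I and amide II, and three
#' carbohydrate / nucleic-acid bands.  None of the default bands falls in
#' the 1,480-1,300 cm-1 fatty-acid bending interval; users studying that
#' interval can supply their own rows.
#'
#' @param bands A data.frame with columns `center` (cm-1, strictly
#'   descending), `fwhm` (cm-1), `amplitude` (a.u.) and `region`.
#'   `NULL` selects the 14-band default.
#' @return An object of class `ir_band_table` (a data.frame).
#' @export
band_table <- function(bands = NULL) {
  if (is.null(bands)) {
    bands <- data.frame(
      center = c(2960, 2924, 2872, 2852,
                 1740, 1696, 1656, 1628, 1584, 1544, 1514,
                 1240, 1084, 1050),
      fwhm   = c(16, 16, 10, 10,
                 16, 12, 22, 14, 12, 20, 10,
                 24, 26, 18),
      amplitude = c(0.30, 0.45, 0.30, 0.35,
                    0.30, 0.25, 1.00, 0.50, 0.20, 0.70, 0.25,
                    0.35, 0.45, 0.35),
      region = c(rep("fatty_acid", 4), rep("protein", 7),
                 rep("carbohydrate", 3)))
  }
  bands <- as.data.frame(bands)
  need <- c("center", "fwhm", "amplitude", "region")
  if (!all(need %in% names(bands)))
    stop("band table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(diff(bands$center) >= 0))
    stop("band centers must be strictly descending", call. = FALSE)
  if (any(bands$fwhm <= 0) || any(bands$amplitude <= 0))
    stop("band widths and amplitudes must be positive", call. = FALSE)
  structure(bands, class = c("ir_band_table", "data.frame"))
}

#' Design of a simulated single-cell cohort
#'
#' Describes the statistical structure of a simulated cohort: the number of
#' cells per treatment group, per-group multiplicative band-intensity
#' effects, log-normal cell-to-cell variability of band amplitudes,
#' additive detector noise, Mie-like scattering baseline distortion, and
#' the random seed.
#'
#' @param n_cells Cells per group.  Either a named vector (names are the
#'   group labels) or a scalar with `groups` supplied.
#' @param groups Group labels when `n_cells` is scalar.
#' @param group_effects Named list: per group, a multiplicative factor per
#'   band (scalar recycled, or one value per band).  Groups omitted get 1.
#' @param cell_cv Log-normal coefficient of variation of per-cell band
#'   amplitudes (unitless, >= 0).
#' @param noise_sd Additive Gaussian noise standard deviation, a.u.
#' @param mie_amplitude Scale of the per-cell Mie scattering baseline,
#'   a.u. (0 disables it).
#' @param mie_diameter Range (min, max) of per-cell sphere diameters, um.
#' @param mie_index Range (min, max) of per-cell refractive indices.
#' @param drift_sd Standard deviation of the random linear baseline drift
#'   (intercept and slope components), a.u.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the design.
#' @return An object of class `ir_cohort_design`.
#' @export
cohort_design <- function(n_cells = c(untreated = 50), groups = NULL,
                          group_effects = list(), cell_cv = 0.15,
                          noise_sd = 0.002, mie_amplitude = 0,
                          mie_diameter = c(8, 20), mie_index = c(1.3, 1.4),
                          drift_sd = 0.005, seed = 1L) {
  if (!is.null(groups)) {
    n_cells <- rep_len(n_cells, length(groups))
    names(n_cells) <- groups
  }
  if (is.null(names(n_cells)))
    stop("group labels required (name n_cells or supply groups=)", call. = FALSE)
  if (any(n_cells < 2)) stop("need at least 2 cells per group", call. = FALSE)
  if (cell_cv < 0 || noise_sd < 0 || mie_amplitude < 0 || drift_sd < 0)
    stop("cell_cv, noise_sd, mie_amplitude and drift_sd must be >= 0",
         call. = FALSE)
  if (length(group_effects)) {
    if (is.null(names(group_effects)))
      stop("group_effects must be a named list", call. = FALSE)
    if (any(unlist(group_effects) <= 0))
      stop("group effects must be > 0", call. = FALSE)
  }
  structure(
    list(n_cells = n_cells, group_effects = group_effects,
         cell_cv = cell_cv, noise_sd = noise_sd,
         mie_amplitude = mie_amplitude, mie_diameter = mie_diameter,
         mie_index = mie_index, drift_sd = drift_sd,
         seed = as.integer(seed)),
    class = "ir_cohort_design")
}

#' Van de Hulst Mie extinction baseline
#'
#' The non-resonant van de Hulst approximation to the Mie extinction
#' efficiency of a homogeneous sphere,
#' `Q(w) = 2 - (4/rho) sin(rho) + (4/rho^2) (1 - cos(rho))` with phase
#' `rho = 2 pi d (n - 1) w` (`w` in cm-1, `d` converted from um to cm).
#' This is the broad oscillatory baseline that Mie scattering by whole
#' cells superimposes on single-cell infrared spectra; the same curve
#' family forms the interferent basis of [emsc_mie_correct()].
#'
#' @param grid Wavenumber vector, cm-1.
#' @param amplitude Peak absolute value of the returned baseline, a.u.
#' @param sphere_diameter Sphere diameter, um, in (2, 30).
#' @param refractive_index Real refractive index, in (1.1, 1.5).
#' @return Numeric baseline vector, max absolute value equal to `amplitude`
#'   (all zeros when `amplitude = 0`).
#' @export
mie_artifact <- function(grid, amplitude, sphere_diameter = 12,
                         refractive_index = 1.35) {
  if (sphere_diameter < 2 || sphere_diameter > 30)
    stop("sphere_diameter must lie in [2, 30] um", call. = FALSE)
  if (refractive_index < 1.1 || refractive_index > 1.5)
    stop("refractive_index must lie in [1.1, 1.5]", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  d_cm <- sphere_diameter * 1e-4
  rho <- 2 * pi * d_cm * (refractive_index - 1) * grid
  q <- 2 - (4 / rho) * sin(rho) + (4 / rho^2) * (1 - cos(rho))
  q[rho == 0] <- 0
  if (amplitude == 0) return(numeric(length(grid)))
  amplitude * q / max(abs(q))
}

#' Simulate a cohort of single-cell infrared spectra
#'
#' Generates an aligned cohort with the generative model
#' `A_cell(w) = sum_b amp_cell_b G(w; center_b, fwhm_b) + baseline + noise`
#' where `amp_cell_b = amplitude_b * effect_group_b * LN(cv)` with a
#' mean-one log-normal cell factor, the baseline is a per-cell van de
#' Hulst Mie curve (random diameter and index) plus a random linear
#' drift, and the noise is additive Gaussian.  All random draws are
#' consumed in cell-id order from a single generator seeded by the
#' design, so the cohort is bitwise reproducible.
#'
#' @param design A [cohort_design()].
#' @param bands A [band_table()] (default: the 14-band table).
#' @param grid Wavenumber grid, cm-1 (default [default_grid()]); must
#'   cover all band centers.
#' @return A `ir_spectrum_set` with group labels attached and provenance
#'   `"simulated"`.
#' @export
simulate_cohort <- function(design, bands = band_table(),
                            grid = default_grid()) {
  stopifnot(inherits(design, "ir_cohort_design"))
  bands <- band_table(bands)
  if (any(bands$center > max(grid) | bands$center < min(grid)))
    stop("all band centers must lie inside the grid", call. = FALSE)
  n_b <- nrow(bands)
  sigma <- bands$fwhm / (2 * sqrt(2 * log(2)))
  # band shape matrix: grid x band
  shapes <- vapply(seq_len(n_b), function(b)
    exp(-(grid - bands$center[b])^2 / (2 * sigma[b]^2)),
    numeric(length(grid)))
  sdlog <- sqrt(log(1 + design$cell_cv^2))
  w01 <- (grid - min(grid)) / (max(grid) - min(grid)) # for linear drift

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(design$seed)

  groups_out <- character(0); ids <- character(0)
  cols <- vector("list", sum(design$n_cells))
  cell_k <- 0L
  for (g in names(design$n_cells)) {
    eff <- design$group_effects[[g]]
    eff <- if (is.null(eff)) rep(1, n_b) else rep_len(eff, n_b)
    for (i in seq_len(design$n_cells[[g]])) {
      cell_k <- cell_k + 1L
      # fixed per-cell draw order: amplitudes, mie (d, n), drift, noise
      lnf <- if (design$cell_cv > 0)
        stats::rlnorm(n_b, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      else rep(1, n_b)
      amps <- bands$amplitude * eff * lnf
      d <- stats::runif(1, design$mie_diameter[1], design$mie_diameter[2])
      ri <- stats::runif(1, design$mie_index[1], design$mie_index[2])
      base <- if (design$mie_amplitude > 0)
        mie_artifact(grid, design$mie_amplitude, d, ri)
      else numeric(length(grid))
      drift <- stats::rnorm(2, 0, design$drift_sd)
      noise <- if (design$noise_sd > 0)
        stats::rnorm(length(grid), 0, design$noise_sd)
      else numeric(length(grid))
      cols[[cell_k]] <- drop(shapes %*% amps) + base +
        drift[1] + drift[2] * w01 + noise
      ids <- c(ids, sprintf("%s_%03d", g, i))
      groups_out <- c(groups_out, g)
    }
  }
  spectrum_set(grid, do.call(cbind, cols), ids, groups_out,
               provenance = "simulated")
}

# Expected noise-free absorbance of a group at given wavenumbers (band sum
# including overlap), used by parameter-recovery tests.
expected_band_sum <- function(bands, wavenumbers, effect = 1) {
  bands <- band_table(bands)
  effect <- rep_len(effect, nrow(bands))
  sigma <- bands$fwhm / (2 * sqrt(2 * log(2)))
  vapply(wavenumbers, function(w)
    sum(bands$amplitude * effect * exp(-(w - bands$center)^2 / (2 * sigma^2))),
    0)
}
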