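#' Consensus peak set
#'
#' The ordered wavenumber positions of the absorption peaks used as the
#' per-cell feature basis, with their region assignment.  Under the
#' default region table a valid peak set has exactly 14 positions
#' partitioned 4 (fatty acid) / 7 (protein) / 3 (carbohydrate); peak 1 is
#' the highest wavenumber.
#'
#' @param positions Numeric wavenumbers, cm-1, strictly descending.
#' @param region_of Character region label per position.
#' @param regions The [region_table()] the assignment refers to.
#' @return An object of class `ir_peak_set`.
#' @export
peak_set <- function(positions, region_of, regions = region_table()) {
  positions <- as.numeric(positions)
  if (any(diff(positions) >= 0))
    stop("peak positions must be strictly descending", call. = FALSE)
  if (length(region_of) != length(positions))
    stop("need one region per position", call. = FALSE)
  mem <- region_membership(positions, regions)
  if (any(is.na(mem)) || any(mem != region_of))
    stop("every position must lie inside its assigned region", call. = FALSE)
  structure(list(positions = positions, region_of = as.character(region_of),
                 regions = regions),
            class = "ir_peak_set")
}

#' @export
print.ir_peak_set <- function(x, ...) {
  cat(sprintf("<ir_peak_set> %d peaks\n", length(x$positions)))
  for (r in unique(x$region_of))
    cat(sprintf("  %-13s %s\n", r,
                paste(x$positions[x$region_of == r], collapse = ", ")))
  invisible(x)
}

# Indices of strict local minima of v (plateau-tolerant on the right).
local_minima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[v[i] < v[i - 1L] & v[i] <= v[i + 1L]]
}

#' Detect consensus absorption peaks from second-derivative spectra
#'
#' Finds, on the cohort-mean second-derivative spectrum, the local minima
#' within each spectral region (absorption band maxima appear as
#' second-derivative minima), ranks them by depth and keeps the expected
#' count per region — 4 fatty-acid, 7 protein and 3 carbohydrate peaks by
#' default, giving the 14-dimensional feature basis.  Depth ties are
#' broken toward the higher wavenumber.
#'
#' @param set A `ir_spectrum_set` carrying a `second_derivative` provenance
#'   tag.
#' @param regions A [region_table()].
#' @param expected_counts Named integer vector of peaks to keep per region;
#'   default `c(fatty_acid = 4, protein = 7, carbohydrate = 3)`.
#' @param prominence_quantile Fraction in `[0, 1)`: minima shallower than
#'   this quantile of depths within a region are dropped before ranking.
#'   Default 0 (keep top-N by depth only).
#' @return An `ir_peak_set` with `sum(expected_counts)` positions.
#' @export
detect_peaks <- function(set, regions = region_table(),
                         expected_counts = c(fatty_acid = 4, protein = 7,
                                             carbohydrate = 3),
                         prominence_quantile = 0) {
  stopifnot(inherits(set, "ir_spectrum_set"))
  if (!any(grepl("^second_derivative", set$provenance)))
    stop("detect_peaks expects second-derivative spectra ",
         "(run second_derivative() first)", call. = FALSE)
  mean_d2 <- rowMeans(set$absorbance)
  mem <- region_membership(set$wavenumbers, regions)
  pos <- numeric(0); reg <- character(0)
  for (r in names(expected_counts)) {
    idx <- which(!is.na(mem) & mem == r)
    if (!length(idx))
      stop("region '", r, "' does not overlap the grid", call. = FALSE)
    # minima within contiguous runs of the region's grid points
    runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
    mins <- unlist(lapply(runs, function(ii) ii[local_minima(mean_d2[ii])]),
                   use.names = FALSE)
    depth <- -mean_d2[mins]
    if (prominence_quantile > 0 && length(depth)) {
      keep <- depth >= stats::quantile(depth, prominence_quantile)
      mins <- mins[keep]; depth <- depth[keep]
    }
    k <- expected_counts[[r]]
    if (length(mins) < k)
      stop(sprintf("region '%s': found %d second-derivative minima, expected %d",
                   r, length(mins), k), call. = FALSE)
    # rank by depth, ties toward the higher wavenumber
    o <- order(-depth, -set$wavenumbers[mins])
    sel <- mins[o[seq_len(k)]]
    pos <- c(pos, set$wavenumbers[sel])
    reg <- c(reg, rep(r, k))
  }
  o <- order(pos, decreasing = TRUE)
  peak_set(pos[o], reg[o], regions)
}

#' Single-cell spectral absorption matrix
#'
#' Builds the k x 14 feature matrix: one row per cell, one column per
#' consensus peak (peak 1 = highest wavenumber).  For each cell the
#' consensus position is refined to the cell's own second-derivative
#' minimum within +/- `refine_window` cm-1 (falling back to the consensus
#' position, with a note, when no in-region minimum exists there).  The
#' stored value is the cell's processed absorbance at the refined grid
#' point (`value_source = "original_absorbance"`, default) or the negated
#' second-derivative value there (`"second_derivative_depth"`).
#'
#' @param raw A `ir_spectrum_set` of (smoothed, baseline-corrected)
#'   absorbance spectra.
#' @param deriv The matching second-derivative `ir_spectrum_set` (same
#'   cells, same order, same grid).
#' @param peaks An `ir_peak_set` from [detect_peaks()].
#' @param value_source `"original_absorbance"` or
#'   `"second_derivative_depth"`.
#' @param refine_window Half-width of the per-cell refinement window,
#'   cm-1, default 8.
#' @return An object of class `ir_feature_matrix` with fields `values`
#'   (k x n_peaks matrix), `cell_ids`, `groups`, `peaks`, `value_source`
#'   and `notes` (per-cell refinement fallbacks).
#' @export
build_feature_matrix <- function(raw, deriv, peaks,
                                 value_source = c("original_absorbance",
                                                  "second_derivative_depth"),
                                 refine_window = 8) {
  value_source <- match.arg(value_source)
  stopifnot(inherits(raw, "ir_spectrum_set"),
            inherits(deriv, "ir_spectrum_set"),
            inherits(peaks, "ir_peak_set"))
  if (!identical(raw$cell_ids, deriv$cell_ids))
    stop("raw and derivative sets must contain the same cells in the same order",
         call. = FALSE)
  if (!identical(raw$wavenumbers, deriv$wavenumbers))
    stop("raw and derivative sets must share the grid", call. = FALSE)
  grid <- raw$wavenumbers
  mem <- region_membership(grid, peaks$regions)
  k <- n_cells(raw)
  np <- length(peaks$positions)
  values <- matrix(NA_real_, k, np,
                   dimnames = list(raw$cell_ids,
                                   sprintf("peak%02d_%g", seq_len(np),
                                           peaks$positions)))
  notes <- character(0)
  cons_idx <- vapply(peaks$positions,
                     function(p) which.min(abs(grid - p)), 0L)
  for (p in seq_len(np)) {
    win <- which(abs(grid - peaks$positions[p]) <= refine_window + 1e-9)
    in_region <- win[!is.na(mem[win]) & mem[win] == peaks$region_of[p]]
    for (j in seq_len(k)) {
      d2 <- deriv$absorbance[, j]
      lm_idx <- in_region[local_minima_within(d2, in_region)]
      if (length(lm_idx)) {
        at <- lm_idx[which.min(d2[lm_idx])]
      } else {
        at <- cons_idx[p]
        notes <- c(notes,
                   sprintf("cell %s peak %d: no in-window minimum, consensus position used",
                           raw$cell_ids[j], p))
      }
      values[j, p] <- if (value_source == "original_absorbance")
        raw$absorbance[at, j] else -d2[at]
    }
  }
  structure(
    list(values = values, cell_ids = raw$cell_ids, groups = raw$groups,
         peaks = peaks, value_source = value_source, notes = notes),
    class = "ir_feature_matrix")
}

# local minima of v restricted to index window idx (contiguous in grid
# terms is not required; evaluated against immediate grid neighbours).
local_minima_within <- function(v, idx) {
  which(vapply(idx, function(i)
    i > 1L && i < length(v) && v[i] < v[i - 1L] && v[i] <= v[i + 1L], NA))
}

#' @export
print.ir_feature_matrix <- function(x, ...) {
  cat(sprintf("<ir_feature_matrix> %d cells x %d peaks (%s)\n",
              nrow(x$values), ncol(x$values), x$value_source))
  tab <- table(x$peaks$region_of)[unique(x$peaks$region_of)]
  cat("regions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  if (length(x$notes)) cat(length(x$notes), "refinement fallback note(s)\n")
  invisible(x)
}

#' Split a feature matrix into its subregional views
#'
#' Partitions the columns of a feature matrix by spectral region,
#' preserving column order: under the defaults a 4-column fatty-acid view
#' (peaks 1-4), a 7-column protein view (peaks 5-11) and a 3-column
#' carbohydrate view (peaks 12-14).  Binding the views back together in
#' region order reproduces the input exactly.
#'
#' @param fm An `ir_feature_matrix`.
#' @return Named list of `ir_feature_matrix` views, one per region, in
#'   the order regions first appear along the peaks.
#' @export
split_subregions <- function(fm) {
  stopifnot(inherits(fm, "ir_feature_matrix"))
  if (any(diff(fm$peaks$positions) >= 0))
    stop("feature-matrix columns must be in descending peak order",
         call. = FALSE)
  region_order <- unique(fm$peaks$region_of)
  out <- lapply(region_order, function(r) {
    cols <- which(fm$peaks$region_of == r)
    structure(
      list(values = fm$values[, cols, drop = FALSE],
           cell_ids = fm$cell_ids, groups = fm$groups,
           peaks = peak_set(fm$peaks$positions[cols],
                            fm$peaks$region_of[cols], fm$peaks$regions),
           value_source = fm$value_source, notes = fm$notes),
      class = "ir_feature_matrix")
  })
  names(out) <- region_order
  out
}

#' Write a feature matrix as a delimited table
#'
#' @param fm An `ir_feature_matrix`.
#' @param path Output CSV path; a `<path>.peaks.csv` sidecar records the
#'   peak positions and regions.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "ir_feature_matrix"))
  df <- data.frame(cell_id = fm$cell_ids, group = fm$groups,
                   fm$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  side <- data.frame(peak = seq_along(fm$peaks$positions),
                     wavenumber_cm1 = fm$peaks$positions,
                     region = fm$peaks$region_of)
  utils::write.csv(side, paste0(path, ".peaks.csv"), row.names = FALSE)
  invisible(path)
}
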