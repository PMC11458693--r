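#' Single-cell infrared spectrum
#'
#' A `ir_spectrum` holds one cell's mid-infrared absorbance spectrum on a
#' strictly descending wavenumber grid (spectrometer convention,
#' 4,000 -> 650 cm-1), together with its cell identifier, treatment-group
#' label and a provenance trail of applied processing steps.
#'
#' @param cell_id Character scalar identifying the cell.
#' @param wavenumbers Numeric vector of wavenumbers in cm-1, strictly
#'   monotone.  Ascending input is reversed to descending with a message.
#' @param absorbance Numeric vector of absorbance values (a.u.), same length
#'   as `wavenumbers` (at least 16 points).
#' @param group Treatment-group label (character scalar), `NA` if unknown.
#' @param provenance Character vector of processing tags already applied.
#'
#' @return An object of class `ir_spectrum`.
#' @export
spectrum <- function(cell_id, wavenumbers, absorbance, group = NA_character_,
                     provenance = character()) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) != length(absorbance))
    stop("wavenumbers and absorbance must have equal length", call. = FALSE)
  if (length(wavenumbers) < 16L)
    stop("a spectrum needs at least 16 points", call. = FALSE)
  d <- diff(wavenumbers)
  if (all(d > 0)) {
    message("ascending wavenumber grid reversed to descending")
    wavenumbers <- rev(wavenumbers)
    absorbance <- rev(absorbance)
    d <- -rev(d)
  }
  if (any(d >= 0))
    stop("wavenumbers must be strictly monotone", call. = FALSE)
  sp <- abs(d)
  if (max(sp) / min(sp) >= 1.01)
    stop("wavenumber grid spacing is not approximately uniform", call. = FALSE)
  structure(
    list(cell_id = as.character(cell_id), wavenumbers = wavenumbers,
         absorbance = absorbance, group = as.character(group),
         provenance = as.character(provenance)),
    class = "ir_spectrum")
}

#' Cohort of single-cell spectra on a shared grid
#'
#' A `ir_spectrum_set` is an aligned collection of single-cell spectra: a
#' shared descending wavenumber grid and an absorbance matrix with one
#' column per cell.  All downstream stages (preprocessing, feature
#' extraction, distances, PCA) operate on sets.
#'
#' @param wavenumbers Shared wavenumber grid, cm-1, strictly descending
#'   (ascending input is reversed).
#' @param absorbance Numeric matrix, `length(wavenumbers)` rows, one column
#'   per cell.
#' @param cell_ids Character vector of unique cell identifiers, one per
#'   column.
#' @param groups Character vector of treatment-group labels, one per cell
#'   (recycled if scalar).
#' @param provenance Character vector of processing tags applied to the
#'   whole cohort.
#'
#' @return An object of class `ir_spectrum_set`.
#' @export
spectrum_set <- function(wavenumbers, absorbance, cell_ids,
                         groups = NA_character_, provenance = character()) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.matrix(absorbance)
  if (nrow(absorbance) != length(wavenumbers))
    stop("absorbance must have one row per wavenumber", call. = FALSE)
  if (length(wavenumbers) < 16L)
    stop("a spectrum set needs at least 16 grid points", call. = FALSE)
  d <- diff(wavenumbers)
  if (all(d > 0)) {
    wavenumbers <- rev(wavenumbers)
    absorbance <- absorbance[rev(seq_len(nrow(absorbance))), , drop = FALSE]
    d <- -rev(d)
  }
  if (any(d >= 0))
    stop("wavenumbers must be strictly monotone", call. = FALSE)
  sp <- abs(d)
  if (max(sp) / min(sp) >= 1.01)
    stop("wavenumber grid spacing is not approximately uniform", call. = FALSE)
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != ncol(absorbance))
    stop("need one cell_id per spectrum", call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("cell_ids must be unique", call. = FALSE)
  groups <- rep_len(as.character(groups), ncol(absorbance))
  dimnames(absorbance) <- list(NULL, cell_ids)
  structure(
    list(wavenumbers = wavenumbers, absorbance = absorbance,
         cell_ids = cell_ids, groups = groups,
         provenance = as.character(provenance)),
    class = "ir_spectrum_set")
}

#' @export
print.ir_spectrum_set <- function(x, ...) {
  cat(sprintf("<ir_spectrum_set> %d cells x %d points, %.0f-%.0f cm-1\n",
              n_cells(x), length(x$wavenumbers),
              max(x$wavenumbers), min(x$wavenumbers)))
  gr <- table(x$groups, useNA = "ifany")
  cat("groups:", paste(sprintf("%s (%d)", names(gr), gr), collapse = ", "), "\n")
  if (length(x$provenance))
    cat("provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
print.ir_spectrum <- function(x, ...) {
  cat(sprintf("<ir_spectrum> cell '%s' (group %s), %d points, %.0f-%.0f cm-1\n",
              x$cell_id, x$group, length(x$wavenumbers),
              max(x$wavenumbers), min(x$wavenumbers)))
  invisible(x)
}

#' Number of cells in a spectrum set
#' @param set A `ir_spectrum_set`.
#' @return Integer count of cells.
#' @export
n_cells <- function(set) {
  stopifnot(inherits(set, "ir_spectrum_set"))
  ncol(set$absorbance)
}

#' Extract one cell from a set as a single spectrum
#' @param set A `ir_spectrum_set`.
#' @param cell_id Cell identifier to extract.
#' @return An `ir_spectrum`.
#' @export
get_spectrum <- function(set, cell_id) {
  stopifnot(inherits(set, "ir_spectrum_set"))
  j <- match(cell_id, set$cell_ids)
  if (is.na(j)) stop("unknown cell_id: ", cell_id, call. = FALSE)
  spectrum(cell_id, set$wavenumbers, set$absorbance[, j],
           group = set$groups[j], provenance = set$provenance)
}

#' Subset a spectrum set by cell
#' @param set A `ir_spectrum_set`.
#' @param cells Character cell ids or logical/integer index over cells.
#' @return A `ir_spectrum_set` with the selected cells, in the given order.
#' @export
subset_cells <- function(set, cells) {
  stopifnot(inherits(set, "ir_spectrum_set"))
  if (is.character(cells)) {
    j <- match(cells, set$cell_ids)
    if (anyNA(j)) stop("unknown cell ids: ",
                       paste(cells[is.na(j)], collapse = ", "), call. = FALSE)
  } else j <- seq_len(n_cells(set))[cells]
  spectrum_set(set$wavenumbers, set$absorbance[, j, drop = FALSE],
               set$cell_ids[j], set$groups[j], set$provenance)
}

#' Spectral region table
#'
#' Named wavenumber intervals delimiting the biochemical subregions used
#' throughout the package.  The defaults are the canonical cell-FTIR
#' assignments: fatty acid (CH stretching 3,000-2,800 cm-1 and CH bending
#' 1,480-1,300 cm-1), protein (amide region 1,800-1,480 cm-1) and
#' carbohydrate / nucleic acid (1,300-900 cm-1).
#'
#' Interval membership is `lo <= w <= hi`.  A wavenumber shared by two
#' adjacent intervals (e.g. 1,480 or 1,300 cm-1) is assigned to the
#' higher-wavenumber interval only, so the subregional point sets
#' partition the grid and subregional distances add exactly.
#'
#' @param regions Named list; each element a list of `c(lo, hi)` intervals
#'   in cm-1.  Defaults to the three-region table described above.
#'
#' @return An object of class `ir_region_table`.
#' @export
region_table <- function(regions = NULL) {
  if (is.null(regions)) {
    regions <- list(
      fatty_acid   = list(c(3000, 2800), c(1480, 1300)),
      protein      = list(c(1800, 1480)),
      carbohydrate = list(c(1300, 900)))
  }
  if (is.null(names(regions)) || any(!nzchar(names(regions))))
    stop("regions must be named", call. = FALSE)
  regions <- lapply(regions, function(r) {
    if (is.numeric(r)) r <- list(r)
    lapply(r, function(iv) {
      iv <- sort(as.numeric(iv))
      if (length(iv) != 2L || iv[1] >= iv[2])
        stop("each interval must be c(lo, hi) with lo < hi", call. = FALSE)
      iv
    })
  })
  for (nm in names(regions)) {
    ivs <- regions[[nm]]
    if (length(ivs) > 1L) {
      o <- order(vapply(ivs, `[`, 0, 1))
      for (i in seq_len(length(ivs) - 1L))
        if (ivs[[o[i]]][2] > ivs[[o[i + 1L]]][1])
          stop("intervals within region '", nm, "' overlap", call. = FALSE)
    }
  }
  structure(list(regions = regions), class = "ir_region_table")
}

#' @export
print.ir_region_table <- function(x, ...) {
  cat("<ir_region_table>\n")
  for (nm in names(x$regions)) {
    ivs <- vapply(x$regions[[nm]],
                  function(iv) sprintf("[%g, %g]", iv[1], iv[2]), "")
    cat(sprintf("  %-13s %s cm-1\n", nm, paste(ivs, collapse = ", ")))
  }
  invisible(x)
}

# Assign each wavenumber to a region (or NA).  Ties at interval boundaries
# go to the interval with the higher upper bound, scanning intervals in
# descending-hi order, so regions partition the grid.
region_membership <- function(wavenumbers, regions) {
  stopifnot(inherits(regions, "ir_region_table"))
  ivs <- list(); lab <- character()
  for (nm in names(regions$regions))
    for (iv in regions$regions[[nm]]) {
      ivs <- c(ivs, list(iv)); lab <- c(lab, nm)
    }
  o <- order(vapply(ivs, `[`, 0, 2), decreasing = TRUE)
  out <- rep(NA_character_, length(wavenumbers))
  for (i in o) {
    iv <- ivs[[i]]
    hit <- is.na(out) & wavenumbers >= iv[1] - 1e-9 & wavenumbers <= iv[2] + 1e-9
    out[hit] <- lab[i]
  }
  out
}

#' Crop a spectrum set to a wavenumber interval
#'
#' Restricts the shared grid to `lo <= w <= hi` (inclusive, independent of
#' storage order).  Points are never reordered.
#'
#' @param set A `ir_spectrum_set`.
#' @param interval Numeric `c(lo, hi)` in cm-1 (any order).
#' @return The cropped `ir_spectrum_set`, with a provenance tag appended.
#' @export
crop <- function(set, interval) {
  stopifnot(inherits(set, "ir_spectrum_set"))
  iv <- sort(as.numeric(interval))
  keep <- set$wavenumbers >= iv[1] - 1e-9 & set$wavenumbers <= iv[2] + 1e-9
  if (!any(keep))
    stop(sprintf("interval [%g, %g] does not overlap the grid (%g-%g cm-1)",
                 iv[1], iv[2], min(set$wavenumbers), max(set$wavenumbers)),
         call. = FALSE)
  structure(
    list(wavenumbers = set$wavenumbers[keep],
         absorbance = set$absorbance[keep, , drop = FALSE],
         cell_ids = set$cell_ids, groups = set$groups,
         provenance = c(set$provenance,
                        sprintf("crop[%g,%g]", iv[1], iv[2]))),
    class = "ir_spectrum_set")
}

# Crop to the union of a region's intervals (points in any interval, in
# original grid order).
crop_region <- function(set, regions, region) {
  stopifnot(inherits(set, "ir_spectrum_set"))
  mem <- region_membership(set$wavenumbers, regions)
  keep <- !is.na(mem) & mem == region
  if (!any(keep))
    stop("region '", region, "' does not overlap the grid", call. = FALSE)
  structure(
    list(wavenumbers = set$wavenumbers[keep],
         absorbance = set$absorbance[keep, , drop = FALSE],
         cell_ids = set$cell_ids, groups = set$groups,
         provenance = c(set$provenance, sprintf("crop_region[%s]", region))),
    class = "ir_spectrum_set")
}

#' Read a spectrum set from a plain-text table
#'
#' Two layouts are supported.  `wide_table`: first column the wavenumber
#' grid, remaining columns one cell each; an optional `#group:` header line
#' maps cell ids to treatment groups
#' (`#group: cell1=ctrl,cell2=treated,...`).  `long_table`: columns
#' `cell_id, group, wavenumber_cm-1, absorbance`, one row per point.  Cells
#' must share the identical grid; no interpolation is attempted.
#'
#' @param path Path to a tab- or comma-delimited text file.
#' @param format `"wide_table"` (default) or `"long_table"`.
#' @return A `ir_spectrum_set`.
#' @export
read_spectrum_set <- function(path, format = c("wide_table", "long_table")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  head_lines <- readLines(path, n = 50L)
  groups_map <- NULL
  g <- grep("^#group:", head_lines, value = TRUE)
  if (length(g)) {
    pairs <- strsplit(strsplit(sub("^#group:\\s*", "", g[1]), ",")[[1]], "=")
    groups_map <- vapply(pairs, function(p) trimws(p[2]), "")
    names(groups_map) <- vapply(pairs, function(p) trimws(p[1]), "")
  }
  sep <- if (grepl(",", grep("^[^#]", head_lines, value = TRUE)[1])) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           check.names = FALSE, colClasses = "character")
  if (format == "wide_table") {
    num <- suppressWarnings(
      vapply(raw, as.numeric, numeric(nrow(raw))))
    if (anyNA(num)) {
      bad <- which(is.na(num), arr.ind = TRUE)[1, ]
      stop(sprintf("non-numeric value at data row %d, column '%s'",
                   bad[1], colnames(raw)[bad[2]]), call. = FALSE)
    }
    num <- matrix(num, nrow = nrow(raw),
                  dimnames = list(NULL, colnames(raw)))
    wn <- num[, 1]
    ab <- num[, -1, drop = FALSE]
    ids <- colnames(raw)[-1]
    grp <- if (is.null(groups_map)) NA_character_ else
      unname(groups_map[ids])
    spectrum_set(wn, ab, ids, grp)
  } else {
    need <- c("cell_id", "group", "wavenumber_cm-1", "absorbance")
    if (!all(need %in% colnames(raw)))
      stop("long table must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    wn_all <- suppressWarnings(as.numeric(raw[["wavenumber_cm-1"]]))
    ab_all <- suppressWarnings(as.numeric(raw[["absorbance"]]))
    if (anyNA(wn_all) || anyNA(ab_all)) {
      bad <- which(is.na(wn_all) | is.na(ab_all))[1]
      stop(sprintf("non-numeric value at data row %d", bad), call. = FALSE)
    }
    ids <- unique(raw$cell_id)
    split_wn <- split(wn_all, factor(raw$cell_id, levels = ids))
    split_ab <- split(ab_all, factor(raw$cell_id, levels = ids))
    # common grid from the first cell, descending
    ref <- sort(split_wn[[1]], decreasing = TRUE)
    ok <- vapply(split_wn, function(w)
      length(w) == length(ref) && all(sort(w, decreasing = TRUE) == ref),
      NA)
    if (!all(ok))
      stop("cells cannot be aligned on a common grid: ",
           paste(ids[!ok], collapse = ", "), call. = FALSE)
    ab <- vapply(ids, function(id) {
      o <- order(split_wn[[id]], decreasing = TRUE)
      split_ab[[id]][o]
    }, numeric(length(ref)))
    grp <- vapply(ids, function(id) raw$group[raw$cell_id == id][1], "")
    spectrum_set(ref, ab, ids, grp)
  }
}

#' Write a spectrum set as a wide plain-text table
#'
#' Writes a comma-delimited wide table (`wavenumber_cm-1` first column, one
#' column per cell) with full float precision, preceded by `#` header
#' lines recording the group map and provenance.  `read_spectrum_set()` of
#' the result reproduces the set bitwise.
#'
#' @param set A non-empty `ir_spectrum_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_set <- function(set, path) {
  stopifnot(inherits(set, "ir_spectrum_set"))
  if (n_cells(set) < 1L) stop("cannot write an empty spectrum set", call. = FALSE)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error"))
    stop("cannot open for writing: ", path, call. = FALSE)
  on.exit(close(con))
  writeLines(sprintf("#group: %s",
                     paste(set$cell_ids, set$groups, sep = "=", collapse = ",")),
             con)
  if (length(set$provenance))
    writeLines(sprintf("#provenance: %s", paste(set$provenance, collapse = ";")),
               con)
  writeLines(paste(c("wavenumber_cm-1", set$cell_ids), collapse = ","), con)
  body <- cbind(set$wavenumbers, set$absorbance)
  lines <- apply(body, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(lines, con)
  invisible(path)
}
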