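#' Cell-to-cell Euclidean distance
#'
#' The root-sum-of-squares difference between two cells' feature vectors,
#' `D_Eu(p, q) = sqrt(sum_i (p_i - q_i)^2)`.  Larger distances mean lower
#' cell-to-cell spectral similarity.
#'
#' @param p,q Numeric feature vectors of equal length.
#' @return Non-negative scalar distance, a.u.
#' @export
euclidean_distance <- function(p, q) {
  if (length(p) != length(q))
    stop(sprintf("dimension mismatch: length %d vs %d", length(p), length(q)),
         call. = FALSE)
  sqrt(sum((p - q)^2))
}

#' All-pairs cell-to-cell distance matrix
#'
#' Computes the full k x k matrix of cell-to-cell Euclidean distances over
#' a chosen feature scope: all 14 peaks (`"full_14"`) or one subregional
#' vector (`"fatty_acid_4"`: peaks 1-4, `"protein_7"`: peaks 5-11,
#' `"carbohydrate_3"`: peaks 12-14 under the defaults).  All k^2 entries
#' form the heatmap; the k(k-1)/2 unique unordered pairs feed
#' [pair_histogram()] and [heterogeneity_index()].
#'
#' @param fm An `ir_feature_matrix` with at least 2 cells.
#' @param region_scope One of `"full_14"`, `"fatty_acid_4"`,
#'   `"protein_7"`, `"carbohydrate_3"`.
#' @param standardize Logical: z-score each column before computing
#'   distances.  Default `FALSE` (distances on raw feature values).
#' @return An object of class `ir_distance_matrix` with fields `D`
#'   (symmetric k x k, zero diagonal), `cell_ids`, `groups`,
#'   `region_scope`.
#' @export
distance_matrix <- function(fm,
                            region_scope = c("full_14", "fatty_acid_4",
                                             "protein_7", "carbohydrate_3"),
                            standardize = FALSE) {
  stopifnot(inherits(fm, "ir_feature_matrix"))
  region_scope <- match.arg(region_scope)
  if (nrow(fm$values) < 2L) stop("need at least 2 cells", call. = FALSE)
  cols <- switch(region_scope,
                 full_14 = seq_len(ncol(fm$values)),
                 fatty_acid_4 = which(fm$peaks$region_of == "fatty_acid"),
                 protein_7 = which(fm$peaks$region_of == "protein"),
                 carbohydrate_3 = which(fm$peaks$region_of == "carbohydrate"))
  if (!length(cols))
    stop("scope '", region_scope, "' selects no feature columns", call. = FALSE)
  v <- fm$values[, cols, drop = FALSE]
  if (standardize) v <- scale(v)
  k <- nrow(v)
  # expand |p - q|^2 = |p|^2 + |q|^2 - 2 p.q over all pairs
  sq <- rowSums(v^2)
  d2 <- outer(sq, sq, `+`) - 2 * tcrossprod(v)
  d2[d2 < 0] <- 0
  D <- sqrt(d2)
  D[cbind(seq_len(k), seq_len(k))] <- 0
  D <- (D + t(D)) / 2
  dimnames(D) <- list(fm$cell_ids, fm$cell_ids)
  structure(list(D = D, cell_ids = fm$cell_ids, groups = fm$groups,
                 region_scope = region_scope),
            class = "ir_distance_matrix")
}

#' @export
print.ir_distance_matrix <- function(x, ...) {
  k <- nrow(x$D)
  cat(sprintf("<ir_distance_matrix> %d x %d (%d distances, %d unique pairs), scope %s\n",
              k, k, k^2, k * (k - 1) / 2, x$region_scope))
  cat(sprintf("mean unique-pair distance: %.4g\n",
              mean(x$D[upper.tri(x$D)])))
  invisible(x)
}

# Unique unordered pair distances (upper triangle).
pair_distances <- function(dm) {
  stopifnot(inherits(dm, "ir_distance_matrix"))
  dm$D[upper.tri(dm$D)]
}

#' Histogram of unique pair distances
#'
#' Bins the k(k-1)/2 unique cell-to-cell distances (upper triangle of the
#' distance matrix); the heatmap, by contrast, displays all k^2 entries.
#'
#' @param dm An `ir_distance_matrix`.
#' @param n_bins Number of equal-width bins (>= 1).
#' @return List with `breaks` (length `n_bins + 1`), `counts`
#'   (length `n_bins`, summing to k(k-1)/2) and `mids`.
#' @export
pair_histogram <- function(dm, n_bins = 30L) {
  if (n_bins < 1L) stop("n_bins must be >= 1", call. = FALSE)
  d <- pair_distances(dm)
  rng <- range(d)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE)
  list(breaks = h$breaks, counts = h$counts, mids = h$mids)
}

#' Heterogeneity summary of a distance matrix
#'
#' Location and spread statistics of the unique cell-to-cell distances.
#' Distance is inversely related to similarity: a larger mean distance
#' means a more heterogeneous (less mutually similar) cohort.
#'
#' @param dm An `ir_distance_matrix`.
#' @return List with `mean`, `median`, `iqr` and `n_pairs`.
#' @export
heterogeneity_index <- function(dm) {
  d <- pair_distances(dm)
  list(mean = mean(d), median = stats::median(d),
       iqr = stats::IQR(d), n_pairs = length(d))
}

#' Principal component analysis of second-derivative spectra
#'
#' Mean-centered (unscaled) PCA of the cells' second-derivative spectra
#' over the full spectrum or one spectral region.  Components are ordered
#' by explained variance, descending; each loading's sign is fixed so its
#' largest-magnitude element is positive.
#'
#' @param set A `ir_spectrum_set` carrying a `second_derivative`
#'   provenance tag (k cells).
#' @param region_scope `"full_spectrum"` (default) or one of the region
#'   names of `regions`.
#' @param n_components Number of components to keep (>= 2, < k).
#' @param regions A [region_table()] used to resolve region scopes.
#' @return An object of class `ir_pca_result` with `scores`
#'   (k x n_components, column means 0), `explained_variance_fraction`,
#'   `loadings` (n_components x n_wavenumbers), `wavenumbers`, `groups`
#'   and `region_scope`.
#' @export
pca_spectra <- function(set, region_scope = "full_spectrum",
                        n_components = 2L, regions = region_table()) {
  stopifnot(inherits(set, "ir_spectrum_set"))
  if (!any(grepl("^second_derivative", set$provenance)))
    stop("pca_spectra expects second-derivative spectra", call. = FALSE)
  if (region_scope != "full_spectrum") {
    if (!region_scope %in% names(regions$regions))
      stop("unknown region scope: ", region_scope, call. = FALSE)
    set <- crop_region(set, regions, region_scope)
  }
  k <- n_cells(set)
  if (n_components < 2L || k <= n_components)
    stop("need k > n_components >= 2", call. = FALSE)
  x <- t(set$absorbance)            # cells x wavenumbers
  if (all(apply(x, 2L, stats::var) < 1e-30))
    stop("degenerate input: spectra have no variance", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  total_var <- sum(pc$sdev^2)
  m <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(m), drop = FALSE]
  loadings <- t(pc$rotation[, seq_len(m), drop = FALSE])
  for (i in seq_len(m)) {
    j <- which.max(abs(loadings[i, ]))
    if (loadings[i, j] < 0) {
      loadings[i, ] <- -loadings[i, ]
      scores[, i] <- -scores[, i]
    }
  }
  structure(
    list(scores = scores,
         explained_variance_fraction = pc$sdev[seq_len(m)]^2 / total_var,
         loadings = loadings, wavenumbers = set$wavenumbers,
         cell_ids = set$cell_ids, groups = set$groups,
         region_scope = region_scope),
    class = "ir_pca_result")
}

#' @export
print.ir_pca_result <- function(x, ...) {
  cat(sprintf("<ir_pca_result> scope %s, %d cells, %d components\n",
              x$region_scope, nrow(x$scores), ncol(x$scores)))
  cat("explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance_fraction),
            collapse = ", "), "\n")
  invisible(x)
}

#' Mean silhouette of group labels in PC space
#'
#' Mean silhouette width of the treatment-group labelling over the first
#' two principal-component scores (Euclidean distance), a scalar summary
#' of how separately the groups cluster in the score plot: values near 1
#' mean tight, well-separated groups; values near 0 mean overlapping
#' groups.
#'
#' @param pca An `ir_pca_result` with group labels.
#' @param components Score columns to use, default `1:2`.
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
group_silhouette <- function(pca, components = 1:2) {
  stopifnot(inherits(pca, "ir_pca_result"))
  lab <- factor(pca$groups)
  if (nlevels(lab) < 2L)
    stop("silhouette needs at least 2 groups", call. = FALSE)
  d <- stats::dist(pca$scores[, components, drop = FALSE])
  sil <- cluster::silhouette(as.integer(lab), d)
  mean(sil[, "sil_width"])
}
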