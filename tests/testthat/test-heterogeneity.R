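# Small hand-made feature matrix used across tests.
toy_fm <- function(values, regions = c("fatty_acid", "protein",
                                       "carbohydrate")) {
  npk <- c(fatty_acid = 4L, protein = 7L, carbohydrate = 3L)
  pos <- c(2960, 2920, 2880, 2840, 1750, 1700, 1650, 1600, 1560, 1520,
           1490, 1250, 1100, 1000)
  structure(
    list(values = values, cell_ids = rownames(values),
         groups = rep("g", nrow(values)),
         peaks = peak_set(pos, rep(names(npk), npk)),
         value_source = "original_absorbance", notes = character()),
    class = "ir_feature_matrix")
}

test_that("euclidean_distance implements the root-sum-of-squares formula", {
  expect_equal(euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(euclidean_distance(c(0, 0, 0, 0), c(3, 4, 0, 0)), 5)
  expect_error(euclidean_distance(1:3, 1:4), "dimension")
  set.seed(4)
  for (i in 1:20) {
    p <- rnorm(14); q <- rnorm(14)
    # term-by-term summation oracle
    acc <- 0
    for (k in 1:14) acc <- acc + (p[k] - q[k])^2
    expect_equal(euclidean_distance(p, q), sqrt(acc), tolerance = 1e-12)
  }
})

test_that("distance matrices are symmetric, zero-diagonal and scope columns", {
  v <- matrix(rnorm(3 * 14), 3, 14,
              dimnames = list(c("a", "b", "c"), NULL))
  fm <- toy_fm(v)
  dm <- distance_matrix(fm, "full_14")
  expect_equal(dim(dm$D), c(3L, 3L))
  expect_equal(dm$D, t(dm$D))
  expect_equal(diag(dm$D), c(a = 0, b = 0, c = 0))
  # hand-computed pair
  expect_equal(dm$D["a", "b"], sqrt(sum((v[1, ] - v[2, ])^2)),
               tolerance = 1e-12)
  # independent oracle over all pairs
  expect_equal(unname(dm$D), unname(as.matrix(dist(v))), tolerance = 1e-12)

  # subregional scopes use exactly their column blocks
  expect_equal(unname(distance_matrix(fm, "fatty_acid_4")$D),
               unname(as.matrix(dist(v[, 1:4]))), tolerance = 1e-12)
  expect_equal(unname(distance_matrix(fm, "protein_7")$D),
               unname(as.matrix(dist(v[, 5:11]))), tolerance = 1e-12)
  expect_equal(unname(distance_matrix(fm, "carbohydrate_3")$D),
               unname(as.matrix(dist(v[, 12:14]))), tolerance = 1e-12)

  # duplicating a cell adds a zero off-diagonal entry
  v2 <- rbind(v, a2 = v[1, ])
  dm2 <- distance_matrix(toy_fm(v2), "full_14")
  expect_equal(dm2$D["a", "a2"], 0)
})

test_that("squared subregional distances sum to the full squared distance", {
  set.seed(5)
  v <- matrix(rlnorm(20 * 14), 20, 14,
              dimnames = list(sprintf("c%02d", 1:20), NULL))
  fm <- toy_fm(v)
  d_full <- distance_matrix(fm, "full_14")$D
  d_fat <- distance_matrix(fm, "fatty_acid_4")$D
  d_pro <- distance_matrix(fm, "protein_7")$D
  d_car <- distance_matrix(fm, "carbohydrate_3")$D
  expect_equal(d_full^2, d_fat^2 + d_pro^2 + d_car^2, tolerance = 1e-12)
})

test_that("pair histograms cover the unique unordered pairs", {
  k <- 200L
  set.seed(6)
  v <- matrix(rnorm(k * 14), k, 14,
              dimnames = list(sprintf("c%03d", 1:k), NULL))
  dm <- distance_matrix(toy_fm(v), "full_14")
  h <- pair_histogram(dm, 25)
  expect_equal(sum(h$counts), k * (k - 1L) / 2L)  # C(200, 2) = 19,900
  expect_equal(sum(h$counts), 19900L)
  expect_length(h$counts, 25L)

  # k = 2: a single pair
  dm2 <- distance_matrix(toy_fm(v[1:2, , drop = FALSE]), "full_14")
  h2 <- pair_histogram(dm2, 5)
  expect_equal(sum(h2$counts), 1L)
  expect_error(pair_histogram(dm, 0), "n_bins")

  # identical cells: all mass at zero
  same <- toy_fm(matrix(1, 4, 14, dimnames = list(letters[1:4], NULL)))
  h3 <- pair_histogram(distance_matrix(same, "full_14"), 3)
  zero_bin <- findInterval(0, h3$breaks, rightmost.closed = TRUE)
  expect_equal(h3$counts[zero_bin], 6L)
  expect_equal(sum(h3$counts), 6L)
})

test_that("heterogeneity indices summarise unique pair distances", {
  same <- toy_fm(matrix(2, 5, 14, dimnames = list(letters[1:5], NULL)))
  hi <- heterogeneity_index(distance_matrix(same, "full_14"))
  expect_equal(hi$mean, 0)
  expect_equal(hi$n_pairs, 10L)

  # two tight clusters separated by d: between-pairs dominate the median
  # for balanced clusters (combinatorial count: 25 of 45 pairs are between)
  d <- 10
  v <- rbind(matrix(0, 5, 14), matrix(d / sqrt(14), 5, 14))
  rownames(v) <- sprintf("c%02d", 1:10)
  hi2 <- heterogeneity_index(distance_matrix(toy_fm(v), "full_14"))
  expect_equal(hi2$median, d, tolerance = 1e-12)
})

test_that("mean pairwise distance rises monotonically with cell_cv", {
  means <- vapply(c(0.05, 0.15, 0.3), function(cv) {
    des <- cohort_design(n_cells = c(g = 40), cell_cv = cv,
                         noise_sd = 0.002, seed = 21)
    proc <- preprocess_set(simulate_cohort(des))
    pk <- detect_peaks(proc$derivative)
    fm <- build_feature_matrix(proc$absorbance, proc$derivative, pk)
    heterogeneity_index(distance_matrix(fm, "full_14"))$mean
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("PCA on second-derivative spectra obeys its contracts", {
  des <- cohort_design(n_cells = c(a = 15, b = 15), cell_cv = 0.2,
                       noise_sd = 0.005, seed = 8)
  proc <- preprocess_set(simulate_cohort(des))
  pr <- pca_spectra(proc$derivative, n_components = 4)
  expect_equal(ncol(pr$scores), 4L)
  # centered scores, non-increasing variance fractions summing <= 1
  expect_equal(unname(colMeans(pr$scores)), rep(0, 4), tolerance = 1e-10)
  expect_true(all(diff(pr$explained_variance_fraction) <= 1e-12))
  expect_lte(sum(pr$explained_variance_fraction), 1)
  expect_true(all(pr$explained_variance_fraction >= 0))
  # sign convention: largest-magnitude loading element positive
  for (i in 1:4) {
    l <- pr$loadings[i, ]
    expect_gt(l[which.max(abs(l))], 0)
  }
  # requires derivative provenance and non-degenerate input
  expect_error(pca_spectra(simulate_cohort(des)), "second-derivative")
  flat <- second_derivative(toy_set(list(0 * (1:101), 0 * (1:101),
                                         0 * (1:101)),
                                    seq(2000, 1000, by = -10)))
  expect_error(pca_spectra(flat), "degenerate|variance")
})

test_that("rank-2 data is fully explained by two components", {
  grid <- seq(2000, 1000, by = -10)
  b1 <- gauss_band(grid, 1700, 60)
  b2 <- gauss_band(grid, 1200, 80)
  set.seed(9)
  cols <- lapply(1:12, function(i) runif(1) * b1 + runif(1) * b2)
  s <- toy_set(cols, grid)
  s$provenance <- "second_derivative[9,3]"   # rank test, content immaterial
  pr <- pca_spectra(s, n_components = 2)
  expect_equal(sum(pr$explained_variance_fraction), 1, tolerance = 1e-9)
})

test_that("scores match an eigendecomposition oracle", {
  grid <- seq(1500, 1300, by = -10)
  set.seed(10)
  m <- matrix(rnorm(length(grid) * 8), length(grid), 8)
  s <- spectrum_set(grid, m, sprintf("c%d", 1:8),
                    provenance = "second_derivative[9,3]")
  pr <- pca_spectra(s, n_components = 3)
  x <- scale(t(m), center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(x) / 1)      # spectral decomposition of X'X
  for (i in 1:3) {
    oracle <- x %*% eig$vectors[, i]
    # same axis up to sign
    expect_equal(abs(unname(pr$scores[, i])), abs(drop(oracle)),
                 tolerance = 1e-8)
  }
})

test_that("rigid feature rotation leaves pairwise score distances unchanged", {
  grid <- seq(1500, 1300, by = -10)
  set.seed(11)
  m <- matrix(rnorm(length(grid) * 10), length(grid), 10)
  s <- spectrum_set(grid, m, sprintf("c%d", 1:10),
                    provenance = "second_derivative[9,3]")
  q <- qr.Q(qr(matrix(rnorm(length(grid)^2), length(grid))))
  s_rot <- s
  s_rot$absorbance <- q %*% m
  d1 <- dist(pca_spectra(s, n_components = 5)$scores)
  d2 <- dist(pca_spectra(s_rot, n_components = 5)$scores)
  expect_equal(unname(as.vector(d1)), unname(as.vector(d2)),
               tolerance = 1e-8)
})

test_that("groups differing only in carbohydrate bands separate only there", {
  des <- cohort_design(n_cells = c(ctrl = 100, treated = 100),
                       group_effects = list(
                         treated = c(rep(1, 11), rep(0.5, 3))),
                       cell_cv = 0.15, noise_sd = 0.002, seed = 11)
  proc <- preprocess_set(simulate_cohort(des))
  sil_carb <- group_silhouette(pca_spectra(proc$derivative, "carbohydrate"))
  sil_prot <- group_silhouette(pca_spectra(proc$derivative, "protein"))
  expect_gt(sil_carb, 0.5)
  expect_lt(sil_prot, 0.2)
})
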