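stack_from_matrix <- function(m, names = paste0("L", seq_len(ncol(m)))) {
  n <- nrow(m)
  side <- ceiling(sqrt(n))
  # pad to a rectangular grid if needed
  grid <- grid_definition(side, ceiling(n / side))
  if (n_cells(grid) > n) {
    m <- rbind(m, m[seq_len(n_cells(grid) - n), , drop = FALSE])
  }
  colnames(m) <- names
  structure(list(grid = grid, values = m,
                 groups = setNames(rep("g", ncol(m)), names)),
            class = "env_stack")
}

test_that("uncorrelated layers all survive the collinearity filter", {
  set.seed(1)
  st <- stack_from_matrix(matrix(rnorm(400 * 5), 400))
  expect_setequal(collinearity_filter(st, 0.8), paste0("L", 1:5))
})

test_that("an exact duplicate layer is dropped", {
  set.seed(2)
  base <- rnorm(400)
  st <- stack_from_matrix(cbind(base, base, rnorm(400)),
                          c("A", "Acopy", "C"))
  kept <- collinearity_filter(st, 0.8)
  expect_length(kept, 2)
  expect_true(sum(c("A", "Acopy") %in% kept) == 1)
})

test_that("the filter drops the member with larger mean correlation", {
  # r(B,C) = 0.75 keeps the matrix positive definite and below r_max
  R <- rbind(c(1, 0.95, 0.9),
             c(0.95, 1, 0.75),
             c(0.9, 0.75, 1))
  m <- correlated_layers(900, R, seed = 3)
  st <- stack_from_matrix(m, c("A", "B", "C"))
  # worst pair (A,B); mean|r|: A = 0.925 > B = 0.85, so A is dropped;
  # the surviving pair (B,C) sits below the ceiling
  expect_setequal(collinearity_filter(st, 0.8), c("B", "C"))
  # result independent of column order
  st2 <- stack_from_matrix(m[, c(3, 1, 2)], c("C", "A", "B"))
  expect_setequal(collinearity_filter(st2, 0.8), c("B", "C"))
})

test_that("PCA reduction keeps all layers when k equals the count", {
  set.seed(4)
  st <- stack_from_matrix(matrix(rnorm(400 * 4), 400))
  expect_setequal(pca_reduce_bioclim(st, k = 4), paste0("L", 1:4))
  expect_error(pca_reduce_bioclim(st, k = 9), "exceeds")
})

test_that("PCA reduction does not select a redundant copy twice", {
  set.seed(5)
  a <- rnorm(500)
  b <- rnorm(500)
  st <- stack_from_matrix(cbind(a, a, b, rnorm(500)),
                          c("A1", "A2", "B", "C"))
  sel <- pca_reduce_bioclim(st, k = 2)
  expect_lte(sum(c("A1", "A2") %in% sel), 1)
})

test_that("PCA reduction recovers signal layers among noisy copies", {
  # 6 independent signals plus 13 noisy copies, as a 19-layer bioclim stand-in
  set.seed(6)
  n <- 1500
  signals <- matrix(rnorm(n * 6), n)
  copies <- signals[, rep(1:6, length.out = 13)] +
    matrix(rnorm(n * 13, sd = 0.5), n)
  st <- stack_from_matrix(cbind(signals, copies),
                          c(paste0("SIG", 1:6), paste0("CPY", 1:13)))
  sel <- pca_reduce_bioclim(st, k = 6)
  # oracle: each selected layer should be one of the true signals
  expect_setequal(sel, paste0("SIG", 1:6))
})

test_that("LSVM merit scales |w| onto [1, 10] with a >5 influence cut", {
  cfg <- small_config(n = 25, seed = 8)
  st <- generate_env_stack(cfg)
  truth <- toy_truth(st, c(environmental_1 = 3), prevalence = 0.2, code = "CT")
  occ <- sample_occurrences(st, truth, 80, seed = 1)
  mt <- lsvm_average_merit(occ, st, seed = 2)
  expect_true(all(mt$average_merit >= 1 & mt$average_merit <= 10))
  expect_identical(mt$influential, mt$average_merit > 5)
  # min-max map endpoints
  expect_equal(min(mt$average_merit), 1)
  expect_equal(max(mt$average_merit), 10)
  # permutation equivariance: reordering layers leaves merits unchanged
  st_perm <- subset_stack(st, rev(colnames(st$values)))
  mt2 <- lsvm_average_merit(occ, st_perm, seed = 2)
  m1 <- setNames(mt$average_merit, mt$predictor)
  m2 <- setNames(mt2$average_merit, mt2$predictor)
  expect_equal(m1[sort(names(m1))], m2[sort(names(m1))], tolerance = 1e-6)
})

test_that("a single predictor gets merit 10", {
  cfg <- small_config(n = 20, seed = 9)
  st <- generate_env_stack(cfg)
  st1 <- subset_stack(st, "topographic_1")
  truth <- toy_truth(st1, c(topographic_1 = 3), prevalence = 0.2, code = "AR")
  occ <- sample_occurrences(st1, truth, 60, seed = 3)
  mt <- lsvm_average_merit(occ, st1, seed = 4)
  expect_equal(mt$average_merit, 10)
})

test_that("the true driver is flagged influential in most replicates", {
  cfg <- landscape_config(n_rows = 35, n_cols = 35,
                          n_predictors_per_group = 2,
                          spatial_autocorrelation_range = 3, seed = 10)
  st <- generate_env_stack(cfg)   # 12 layers: 1 driver + 11 nuisance
  truth <- toy_truth(st, c(water_1 = 3), prevalence = 0.2, code = "SA")
  hits <- 0L
  for (s in 1:20) {
    occ <- sample_occurrences(st, truth, 300, seed = s)
    mt <- lsvm_average_merit(occ, st, seed = 100 + s)
    if (mt$influential[mt$predictor == "water_1"]) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})
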