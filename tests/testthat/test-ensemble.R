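test_that("pseudo-absences are unoccupied, exact and reproducible", {
  g <- grid_definition(6, 6)
  occ_cells <- c(1L, 5L, 20L)
  expect_identical(generate_pseudo_absences(g, occ_cells, 0, 1), integer(0))
  all_free <- generate_pseudo_absences(g, occ_cells, 33, 1)
  expect_setequal(all_free, setdiff(1:36, occ_cells))
  expect_error(generate_pseudo_absences(g, occ_cells, 34, 1), "more background")
  expect_identical(generate_pseudo_absences(g, occ_cells, 10, 7),
                   generate_pseudo_absences(g, occ_cells, 10, 7))
})

test_that("the nested split has the stated sizes and is a partition", {
  labels <- c(rep(1, 100), rep(0, 100))
  sp <- split_data(labels, seed = 3)
  expect_length(sp$extrinsic, 40)
  expect_length(sp$train, 120)
  expect_length(sp$intrinsic_test, 40)
  all_idx <- c(sp$train, sp$intrinsic_test, sp$extrinsic)
  expect_setequal(all_idx, seq_along(labels))
  expect_equal(length(all_idx), length(unique(all_idx)))
  # stratification: each partition holds both classes
  for (part in sp) expect_setequal(unique(labels[part]), c(0, 1))
  expect_identical(sp, split_data(labels, seed = 3))
  expect_error(split_data(c(rep(1, 5), rep(0, 20))), "at least 8")
})

test_that("SRE scores 1 inside the presence envelope and 0 outside", {
  x <- matrix(c(2, 4, 6, 8), ncol = 1, dimnames = list(NULL, "v"))
  fit <- fit_learner(learner_spec("SRE", list(q = 0)), x, rep(1, 4))
  newx <- matrix(c(5, 9), ncol = 1, dimnames = list(NULL, "v"))
  expect_equal(predict_suitability(fit, newx), c(1, 0))
})

test_that("GLM separates a linearly separable toy exactly", {
  x <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1, dimnames = list(NULL, "v"))
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_learner(learner_spec("GLM"), x, y)
  expect_equal(roc_auc(predict_suitability(fit, x), y), 1)
})

test_that("every registered learner fits and scores within [0, 1]", {
  cfg <- small_config(n = 20, seed = 21)
  st <- generate_env_stack(cfg)
  d <- build_design(st, toy_truth(st, c(soil_2 = 3, water_1 = -2),
                                  prevalence = 0.2), 40, seed = 5)
  x <- st$values[d$cells, 1:6]
  for (ln in learner_registry()) {
    fit <- fit_learner(learner_spec(ln, seed = 2), x, d$labels)
    p <- predict_suitability(fit, st$values[, 1:6])
    expect_length(p, n_cells(st$grid))
    expect_true(all(p >= 0 & p <= 1), info = ln)
  }
  expect_error(learner_spec("SVM"), "unknown learner")
})

test_that("truth-generated GLM recovers coefficient signs", {
  cfg <- landscape_config(n_rows = 30, n_cols = 30,
                          n_predictors_per_group = 1,
                          spatial_autocorrelation_range = 3, seed = 22)
  st <- generate_env_stack(cfg)   # 6 layers
  truth <- toy_truth(st, c(topographic_1 = 2, environmental_1 = -1.5),
                     prevalence = 0.25)
  hits <- 0L
  for (s in 1:20) {
    d <- build_design(st, truth, 200, seed = 50 + s)
    fit <- fit_learner(learner_spec("GLM"), st$values[d$cells, ], d$labels)
    cf <- coef(fit$model)
    if (cf[["topographic_1"]] > 0 && cf[["environmental_1"]] < 0) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 19L)
})

test_that("the gate requires all three metrics strictly above threshold", {
  sc <- data.frame(learner = c("A", "B", "C"),
                   kappa = c(0.8, 0.8, 0.9),
                   tss = c(0.8, 0.75, 0.9),
                   roc = c(0.8, 0.9, 0.74))
  expect_equal(gate_learners(sc), "A")
  # raising any learner's scores never shrinks the qualifier set
  set.seed(6)
  for (i in 1:20) {
    sc <- data.frame(learner = letters[1:5], kappa = runif(5),
                     tss = runif(5), roc = runif(5))
    before <- gate_learners(sc)
    j <- sample(5, 1)
    sc2 <- sc
    sc2[j, 2:4] <- pmin(1, unlist(sc[j, 2:4]) + runif(3, 0, 0.3))
    expect_true(all(before %in% gate_learners(sc2)))
  }
})

test_that("the weighted-mean ensemble follows the normalized weights", {
  one <- ensemble_weighted_mean(list(A = c(0.2, 0.9)), 0.8)
  expect_equal(one$values, c(0.2, 0.9))
  half <- ensemble_weighted_mean(list(A = rep(0.2, 3), B = rep(0.8, 3)),
                                 c(1, 1))
  expect_equal(half$values, rep(0.5, 3))
  w <- ensemble_weighted_mean(list(A = 0.6, B = 0.3), c(0.9, 0.45))
  expect_equal(w$values, (0.9 * 0.6 + 0.45 * 0.3) / 1.35)
  expect_equal(sum(w$weights), 1)
  expect_error(ensemble_weighted_mean(list(), numeric(0)), "no qualifying")
  # bounded by per-cell min and max of the members
  set.seed(7)
  surfs <- list(A = runif(50), B = runif(50), C = runif(50))
  ens <- ensemble_weighted_mean(surfs, runif(3, 0.5, 1))
  lo <- pmin(surfs$A, surfs$B, surfs$C)
  hi <- pmax(surfs$A, surfs$B, surfs$C)
  expect_true(all(ens$values >= lo - 1e-12 & ens$values <= hi + 1e-12))
})

test_that("suitability classes partition the surface at the cutpoints", {
  cls <- classify_suitability(c(0, 0.25, 0.4, 0.5, 0.74, 0.75, 1))
  expect_equal(as.character(cls),
               c("not", "slightly", "slightly", "moderately", "moderately",
                 "highly", "highly"))
  expect_error(classify_suitability(0.5, cutpoints = c(0.5, 0.4, 0.8)),
               "increasing")
  # uniform surface: ~25% per class within 3 binomial SE
  set.seed(8)
  u <- runif(10000)
  shares <- table(classify_suitability(u)) / 10000
  se3 <- 3 * sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(shares - 0.25) < se3))
})

test_that("run_all records one fit per species-learner pair and skips small species", {
  cfg <- small_config(n = 22, seed = 23)
  st <- generate_env_stack(cfg)
  truths <- list(
    AR = toy_truth(st, c(topographic_1 = 4, soil_1 = -3), 0.15, "AR"),
    CD = toy_truth(st, c(water_1 = 4, bioclimatic_2 = -3), 0.15, "CD"),
    HF = toy_truth(st, c(environmental_3 = 4), 0.15, "HF"))
  recs <- rbind(sample_occurrences(st, truths$AR, 60, 1)$records,
                sample_occurrences(st, truths$CD, 60, 2)$records,
                sample_occurrences(st, truths$HF, 5, 3)$records)
  occ <- occurrence_set(recs, st$grid)
  # the under-sampled species alone triggers the skip warning
  occ_small <- occurrence_set(recs[recs$species_code == "HF", ], st$grid)
  expect_warning(run_all(occ_small, st, learners = "GLM", seed = 4),
                 "skipped")
  run <- suppressWarnings(
    run_all(occ, st, predictors = colnames(st$values)[1:10], seed = 4))
  expect_equal(run$manifest$n_fits, 20L)
  expect_equal(run$manifest$skipped_species, "HF")
  expect_equal(nrow(run$evaluation), 20L)
  # one species, one learner
  occ1 <- occ_from_cells(st$grid, sample(n_cells(st$grid), 40), "AR")
  run1 <- suppressWarnings(run_all(occ1, st, learners = "GLM", seed = 5))
  expect_equal(run1$manifest$n_fits, 1L)
})
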