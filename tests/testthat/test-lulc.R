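test_that("overall accuracy follows the confusion-matrix arithmetic", {
  expect_equal(overall_accuracy(confusion_matrix(diag(c(10, 20, 30)))), 1)
  expect_equal(overall_accuracy(confusion_matrix(rbind(c(40, 10), c(5, 45)))),
               0.85)
  expect_equal(overall_accuracy(confusion_matrix(rbind(c(0, 7), c(9, 0)))), 0)
  expect_error(confusion_matrix(matrix(0, 2, 2)), "empty")
  expect_error(confusion_matrix(matrix(1, 2, 3)), "square")
})

test_that("kappa corrects agreement for chance", {
  expect_equal(kappa_coefficient(confusion_matrix(diag(c(5, 5)))), 1)
  expect_equal(kappa_coefficient(confusion_matrix(matrix(25, 2, 2))), 0)
  expect_equal(kappa_coefficient(confusion_matrix(rbind(c(40, 10),
                                                        c(20, 30)))), 0.4)
})

test_that("kappa is bounded and never exceeds accuracy when p_e > 0", {
  set.seed(1)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    cm <- confusion_matrix(matrix(rpois(k * k, 10), k, k))
    kap <- kappa_coefficient(cm)
    expect_gte(kap, -1)
    expect_lte(kap, 1)
    expect_lte(kap, overall_accuracy(cm) + 1e-12)
  }
})

test_that("change matrix cross-tabulates the two dates exactly", {
  # 2-cell toy: mangrove -> water, swamp -> swamp
  cm <- change_matrix(factor(c("mangrove", "swamp")),
                      factor(c("water", "swamp"),
                             levels = c("mangrove", "swamp", "water")))
  expect_equal(cm$counts["mangrove", "water"], 1L)
  expect_equal(cm$counts["swamp", "swamp"], 1L)
  expect_equal(sum(cm$counts), 2L)

  t1 <- factor(rep(c("a", "b"), 8))
  expect_true(all(change_matrix(t1, t1)$counts[upper.tri(diag(2))] == 0))
  expect_error(change_matrix(t1, t1[-1]), "cell count")
})

test_that("change-matrix margins conserve the class counts", {
  set.seed(7)
  classes <- letters[1:5]
  for (i in 1:100) {
    n <- sample(20:200, 1)
    t1 <- factor(sample(classes, n, replace = TRUE), levels = classes)
    t2 <- factor(sample(classes, n, replace = TRUE), levels = classes)
    cm <- change_matrix(t1, t2)
    expect_equal(unname(rowSums(cm$counts)),
                 as.vector(table(t1)[cm$classes_t1]), ignore_attr = TRUE)
    expect_equal(unname(colSums(cm$counts)),
                 as.vector(table(t2)[cm$classes_t2]), ignore_attr = TRUE)
  }
})

test_that("generator ground truth equals the downstream change matrix", {
  cfg <- small_config(n = 25)
  spec <- lulc_transition_spec()
  tp <- spec$transition_probabilities
  tp["mangrove", "mangrove"] <- 0.7
  tp["mangrove", "swamp"] <- 0.2
  tp["mangrove", "water"] <- 0.1
  pair <- generate_lulc_pair(cfg, lulc_transition_spec(spec$classes, tp),
                             seed = 13)
  cm <- change_matrix(pair)
  expect_equal(cm$counts[spec$classes, spec$classes],
               pair$truth_transitions, ignore_attr = TRUE)
})

test_that("gridwise stats handle the single-cell cases", {
  g1 <- grid_definition(1, 4)
  t1 <- matrix(c("mangrove", "mangrove", "water", "swamp"), 1)
  t2 <- matrix(c("mangrove", "water", "water", "mangrove"), 1)
  st <- gridwise_mangrove_stats(g1, t1, t2)
  # retained mangrove
  expect_equal(unlist(st[1, 2:4]),
               c(mangrove_cover_pct_t2 = 100, degradation_rate_pct = 0,
                 accretion_rate_pct = 0))
  # lost mangrove
  expect_equal(unlist(st[2, 2:4]),
               c(mangrove_cover_pct_t2 = 0, degradation_rate_pct = 100,
                 accretion_rate_pct = 0))
  # never mangrove: zero rates by convention, flagged
  expect_true(st$no_t1_mangrove[3])
  expect_equal(st$degradation_rate_pct[3], 0)
})

test_that("sub-grid maps aggregate by area fraction", {
  # first 1-km grid of a 2x2 lattice holds a 10x10 block: 60 mangrove cells
  # at date 1, 45 retained + 5 new at date 2 -> cover 50%, degradation 25%,
  # accretion 10%; the other three grids stay bare
  g <- grid_definition(2, 2)
  b1 <- matrix("other", 10, 10)
  b1[seq_len(60)] <- "mangrove"
  b2 <- matrix("other", 10, 10)
  b2[seq_len(45)] <- "mangrove"      # 45 of the 60 retained
  b2[61:65] <- "mangrove"            # 5 newly gained
  bare <- matrix("other", 10, 10)
  t1 <- rbind(cbind(b1, bare), cbind(bare, bare))
  t2 <- rbind(cbind(b2, bare), cbind(bare, bare))
  st <- gridwise_mangrove_stats(g, t1, t2)
  expect_equal(st$mangrove_cover_pct_t2[1], 50)
  expect_equal(st$degradation_rate_pct[1], 25)
  expect_equal(st$accretion_rate_pct[1], 10)
  expect_equal(st$mangrove_cover_pct_t2[2:4], rep(0, 3))
  expect_true(all(st$no_t1_mangrove[2:4]))
})

test_that("degraded area sums to the change-matrix total", {
  cfg <- small_config(n = 25)
  spec <- lulc_transition_spec()
  tp <- spec$transition_probabilities
  tp["mangrove", "mangrove"] <- 0.6
  tp["mangrove", "water"] <- 0.4
  pair <- generate_lulc_pair(cfg, lulc_transition_spec(spec$classes, tp),
                             seed = 2)
  st <- gridwise_mangrove_stats(pair$grid, pair$t1, pair$t2)
  cm <- change_matrix(pair)
  lost_cm <- sum(cm$counts["mangrove", ]) - cm$counts["mangrove", "mangrove"]
  # at grid resolution each cell is all-or-nothing: degraded cells have 100%
  lost_grid <- sum(st$degradation_rate_pct == 100 & !st$no_t1_mangrove)
  expect_equal(lost_grid, lost_cm)
})
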