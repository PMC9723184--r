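test_that("HDR spans 0 to 100 over the component extremes", {
  comp <- data.frame(BR = c(0, 100, 50), NP = c(0, 1000, 500),
                     RD = c(0, 8, 4), AR = c(0, 100, 50))
  hdr <- human_disturbance_rate(comp)
  expect_equal(hdr, c(0, 100, 50))
  expect_error(human_disturbance_rate(data.frame(BR = -1, NP = 0, RD = 0,
                                                 AR = 0)), "non-negative")
  expect_error(human_disturbance_rate(comp[1:3]), "columns")
})

test_that("HDR is monotone non-decreasing in every component", {
  set.seed(1)
  base <- data.frame(BR = runif(20, 0, 100), NP = runif(20, 0, 500),
                     RD = runif(20, 0, 5), AR = runif(20, 0, 100))
  h0 <- human_disturbance_rate(base)
  for (col in c("BR", "AR")) {   # bounded % components keep their scale
    up <- base
    up[[col]] <- pmin(100, up[[col]] + 10)
    expect_true(all(human_disturbance_rate(up) >= h0 - 1e-9))
  }
})

test_that("alternative HDR normalizations stay within bounds", {
  set.seed(2)
  comp <- data.frame(BR = runif(30, 0, 100), NP = rpois(30, 200),
                     RD = runif(30, 0, 6), AR = runif(30, 0, 100))
  for (norm in list("mean", "sum", c(2, 1, 1, 1))) {
    h <- human_disturbance_rate(comp, norm = norm)
    expect_true(all(h >= 0 & h <= 100))
  }
  expect_error(human_disturbance_rate(comp, norm = "median"), "norm")
})

test_that("priority ranks are a permutation and follow dominance", {
  attrs <- data.frame(
    species_code = c("HF", "AC", "SA", "NF"),
    niche_breadth = c(0.9, 0.2, 0.3, 0.25),
    potential_distribution = c(0.8, 0.2, 0.25, 0.3),
    degradation_exposure = c(90, 10, 15, 20),
    status_score = c(3, 1, 1, 1))
  ranked <- species_priority_rank(attrs)
  expect_setequal(ranked$priority_rank, 1:4)
  expect_equal(ranked$species_code[ranked$priority_rank == 1], "HF")
})

test_that("tied attribute rows get adjacent ranks broken by code", {
  attrs <- data.frame(
    species_code = c("XM", "AA", "AB"),
    niche_breadth = c(0.9, 0.4, 0.4),
    potential_distribution = c(0.8, 0.3, 0.3),
    degradation_exposure = c(80, 20, 20),
    status_score = c(3, 1, 1))
  ranked <- species_priority_rank(attrs)
  tied <- ranked[ranked$species_code %in% c("AA", "AB"), ]
  expect_equal(sort(tied$priority_rank), c(2, 3))
  expect_equal(tied$species_code[order(tied$priority_rank)], c("AA", "AB"))
})

test_that("a dominant variance axis dictates the ordering (eigen oracle)", {
  set.seed(3)
  n <- 12
  axis <- seq(-2, 2, length.out = n)
  attrs <- data.frame(
    species_code = sprintf("S%02d", 1:n),
    niche_breadth = axis + rnorm(n, sd = 0.01),
    potential_distribution = axis + rnorm(n, sd = 0.01),
    degradation_exposure = axis + rnorm(n, sd = 0.01),
    status_score = round(2 + axis / 2))
  ranked <- species_priority_rank(attrs)
  # PC1 of a rank-one structure is the axis itself
  expect_equal(ranked$species_code,
               attrs$species_code[order(-axis)])
  # constant attribute is dropped with a warning, not an error
  attrs$degradation_exposure <- 5
  expect_warning(species_priority_rank(attrs), "constant")
})

test_that("indicator flags honour strict thresholds and class logic", {
  lev <- c("not", "slightly", "moderately", "highly")
  cls <- factor(c("highly", "not", "moderately", "slightly"), levels = lev)
  fl <- flag_grid(cover_pct = c(95, 80, 10, 50), hdr = c(10, 76, 75, 20),
                  class_map = cls, accretion_pct = c(0, 80, 75, 10),
                  degradation_pct = c(90, 75, 76, 10),
                  overlap_significant = TRUE, rank_top_half = TRUE)
  expect_equal(fl$n1, c(TRUE, FALSE, FALSE, FALSE))   # 80 is not > 80
  expect_equal(fl$n2, c(FALSE, TRUE, FALSE, FALSE))   # 75 is not > 75
  expect_equal(fl$n4, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(fl$p4, c(TRUE, FALSE, TRUE, FALSE))
  # p3 and n3 are mutually exclusive by construction
  expect_true(all(xor(fl$n3, fl$p3)))
  expect_error(flag_grid(numeric(0), 1, cls[1], 1, 1, TRUE, TRUE),
               "missing input")
})

test_that("any negative flag vetoes prioritization over all 2^8 combinations", {
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 8))
  names(combos) <- c(paste0("n", 1:4), paste0("p", 1:4))
  for (rule in c("veto-and-one", "count", "weighted")) {
    pri <- prioritize(combos, rule = rule)
    neg <- combos$n1 | combos$n2 | combos$n3 | combos$n4
    expect_true(all(!pri[neg]), info = rule)
  }
  # default rule semantics on the positive-only rows
  pri <- prioritize(combos)
  pos_only <- !(combos$n1 | combos$n2 | combos$n3 | combos$n4)
  expected <- combos$p3 & (combos$p1 | combos$p2 | combos$p4)
  expect_equal(pri[pos_only], expected[pos_only])
  # p3 alone is not enough
  solo <- data.frame(n1 = FALSE, n2 = FALSE, n3 = FALSE, n4 = FALSE,
                     p1 = FALSE, p2 = FALSE, p3 = TRUE, p4 = FALSE)
  expect_false(prioritize(solo))
})

test_that("raising a veto threshold never increases the prioritized count", {
  set.seed(4)
  n <- 300
  lev <- c("not", "slightly", "moderately", "highly")
  cls <- factor(sample(lev, n, replace = TRUE), levels = lev)
  cover <- runif(n, 0, 100)
  hdr <- runif(n, 0, 100)
  accr <- runif(n, 0, 100)
  degr <- runif(n, 0, 100)
  count_at <- function(dth) {
    fl <- flag_grid(cover, hdr, cls, accr, degr, TRUE, TRUE,
                    thresholds = list(degradation = dth))
    sum(prioritize(fl))
  }
  counts <- vapply(seq(0, 100, by = 10), count_at, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("species map to their published restoration categories", {
  expect_equal(assign_category("HF"), 4L)
  expect_equal(assign_category("NF"), 5L)
  expect_equal(assign_category("AR"), 1L)
  expect_error(assign_category("ZZ"), "unknown species")
  expect_warning(lr <- assign_category("LR"), "no published")
  expect_true(is.na(lr))
  reg <- category_registry()
  expect_length(reg, 8)
  expect_setequal(unlist(reg[1:6]), setdiff(mangrove_species()$code, "LR"))
})

test_that("grid categories take the lowest fully-prioritized category", {
  grids <- 3
  pri <- lapply(setNames(nm = mangrove_species()$code),
                function(code) rep(FALSE, grids))
  # grid 1: full category 5 (NF + PP); grid 2: only HF; grid 3: nothing
  pri$NF[1] <- pri$PP[1] <- TRUE
  pri$HF[2] <- TRUE
  cats <- grid_category(pri)
  expect_equal(cats, c(5L, 4L, NA_integer_))
})
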