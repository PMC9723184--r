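#' Normalize a suitability surface to a probability distribution
#'
#' @param surface A `suitability_surface` or non-negative numeric vector
#'   with positive sum.
#' @return Numeric vector summing to 1.
#' @export
normalize_surface <- function(surface) {
  vals <- if (inherits(surface, "suitability_surface")) surface$values
          else surface
  if (any(vals < 0)) stop("surface has negative values", call. = FALSE)
  s <- sum(vals)
  if (s <= 0) stop("surface sums to zero; cannot normalize", call. = FALSE)
  vals / s
}

check_distribution <- function(p, name) {
  if (abs(sum(p) - 1) > 1e-6) {
    stop(name, " is not a normalized distribution", call. = FALSE)
  }
  invisible(TRUE)
}

#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum(|p1 - p2|)` over two normalized cellwise suitability
#' distributions; 1 for identical distributions, 0 for disjoint support.
#'
#' @param p1,p2 Normalized distributions on the same cells.
#' @return D in `[0, 1]`.
#' @export
#' @examples
#' schoener_D(c(0.5, 0.5, 0), c(0, 0.5, 0.5))  # 0.5
schoener_D <- function(p1, p2) {
  check_distribution(p1, "p1")
  check_distribution(p2, "p2")
  if (length(p1) != length(p2)) stop("supports differ", call. = FALSE)
  max(0, min(1, 1 - 0.5 * sum(abs(p1 - p2))))
}

#' Hellinger-based I niche overlap
#'
#' `I = 1 - 0.5 * sum((sqrt(p1) - sqrt(p2))^2)`, i.e. one minus half the
#' squared Hellinger distance between the two normalized distributions;
#' 1 for identical distributions, 0 at maximal Hellinger distance.
#'
#' @inheritParams schoener_D
#' @return I in `[0, 1]`.
#' @export
hellinger_I <- function(p1, p2) {
  check_distribution(p1, "p1")
  check_distribution(p2, "p2")
  if (length(p1) != length(p2)) stop("supports differ", call. = FALSE)
  max(0, min(1, 1 - 0.5 * sum((sqrt(p1) - sqrt(p2))^2)))
}

# fast surrogate suitability for permutation tests: SRE envelope or GLM
surrogate_surface <- function(cells, stack, method = c("sre", "glm"),
                              seed = 1L) {
  method <- match.arg(method)
  if (method == "sre") {
    pres <- stack$values[cells, , drop = FALSE]
    lo <- apply(pres, 2L, stats::quantile, probs = 0.025)
    hi <- apply(pres, 2L, stats::quantile, probs = 0.975)
    inside <- rep(TRUE, nrow(stack$values))
    for (j in seq_len(ncol(stack$values))) {
      inside <- inside & stack$values[, j] >= lo[j] &
        stack$values[, j] <= hi[j]
    }
    vals <- as.numeric(inside)
    if (sum(vals) == 0) vals <- rep(1 / length(vals), length(vals))
    vals
  } else {
    bg <- generate_pseudo_absences(stack$grid, cells, length(cells),
                                   seed = seed)
    x <- stack$values[c(cells, bg), , drop = FALSE]
    y <- c(rep(1, length(cells)), rep(0, length(bg)))
    df <- data.frame(.y = y, x, check.names = FALSE)
    fit <- suppressWarnings(
      stats::glm(.y ~ ., data = df, family = stats::binomial()))
    as.numeric(stats::predict(fit, newdata = as.data.frame(stack$values),
                              type = "response"))
  }
}

#' Niche-identity permutation test for a species pair
#'
#' Pools the two species' occurrences, randomly reassigns species labels
#' preserving the original counts, refits a fast surrogate suitability
#' model per pseudo-species and recomputes Schoener's D. The one-sided
#' p-value for the "overlap lower than random" alternative is
#' `(1 + #\{D_perm <= D_obs\}) / (n_perm + 1)`; the two-sided option doubles
#' the smaller tail.
#'
#' @param occA,occB `occurrence_set`s of the two species (single species
#'   each) on the stack's grid.
#' @param stack An `env_stack`.
#' @param n_perm Number of permutations (>= 19). Default 99.
#' @param seed Integer seed.
#' @param surrogate `"sre"` (default) or `"glm"` surrogate learner.
#' @param alternative `"less"` (default; overlap lower than the identity
#'   null) or `"two.sided"`.
#' @return List with `D_obs`, `p_value`, `null` (permuted D values).
#' @export
overlap_significance <- function(occA, occB, stack, n_perm = 99, seed = 1L,
                                 surrogate = c("sre", "glm"),
                                 alternative = c("less", "two.sided")) {
  surrogate <- match.arg(surrogate)
  alternative <- match.arg(alternative)
  if (n_perm < 19) stop("n_perm must be at least 19", call. = FALSE)
  cellsA <- occA$records$cell_id
  cellsB <- occB$records$cell_id
  if (length(cellsA) < 5 || length(cellsB) < 5) {
    stop("need at least 5 occurrences per species", call. = FALSE)
  }
  surf <- function(cells, s) normalize_surface(
    surrogate_surface(cells, stack, surrogate, seed = s))
  D_obs <- schoener_D(surf(cellsA, seed), surf(cellsB, seed + 1))

  pool <- c(cellsA, cellsB)
  nA <- length(cellsA)
  set.seed(seed)
  null <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    idx <- sample(length(pool))
    pa <- pool[idx[seq_len(nA)]]
    pb <- pool[idx[-seq_len(nA)]]
    null[i] <- schoener_D(surf(pa, seed + 2 * i), surf(pb, seed + 2 * i + 1))
  }
  p_less <- (1 + sum(null <= D_obs)) / (n_perm + 1)
  p <- if (alternative == "less") p_less else {
    p_great <- (1 + sum(null >= D_obs)) / (n_perm + 1)
    min(1, 2 * min(p_less, p_great))
  }
  list(D_obs = D_obs, p_value = p, null = null)
}

#' Pairwise overlap matrix over modelled species
#'
#' Computes Schoener's D and the Hellinger-based I for every species pair
#' from their normalized ensemble surfaces, and optionally the permutation
#' p-value for each pair. Diagonals are 1 by construction.
#'
#' @param surfaces Named list of suitability surfaces (or vectors), one per
#'   species.
#' @param occ Optional `occurrence_set` (required for p-values).
#' @param stack Optional `env_stack` (required for p-values).
#' @param n_perm Permutations per pair; 0 skips the tests. Default 0.
#' @param seed Integer seed.
#' @return An `overlap_matrix`: symmetric `D`, `I` and (optionally)
#'   `p_value` matrices over the species codes.
#' @export
overlap_matrix <- function(surfaces, occ = NULL, stack = NULL, n_perm = 0,
                           seed = 1L) {
  sp <- names(surfaces)
  k <- length(sp)
  p_list <- lapply(surfaces, normalize_surface)
  D <- diag(1, k)
  I <- diag(1, k)
  P <- matrix(NA_real_, k, k)
  dimnames(D) <- dimnames(I) <- dimnames(P) <- list(sp, sp)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      D[i, j] <- D[j, i] <- schoener_D(p_list[[i]], p_list[[j]])
      I[i, j] <- I[j, i] <- hellinger_I(p_list[[i]], p_list[[j]])
      if (n_perm > 0) {
        subocc <- function(code) occurrence_set(
          occ$records[occ$records$species_code == code, , drop = FALSE],
          occ$grid)
        sig <- overlap_significance(subocc(sp[i]), subocc(sp[j]), stack,
                                    n_perm = n_perm, seed = seed + i * k + j)
        P[i, j] <- P[j, i] <- sig$p_value
      }
    }
  }
  structure(list(species = sp, D = D, I = I,
                 p_value = if (n_perm > 0) P else NULL),
            class = "overlap_matrix")
}

#' Per-cell species richness of suitable habitat
#'
#' Spatial overlay of the per-species 4-class suitability maps: for every
#' grid cell, the count of species whose class there is moderately or
#' highly suitable.
#'
#' @param class_maps Named list of per-species class factors (from
#'   [classify_suitability()]), all on the same grid.
#' @return Integer vector, one count per cell.
#' @export
gridwise_overlap_layer <- function(class_maps) {
  lens <- lengths(class_maps)
  if (length(unique(lens)) != 1) {
    stop("class maps are on different grids", call. = FALSE)
  }
  counts <- integer(lens[1])
  for (cm in class_maps) {
    counts <- counts + (cm %in% c("moderately", "highly"))
  }
  counts
}
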