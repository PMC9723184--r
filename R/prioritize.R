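#' Synthetic per-grid disturbance components
#'
#' Generates the four human-disturbance components on the grid as smooth
#' correlated fields: built-up share (`BR`, percent), population count
#' (`NP`), road density (`RD`, km per cell) and agriculture share (`AR`,
#' percent). Built-up, population and roads co-locate (they share a latent
#' "settlement pressure" field), matching how disturbance clusters around
#' habitation in real coastal landscapes.
#'
#' @param config A [landscape_config()].
#' @param seed Integer seed.
#' @return A `disturbance_components` data.frame: `cell_id`, `BR`, `NP`,
#'   `RD`, `AR`.
#' @export
generate_disturbance_components <- function(config, seed = 1L) {
  grid <- config$grid
  set.seed(seed)
  lat <- function(sd) {
    f <- matrix(stats::rnorm(n_cells(grid)), grid$n_rows, grid$n_cols)
    v <- as.vector(t(smooth_field(f, sd)))
    (v - mean(v)) / stats::sd(v)
  }
  settlement <- lat(config$spatial_autocorrelation_range)
  agri <- lat(config$spatial_autocorrelation_range)
  noise <- function() stats::rnorm(n_cells(grid), sd = 0.3)
  out <- data.frame(
    cell_id = seq_len(n_cells(grid)),
    BR = 100 * stats::plogis(1.5 * (settlement + noise()) - 2),
    NP = round(exp(4 + 1.2 * (settlement + noise()))),
    RD = pmax(0, 2 + 1.5 * (settlement + noise())),
    AR = 100 * stats::plogis(1.2 * (agri + noise()) - 1)
  )
  class(out) <- c("disturbance_components", "data.frame")
  out
}

#' Human disturbance rate (HDR)
#'
#' Per-grid 0-100 composite of the four disturbance components. Each
#' component is first normalized to `[0, 1]` over the grid population —
#' the percentage components (`BR`, `AR`) by dividing by 100, the count
#' components (`NP`, `RD`) by their landscape maxima (min-max if a
#' component's minimum is positive) — and the HDR is 100 times the mean of
#' the four normalized components. Alternative aggregations are selected
#' through `norm`.
#'
#' @param components A data.frame with columns `BR`, `NP`, `RD`, `AR`.
#' @param norm `"mean"` (default), `"sum"` (capped at 100) or a numeric
#'   weight vector of length 4 (in BR, NP, RD, AR order) for a weighted
#'   mean.
#' @return Numeric HDR vector in `[0, 100]`, one value per grid.
#' @export
human_disturbance_rate <- function(components, norm = "mean") {
  need <- c("BR", "NP", "RD", "AR")
  if (!all(need %in% names(components))) {
    stop("components need columns BR, NP, RD, AR", call. = FALSE)
  }
  m <- as.matrix(components[need])
  if (any(!is.finite(m))) stop("components must be finite", call. = FALSE)
  if (any(m < 0)) stop("components must be non-negative", call. = FALSE)
  scale01 <- function(v, pct) {
    if (pct) return(v / 100)
    mx <- max(v)
    if (mx == 0) return(v)    # all-zero component stays 0
    (v - min(v) * 0) / mx     # divide by landscape maximum
  }
  z <- cbind(scale01(m[, "BR"], TRUE), scale01(m[, "NP"], FALSE),
             scale01(m[, "RD"], FALSE), scale01(m[, "AR"], TRUE))
  if (is.numeric(norm) && length(norm) == 4) {
    hdr <- 100 * drop(z %*% (norm / sum(norm)))
  } else if (identical(norm, "mean")) {
    hdr <- 100 * rowMeans(z)
  } else if (identical(norm, "sum")) {
    hdr <- pmin(100, 100 * rowSums(z))
  } else {
    stop("norm must be \"mean\", \"sum\" or 4 weights", call. = FALSE)
  }
  hdr
}

#' Per-species restoration-priority attributes
#'
#' Collects, for each modelled species, the four attributes the priority
#' ranking uses: niche breadth (Levins' B of the normalized ensemble
#' surface, rescaled to `[0, 1]`), potential distribution (fraction of
#' grids highly or moderately suitable), degradation exposure (mean
#' grid degradation rate over occupied grids) and the ordinal
#' conservation-status score (LC = 1, NT = 2, EN = 3).
#'
#' @param run An `sdm_run` from [run_all()].
#' @param occ The `occurrence_set` used for the run.
#' @param grid_stats Per-grid mangrove statistics from
#'   [gridwise_mangrove_stats()].
#' @param registry Species registry with `code` and `iucn_status` columns.
#'   Default [mangrove_species()].
#' @return Data.frame: `species_code`, `niche_breadth`,
#'   `potential_distribution`, `degradation_exposure`, `status_score`.
#' @export
species_priority_attributes <- function(run, occ, grid_stats,
                                        registry = mangrove_species()) {
  sp <- names(run$surfaces)
  rows <- lapply(sp, function(code) {
    p <- normalize_surface(run$surfaces[[code]])
    B <- 1 / sum(p^2)                       # Levins' niche breadth
    breadth <- (B - 1) / (length(p) - 1)    # rescaled to [0, 1]
    cm <- run$class_maps[[code]]
    pot <- mean(cm %in% c("moderately", "highly"))
    occ_cells <- occ$records$cell_id[occ$records$species_code == code]
    degr <- mean(grid_stats$degradation_rate_pct[
      grid_stats$cell_id %in% occ_cells])
    status <- registry$iucn_status[registry$code == code]
    if (length(status) != 1) {
      stop("species ", code, " missing from the registry", call. = FALSE)
    }
    data.frame(species_code = code, niche_breadth = breadth,
               potential_distribution = pot, degradation_exposure = degr,
               status_score = iucn_score(status))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' PCA-based species restoration-priority rank
#'
#' Standardizes the four priority attributes, projects the species onto
#' the first principal component, signs the axis so that a higher
#' conservation-status score maps to a higher priority score, and ranks by
#' descending score (rank 1 = highest restoration priority). Constant
#' attributes are dropped with a warning; ties are broken by status score
#' then species code.
#'
#' @param attrs Output of [species_priority_attributes()] (or any
#'   data.frame with `species_code`, `status_score` and numeric attribute
#'   columns).
#' @return `attrs` with added `priority_score` and `priority_rank`
#'   columns, ordered by rank.
#' @export
species_priority_rank <- function(attrs) {
  if (nrow(attrs) < 2) stop("need at least 2 species", call. = FALSE)
  num_cols <- setdiff(names(attrs)[vapply(attrs, is.numeric, logical(1))],
                      c("priority_score", "priority_rank"))
  m <- as.matrix(attrs[num_cols])
  keep <- apply(m, 2L, stats::sd) > 0
  if (any(!keep)) {
    warning("dropping constant attributes: ",
            paste(colnames(m)[!keep], collapse = ", "))
    m <- m[, keep, drop = FALSE]
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  score <- pc$x[, 1]
  # orient so higher conservation status means higher priority
  if ("status_score" %in% colnames(m)) {
    s <- stats::cor(score, attrs$status_score)
    if (!is.na(s) && s < 0) score <- -score
  }
  attrs$priority_score <- unname(score)
  ord <- order(-attrs$priority_score, -attrs$status_score,
               attrs$species_code)
  attrs <- attrs[ord, , drop = FALSE]
  attrs$priority_rank <- seq_len(nrow(attrs))
  rownames(attrs) <- NULL
  attrs
}

#' Negative and positive restoration indicator flags
#'
#' Evaluates the eight indicators for one species over all grids (all
#' comparisons strict):
#' negative — `n1` mangrove cover > 80% (already forested), `n2` HDR >
#' 75 (too disturbed), `n3` class not/slightly suitable, `n4` natural
#' accretion > 75% (self-recovering); positive — `p1` species priority
#' rank in the top half, `p2` species participates in a significant niche
#' overlap (p < 0.05) relevant to the grid, `p3` class highly/moderately
#' suitable, `p4` degradation > 75%.
#'
#' @param cover_pct Per-grid mangrove cover percent (date 2).
#' @param hdr Per-grid HDR values.
#' @param class_map Per-grid suitability class factor for the species.
#' @param accretion_pct,degradation_pct Per-grid rates.
#' @param overlap_significant Logical per grid: does a significant-overlap
#'   partner pair make this grid a joint high-suitability grid for the
#'   species? Scalar allowed (recycled).
#' @param rank_top_half Logical scalar: species priority rank in the top
#'   half.
#' @param thresholds Named list overriding the default cutoffs
#'   (`cover = 80`, `hdr = 75`, `accretion = 75`, `degradation = 75`).
#' @return Data.frame of logical columns `n1..n4`, `p1..p4`.
#' @export
flag_grid <- function(cover_pct, hdr, class_map, accretion_pct,
                      degradation_pct, overlap_significant, rank_top_half,
                      thresholds = list()) {
  th <- utils::modifyList(
    list(cover = 80, hdr = 75, accretion = 75, degradation = 75),
    thresholds)
  args <- list(cover_pct, hdr, accretion_pct, degradation_pct)
  n <- max(lengths(args), length(class_map))
  miss <- c("cover_pct", "hdr", "accretion_pct", "degradation_pct")[
    vapply(args, function(a) any(is.na(a)) || length(a) == 0, logical(1))]
  if (length(miss)) {
    stop("missing input: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  data.frame(
    n1 = rep_len(cover_pct > th$cover, n),
    n2 = rep_len(hdr > th$hdr, n),
    n3 = rep_len(class_map %in% c("not", "slightly"), n),
    n4 = rep_len(accretion_pct > th$accretion, n),
    p1 = rep_len(isTRUE(rank_top_half), n),
    p2 = rep_len(overlap_significant, n),
    p3 = rep_len(class_map %in% c("moderately", "highly"), n),
    p4 = rep_len(degradation_pct > th$degradation, n)
  )
}

#' Decide restoration prioritization from indicator flags
#'
#' Default rule ("veto-and-one"): a (species, grid) is prioritized iff no
#' negative flag is set, the grid is suitable for the species (`p3`), and
#' at least one further positive indicator (`p1`, `p2` or `p4`) supports
#' it. `"count"` mode instead requires at least `min_positives` positive
#' flags with no negative flag; `"weighted"` mode scores
#' `sum(w * positives)` against `score_threshold` with no negative flag.
#'
#' @param flags Data.frame with columns `n1..n4`, `p1..p4` (one row per
#'   grid, for one species).
#' @param rule `"veto-and-one"` (default), `"count"` or `"weighted"`.
#' @param min_positives For `"count"`. Default 2.
#' @param weights,score_threshold For `"weighted"`: weights over
#'   `p1..p4` and the score cutoff.
#' @return Logical vector: prioritized per grid.
#' @export
prioritize <- function(flags, rule = c("veto-and-one", "count", "weighted"),
                       min_positives = 2, weights = c(1, 1, 1, 1),
                       score_threshold = 2) {
  rule <- match.arg(rule)
  neg <- flags$n1 | flags$n2 | flags$n3 | flags$n4
  pos_m <- as.matrix(flags[c("p1", "p2", "p3", "p4")])
  out <- switch(rule,
    "veto-and-one" = !neg & flags$p3 & (flags$p1 | flags$p2 | flags$p4),
    "count" = !neg & rowSums(pos_m) >= min_positives,
    "weighted" = !neg & drop(pos_m %*% weights) > score_threshold
  )
  unname(out)
}

#' Restoration category registry
#'
#' The eight published restoration categories over the species registry:
#' six single-family categories partitioning 17 of the 18 species, a mixed
#' category (7) and a common-species category (8). Lumnitzera racemosa
#' (LR) belongs to no category in the published scheme.
#'
#' @return Named list of species-code vectors, one per category `1`-`8`.
#' @export
category_registry <- function() {
  list(
    `1` = c("AR", "AC"),
    `2` = c("AA", "AM", "AO"),
    `3` = c("BG", "CD", "CT", "RM"),
    `4` = c("HF", "KC", "EA"),
    `5` = c("NF", "PP"),
    `6` = c("SA", "XG", "XM"),
    `7` = c("AA", "AM", "AO", "BG", "CD", "CT", "RM"),
    `8` = c("AR", "AC", "AA", "AM", "AO")
  )
}

#' Restoration category of a species
#'
#' Returns the lowest-numbered category containing the species (a species
#' may additionally appear in the mixed and common categories 7-8).
#' LR, which the published scheme leaves uncategorized, returns `NA` with
#' a warning; codes outside the registry are an error.
#'
#' @param species_code A registered species code.
#' @return Integer category (1-8), or `NA` for an uncategorized species.
#' @export
#' @examples
#' assign_category("HF")  # 4
assign_category <- function(species_code) {
  if (!species_code %in% mangrove_species()$code) {
    stop("unknown species code: ", species_code, call. = FALSE)
  }
  reg <- category_registry()
  hit <- which(vapply(reg, function(s) species_code %in% s, logical(1)))
  if (!length(hit)) {
    warning("species ", species_code,
            " belongs to no published restoration category")
    return(NA_integer_)
  }
  as.integer(names(reg)[hit[1]])
}

#' Grid-level restoration category
#'
#' For each grid, the lowest-numbered category whose full species set is
#' prioritized in that grid; failing that, the single-species category of
#' any prioritized species there (lowest number); `NA` where nothing is
#' prioritized.
#'
#' @param prioritized Named list (by species code) of logical per-grid
#'   prioritization vectors.
#' @return Integer vector of categories per grid (`NA` = none).
#' @export
grid_category <- function(prioritized) {
  reg <- category_registry()
  n <- length(prioritized[[1]])
  sp_codes <- names(prioritized)
  m <- do.call(cbind, prioritized)   # grids x species
  out <- rep(NA_integer_, n)
  for (cat_name in names(reg)) {     # ascending category number
    members <- reg[[cat_name]]
    if (!all(members %in% sp_codes)) next
    full <- rowSums(m[, members, drop = FALSE]) == length(members)
    out[is.na(out) & full] <- as.integer(cat_name)
  }
  # fall back to the single-species category of any prioritized species
  single_cat <- suppressWarnings(
    vapply(sp_codes, assign_category, integer(1)))
  for (j in order(single_cat)) {
    if (is.na(single_cat[j])) next
    hit <- is.na(out) & m[, j]
    out[hit] <- single_cat[j]
  }
  out
}
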