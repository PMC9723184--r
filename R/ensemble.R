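#' Sample pseudo-absence (background) cells
#'
#' Uniform random draw of unoccupied cells, one point per cell, seeded.
#' Background points stand in for the absences that presence-only
#' occurrence data do not record.
#'
#' @param grid A [grid_definition()].
#' @param occupied_cells Integer cell ids holding presences of the species.
#' @param n Number of background cells to draw.
#' @param seed Integer seed.
#' @return Integer vector of background cell ids.
#' @export
generate_pseudo_absences <- function(grid, occupied_cells, n, seed = 1L) {
  free <- setdiff(seq_len(n_cells(grid)), occupied_cells)
  if (n > length(free)) {
    stop("requested more background cells than unoccupied cells",
         call. = FALSE)
  }
  if (n == 0) return(integer(0))
  set.seed(seed)
  sort(sample(free, n, replace = FALSE))
}

#' Nested train / intrinsic-test / extrinsic-holdout split
#'
#' Stratified by label: an extrinsic holdout (default 20%) is set aside
#' first for final validation, then the remaining 80% is split 75/25 into
#' training and intrinsic test sets used for per-learner evaluation and
#' gating. Partitions are disjoint and exhaustive; the split is redrawn (up
#' to 10 times) if any partition loses a class.
#'
#' @param labels 0/1 label vector; indices refer to the caller's rows.
#' @param extrinsic_frac Fraction held out for extrinsic validation.
#' @param intrinsic_test_frac Fraction of the remainder used as intrinsic
#'   test.
#' @param seed Integer seed.
#' @return List of integer index vectors `train`, `intrinsic_test`,
#'   `extrinsic`.
#' @export
split_data <- function(labels, extrinsic_frac = 0.2,
                       intrinsic_test_frac = 0.25, seed = 1L) {
  if (sum(labels == 1) < 8) {
    stop("need at least 8 presences to split", call. = FALSE)
  }
  set.seed(seed)
  for (attempt in 1:10) {
    ext <- integer(0)
    itest <- integer(0)
    train <- integer(0)
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      n_ext <- round(length(idx) * extrinsic_frac)
      ext <- c(ext, idx[seq_len(n_ext)])
      rest <- idx[-seq_len(n_ext)]
      n_it <- round(length(rest) * intrinsic_test_frac)
      itest <- c(itest, rest[seq_len(n_it)])
      train <- c(train, rest[-seq_len(n_it)])
    }
    ok <- all(vapply(list(train, itest, ext),
                     function(i) length(unique(labels[i])) == 2, logical(1)))
    if (ok) {
      return(list(train = sort(train), intrinsic_test = sort(itest),
                  extrinsic = sort(ext)))
    }
  }
  stop("could not produce a split with both classes in every partition",
       call. = FALSE)
}

#' Gate learners on intrinsic validation scores
#'
#' A learner qualifies for the ensemble only if its intrinsic kappa, TSS
#' and ROC all exceed the gate (strictly; default 0.75 on each).
#'
#' @param scores Data.frame with columns `learner`, `kappa`, `tss`, `roc`.
#' @param threshold Gate value applied to all three metrics. Default 0.75.
#' @return Character vector of qualifying learner names.
#' @export
gate_learners <- function(scores, threshold = 0.75) {
  ok <- scores$kappa > threshold & scores$tss > threshold &
    scores$roc > threshold
  scores$learner[ok]
}

#' Weighted-mean ensemble of suitability surfaces
#'
#' Per-cell weighted mean of the qualifying learners' surfaces, with
#' weights proportional to each learner's validation metric (TSS by
#' convention), normalized to sum to one.
#'
#' @param surfaces Named list of numeric suitability vectors on one grid.
#' @param weights Positive metric values, one per surface.
#' @return A `suitability_surface`: `values` in `[0, 1]`, plus learner
#'   provenance and normalized weights.
#' @export
ensemble_weighted_mean <- function(surfaces, weights) {
  if (length(surfaces) == 0) {
    stop("no qualifying learners: cannot build an ensemble", call. = FALSE)
  }
  if (length(weights) != length(surfaces)) {
    stop("one weight per surface required", call. = FALSE)
  }
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative with positive sum", call. = FALSE)
  }
  lens <- lengths(surfaces)
  if (length(unique(lens)) != 1) {
    stop("surfaces differ in length", call. = FALSE)
  }
  w <- weights / sum(weights)
  vals <- Reduce(`+`, Map(function(s, wi) s * wi, surfaces, w))
  structure(list(values = vals,
                 learners = names(surfaces),
                 weights = stats::setNames(w, names(surfaces))),
            class = "suitability_surface")
}

#' Discretize a suitability surface into 4 classes
#'
#' Fixed cutpoints (default 0.25 / 0.50 / 0.75) partition the continuous
#' suitability into `not`, `slightly`, `moderately` and `highly` suitable;
#' each boundary value upgrades to the higher class (`value >= cut` is the
#' higher class). Quantile cutpoints can be requested instead.
#'
#' @param surface A `suitability_surface` or numeric vector in `[0, 1]`.
#' @param cutpoints Three strictly increasing values in (0, 1).
#' @param quantile_mode If `TRUE`, `cutpoints` are interpreted as
#'   probabilities and replaced by the surface's quantiles.
#' @return Ordered factor over
#'   `c("not", "slightly", "moderately", "highly")` with the cutpoints as
#'   an attribute.
#' @export
classify_suitability <- function(surface, cutpoints = c(0.25, 0.5, 0.75),
                                 quantile_mode = FALSE) {
  vals <- if (inherits(surface, "suitability_surface")) surface$values
          else surface
  if (length(cutpoints) != 3 || any(diff(cutpoints) <= 0)) {
    stop("cutpoints must be 3 strictly increasing values", call. = FALSE)
  }
  if (quantile_mode) {
    cutpoints <- unname(stats::quantile(vals, probs = cutpoints))
    if (any(diff(cutpoints) <= 0)) {
      stop("quantile cutpoints are not strictly increasing", call. = FALSE)
    }
  }
  lev <- c("not", "slightly", "moderately", "highly")
  cls <- lev[1 + (vals >= cutpoints[1]) + (vals >= cutpoints[2]) +
               (vals >= cutpoints[3])]
  out <- factor(cls, levels = lev, ordered = TRUE)
  attr(out, "cutpoints") <- cutpoints
  out
}

#' Fit, gate, ensemble and validate every species
#'
#' The per-species workflow: draw 1:1 pseudo-absences, make the nested
#' 80/20 then 75/25 split, fit every registry learner on the training
#' partition, score each on the intrinsic test set (ROC, and TSS/kappa at
#' the max-TSS threshold), gate at the strict threshold, combine the
#' qualifying learners' full-landscape predictions as a TSS-weighted mean,
#' and validate the ensemble with the continuous Boyce index on the
#' extrinsic presence holdout against the landscape background. Species
#' with fewer presences than `min_presences` are skipped with a warning
#' and recorded.
#'
#' @param occ An `occurrence_set` holding all species.
#' @param stack An `env_stack` of predictors.
#' @param learners Learner names to run. Default: the full registry.
#' @param predictors Optional named list (per species) or character vector
#'   of predictor layer names; default all stack layers for every species.
#' @param gate_threshold Strict gate on kappa, TSS and ROC. Default 0.75.
#' @param weights_metric `"tss"` (default), `"roc"` or `"equal"` ensemble
#'   weighting.
#' @param cutpoints Suitability class cutpoints.
#' @param min_presences Minimum rarefied presences per species. Default 10.
#' @param pseudo_absence_ratio Background:presence ratio. Default 1.
#' @param seed Integer master seed.
#' @return An `sdm_run`: per-species `surfaces` (suitability vectors),
#'   `class_maps`, `evaluation` (per species x learner scores), `report`
#'   (per-species ensemble row: Boyce, qualifiers), and a `manifest`
#'   recording counts, seeds and gate decisions (`manifest$n_fits` is the
#'   number of intrinsic model fits performed).
#' @export
run_all <- function(occ, stack, learners = learner_registry(),
                    predictors = NULL, gate_threshold = 0.75,
                    weights_metric = c("tss", "roc", "equal"),
                    cutpoints = c(0.25, 0.5, 0.75), min_presences = 10,
                    pseudo_absence_ratio = 1, seed = 1L) {
  stopifnot(inherits(occ, "occurrence_set"), inherits(stack, "env_stack"))
  weights_metric <- match.arg(weights_metric)
  species <- sort(unique(occ$records$species_code))
  surfaces <- list()
  class_maps <- list()
  eval_rows <- list()
  report_rows <- list()
  skipped <- character(0)
  no_qualifier <- character(0)
  n_fits <- 0L

  for (sp in species) {
    pres_cells <- occ$records$cell_id[occ$records$species_code == sp]
    if (length(pres_cells) < min_presences) {
      warning("species ", sp, " has ", length(pres_cells),
              " presences (< ", min_presences, "); skipped")
      skipped <- c(skipped, sp)
      next
    }
    sp_seed <- seed + match(sp, species)
    bg_cells <- generate_pseudo_absences(
      stack$grid, pres_cells,
      round(pseudo_absence_ratio * length(pres_cells)), seed = sp_seed)
    cells <- c(pres_cells, bg_cells)
    labels <- c(rep(1L, length(pres_cells)), rep(0L, length(bg_cells)))
    layer_names <- if (is.null(predictors)) colnames(stack$values)
      else if (is.list(predictors)) predictors[[sp]]
      else predictors
    x_all <- stack$values[, layer_names, drop = FALSE]
    x <- x_all[cells, , drop = FALSE]

    parts <- split_data(labels, seed = sp_seed)
    sp_scores <- list()
    sp_surfaces <- list()
    for (ln in learners) {
      fit <- fit_learner(learner_spec(ln, seed = sp_seed),
                         x[parts$train, , drop = FALSE],
                         labels[parts$train])
      n_fits <- n_fits + 1L
      sc <- predict_suitability(fit, x[parts$intrinsic_test, , drop = FALSE])
      es <- eval_scores(sc, labels[parts$intrinsic_test])
      sp_scores[[ln]] <- cbind(data.frame(species_code = sp, learner = ln),
                               es)
      sp_surfaces[[ln]] <- predict_suitability(fit, x_all)
    }
    scores_df <- do.call(rbind, sp_scores)
    rownames(scores_df) <- NULL
    eval_rows[[sp]] <- scores_df

    qual <- gate_learners(scores_df, gate_threshold)
    if (length(qual) == 0) {
      warning("species ", sp, ": no learner passed the ",
              gate_threshold, " gate; no ensemble built")
      no_qualifier <- c(no_qualifier, sp)
      next
    }
    w <- switch(weights_metric,
                tss = scores_df$tss[match(qual, scores_df$learner)],
                roc = scores_df$roc[match(qual, scores_df$learner)],
                equal = rep(1, length(qual)))
    ens <- ensemble_weighted_mean(sp_surfaces[qual], w)
    surfaces[[sp]] <- ens
    class_maps[[sp]] <- classify_suitability(ens, cutpoints)

    # extrinsic validation: Boyce on the 20% presence holdout vs landscape
    ext_pres <- cells[parts$extrinsic][labels[parts$extrinsic] == 1]
    boyce <- tryCatch(
      boyce_index(ens$values[ext_pres], ens$values),
      error = function(e) NA_real_)
    report_rows[[sp]] <- data.frame(
      species_code = sp, n_presences = length(pres_cells),
      n_qualifiers = length(qual),
      qualifiers = paste(qual, collapse = "+"),
      boyce = boyce)
  }

  evaluation <- do.call(rbind, eval_rows)
  rownames(evaluation) <- NULL
  report <- do.call(rbind, report_rows)
  if (!is.null(report)) rownames(report) <- NULL
  structure(
    list(surfaces = surfaces, class_maps = class_maps,
         evaluation = evaluation, report = report,
         manifest = list(
           n_fits = n_fits,
           n_species_run = length(species) - length(skipped),
           n_learners = length(learners),
           learners = learners,
           skipped_species = skipped,
           no_qualifier_species = no_qualifier,
           gate_threshold = gate_threshold,
           weights_metric = weights_metric,
           seed = seed)),
    class = "sdm_run"
  )
}

#' @export
print.sdm_run <- function(x, ...) {
  cat(sprintf(
    "<sdm_run> %d intrinsic fits (%d species x %d learners), %d ensembles\n",
    x$manifest$n_fits, x$manifest$n_species_run, x$manifest$n_learners,
    length(x$surfaces)))
  invisible(x)
}
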