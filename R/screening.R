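#' Greedy collinearity filter
#'
#' While any pair of layers has `|Pearson r| > r_max`, drops the member of
#' the currently worst pair whose mean absolute correlation to all other
#' remaining layers is larger. Ties are broken by layer name so the result
#' does not depend on input layer order. Constant layers cannot enter the
#' correlation and are excluded up front with a warning.
#'
#' @param stack An `env_stack`.
#' @param r_max Pairwise absolute-correlation ceiling, in (0, 1).
#'   Default 0.8.
#' @return Character vector of retained layer names.
#' @export
collinearity_filter <- function(stack, r_max = 0.8) {
  if (r_max <= 0 || r_max >= 1) stop("r_max must be in (0,1)", call. = FALSE)
  v <- stack$values
  if (ncol(v) < 2) stop("need at least 2 layers", call. = FALSE)
  const <- apply(v, 2L, function(x) stats::sd(x) == 0)
  if (any(const)) {
    warning("excluding constant layers: ",
            paste(colnames(v)[const], collapse = ", "))
    v <- v[, !const, drop = FALSE]
  }
  keep <- sort(colnames(v))
  r <- abs(stats::cor(v[, keep, drop = FALSE]))
  diag(r) <- 0
  while (length(keep) > 1 && max(r) > r_max) {
    worst <- which(r == max(r), arr.ind = TRUE)[1, ]
    pair <- keep[worst]
    mean_abs <- vapply(pair, function(nm) {
      others <- setdiff(keep, nm)
      mean(r[nm, others])
    }, numeric(1))
    # drop the more globally correlated member; name order breaks exact ties
    drop_nm <- pair[order(-mean_abs, pair)][1]
    keep <- setdiff(keep, drop_nm)
    r <- r[keep, keep, drop = FALSE]
  }
  keep
}

#' PCA reduction of a bioclimatic layer set
#'
#' Removes redundancy among correlated bioclimatic layers: principal
#' components are computed on the standardized layers, variables are ranked
#' by their maximum absolute loading across the components needed to reach
#' at least 90% cumulative variance, and the top `k` distinct variables are
#' returned. "Distinct" is enforced during the greedy pick: a candidate
#' correlated above `redundancy_r` with an already selected variable is
#' skipped, so the budget is not spent on near-copies of one signal.
#'
#' @param bioclim An `env_stack` of bioclimatic layers (19 in the standard
#'   catalogue).
#' @param k Number of variables to select. Default 6.
#' @param var_target Cumulative variance fraction defining how many
#'   components are inspected. Default 0.9.
#' @param redundancy_r Absolute-correlation ceiling between selected
#'   variables. Default 0.8, matching [collinearity_filter()].
#' @return Character vector of `k` selected layer names.
#' @export
pca_reduce_bioclim <- function(bioclim, k = 6, var_target = 0.9,
                               redundancy_r = 0.8) {
  v <- bioclim$values
  if (k > ncol(v)) stop("k exceeds the number of layers", call. = FALSE)
  if (k == ncol(v)) return(colnames(v))
  pc <- stats::prcomp(v, center = TRUE, scale. = TRUE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  n_comp <- which(cum >= var_target)[1]
  # loadings in the factor-analytic sense (eigenvector * sdev), i.e. the
  # variable-component correlations, so low-variance components do not
  # dominate the ranking
  load <- abs(sweep(pc$rotation[, seq_len(n_comp), drop = FALSE], 2L,
                    pc$sdev[seq_len(n_comp)], `*`))
  score <- apply(load, 1L, max)
  ranked <- names(sort(score, decreasing = TRUE))
  cr <- abs(stats::cor(v))
  chosen <- character(0)
  for (nm in ranked) {
    if (length(chosen) == k) break
    if (length(chosen) && any(cr[nm, chosen] > redundancy_r)) next
    chosen <- c(chosen, nm)
  }
  # backfill from the ranking if the redundancy skip exhausted candidates
  if (length(chosen) < k) {
    chosen <- c(chosen, setdiff(ranked, chosen)[seq_len(k - length(chosen))])
  }
  chosen
}

#' Linear-SVM average merit of predictors
#'
#' Per species, fits a soft-margin linear support-vector classifier
#' (decision function `g(x) = sgn(w'a + b)`, cost C = 1) separating
#' presences from background points on the standardized predictors, and
#' maps the absolute weights onto the 1-10 "average merit" scale by
#' min-max scaling: `merit_i = 1 + 9 (|w_i| - min|w|) / (max|w| - min|w|)`.
#' Predictors with merit above 5 are flagged as influential for the
#' species' habitat model.
#'
#' @param occ An `occurrence_set` (may hold several species).
#' @param stack An `env_stack` of standardized predictors.
#' @param background Optional data.frame of background points with a
#'   `cell_id` column per species; by default, for each species, unoccupied
#'   cells are drawn uniformly at a 1:1 ratio under `seed`.
#' @param cost Soft-margin cost. Default 1.
#' @param seed Integer seed for background sampling.
#' @return A `MeritTable` data.frame: `species_code`, `predictor`,
#'   `average_merit`, `influential`; plus a pooled summary attribute
#'   `"pooled"` (mean merit per predictor across species).
#' @export
lsvm_average_merit <- function(occ, stack, background = NULL, cost = 1,
                               seed = 1L) {
  stopifnot(inherits(occ, "occurrence_set"), inherits(stack, "env_stack"))
  species <- sort(unique(occ$records$species_code))
  out <- list()
  for (sp in species) {
    pres_cells <- occ$records$cell_id[occ$records$species_code == sp]
    if (length(pres_cells) < 10) {
      stop("need at least 10 presences for species ", sp, call. = FALSE)
    }
    if (is.null(background)) {
      bg_cells <- generate_pseudo_absences(
        stack$grid, pres_cells, length(pres_cells),
        seed = seed + match(sp, species))
    } else {
      bg_cells <- background$cell_id[background$species_code == sp]
    }
    x <- stack$values[c(pres_cells, bg_cells), , drop = FALSE]
    y <- factor(c(rep(1, length(pres_cells)), rep(0, length(bg_cells))),
                levels = c(0, 1))
    if (length(unique(y)) < 2) {
      stop("degenerate fit: only one class present", call. = FALSE)
    }
    fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
    w <- abs(drop(crossprod(fit$coefs, fit$SV)))
    names(w) <- colnames(x)
    rng <- max(w) - min(w)
    if (length(w) == 1L) {
      merit <- 10  # a lone predictor is the maximum of its own scale
    } else if (rng < .Machine$double.eps) {
      warning("all |w| equal for species ", sp, "; merits set to 5.5")
      merit <- rep(5.5, length(w))
    } else {
      merit <- 1 + 9 * (w - min(w)) / rng
    }
    out[[sp]] <- data.frame(species_code = sp, predictor = names(w),
                            average_merit = unname(merit),
                            influential = unname(merit) > 5,
                            row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  pooled <- stats::aggregate(average_merit ~ predictor, data = res, FUN = mean)
  attr(res, "pooled") <- pooled
  res
}
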