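#' The 10-learner registry
#'
#' Names of the habitat-suitability algorithms fitted per species:
#' MAXENT (L1-regularized logistic regression on linear, quadratic and
#' product features of presences vs background), GLM (logistic-link linear
#' model), MARS (adaptive piecewise-linear hinge-basis regression), GAM
#' (logistic-link additive model with smooth terms), RF (random forest),
#' GBM (boosted shallow trees), CTA (single classification tree), ANN
#' (one-hidden-layer feed-forward network), FDA (flexible discriminant
#' analysis: LDA on a basis expansion) and SRE (surface range envelope:
#' percentile envelope of the presence values).
#'
#' @return Character vector of the 10 learner names.
#' @export
learner_registry <- function() {
  c("MAXENT", "GLM", "MARS", "GAM", "RF", "GBM", "CTA", "ANN", "FDA", "SRE")
}

#' Specify a learner
#'
#' @param name A name from [learner_registry()].
#' @param hyperparameters Named list overriding the small desk-scale
#'   defaults (e.g. `ntree`, `nrounds`, `size`, `q`).
#' @param seed Integer seed used when fitting (weight initialisation,
#'   bagging, cross-validation folds).
#' @return A `learner_spec`.
#' @export
learner_spec <- function(name, hyperparameters = list(), seed = 1L) {
  if (!name %in% learner_registry()) {
    stop("unknown learner: ", name, " (registry: ",
         paste(learner_registry(), collapse = ", "), ")", call. = FALSE)
  }
  structure(list(name = name, hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "learner_spec")
}

hp <- function(spec, key, default) {
  if (!is.null(spec$hyperparameters[[key]])) spec$hyperparameters[[key]]
  else default
}

# linear + quadratic + pairwise-product feature expansion
maxent_features <- function(x) {
  p <- ncol(x)
  feats <- list(x, x^2)
  cn <- c(colnames(x), paste0(colnames(x), "_sq"))
  if (p >= 2) {
    idx <- utils::combn(p, 2)
    prod_m <- x[, idx[1, ], drop = FALSE] * x[, idx[2, ], drop = FALSE]
    colnames(prod_m) <- paste0(colnames(x)[idx[1, ]], "_x_",
                               colnames(x)[idx[2, ]])
    feats <- c(feats, list(prod_m))
    cn <- c(cn, colnames(prod_m))
  }
  out <- do.call(cbind, feats)
  colnames(out) <- cn
  out
}

# simple quadratic basis for FDA, capped to keep LDA well-posed
fda_features <- function(x, n) {
  out <- cbind(x, x^2)
  colnames(out) <- c(colnames(x), paste0(colnames(x), "_sq"))
  keep <- apply(out, 2L, stats::sd) > 1e-10
  out <- out[, keep, drop = FALSE]
  cap <- max(2L, floor(n / 3))
  if (ncol(out) > cap) out <- out[, seq_len(cap), drop = FALSE]
  out
}

# forward hinge-basis selection for the MARS-style learner
fit_mars_basis <- function(x, y, max_pairs = 8, n_knots = 5) {
  n <- nrow(x)
  cand <- list()
  for (j in seq_len(ncol(x))) {
    ks <- unique(stats::quantile(x[, j], probs = seq(0.15, 0.85,
                                                     length.out = n_knots)))
    for (k in ks) cand[[length(cand) + 1L]] <- c(j, k)
  }
  basis <- matrix(1, n, 1)
  terms <- list()
  dev_cur <- suppressWarnings(
    stats::glm.fit(basis, y, family = stats::binomial())$deviance)
  for (step in seq_len(max_pairs)) {
    best <- NULL
    best_dev <- dev_cur - 1e-6
    for (cd in cand) {
      j <- cd[1]; k <- cd[2]
      pair <- cbind(pmax(0, x[, j] - k), pmax(0, k - x[, j]))
      b <- cbind(basis, pair)
      if (qr(b)$rank < ncol(b)) next
      dev <- suppressWarnings(tryCatch(
        stats::glm.fit(b, y, family = stats::binomial())$deviance,
        error = function(e) Inf))
      if (dev < best_dev) {
        best_dev <- dev
        best <- cd
      }
    }
    if (is.null(best) || dev_cur - best_dev < 1e-4 * n) break
    j <- best[1]; k <- best[2]
    basis <- cbind(basis, pmax(0, x[, j] - k), pmax(0, k - x[, j]))
    terms[[length(terms) + 1L]] <- best
    dev_cur <- best_dev
  }
  fit <- suppressWarnings(
    stats::glm.fit(basis, y, family = stats::binomial()))
  list(coef = fit$coefficients, terms = terms)
}

mars_basis_matrix <- function(x, terms) {
  basis <- matrix(1, nrow(x), 1)
  for (cd in terms) {
    j <- cd[1]; k <- cd[2]
    basis <- cbind(basis, pmax(0, x[, j] - k), pmax(0, k - x[, j]))
  }
  basis
}

#' Fit one learner on a presence/background training set
#'
#' All learners are fitted as presence-vs-background classifiers and
#' return a scorer mapping a feature matrix to suitabilities in `[0, 1]`.
#' SRE uses presences only (percentile envelope with tail fraction `q`,
#' default 0.025). Hyperparameter defaults are deliberately small so a full
#' multi-species run stays at desk scale; all are overridable through the
#' [learner_spec()].
#'
#' @param spec A [learner_spec()].
#' @param x Numeric feature matrix (rows = training points).
#' @param y 0/1 labels (1 = presence).
#' @return A `fitted_learner`; score new data with [predict_suitability()].
#' @export
fit_learner <- function(spec, x, y) {
  stopifnot(inherits(spec, "learner_spec"))
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("v", seq_len(ncol(x)))
  if (spec$name != "SRE") {
    if (length(unique(y)) < 2) {
      stop("training data must contain both classes", call. = FALSE)
    }
  }
  set.seed(spec$seed)
  n <- nrow(x)
  model <- NULL
  extra <- list()

  if (spec$name == "GLM") {
    df <- data.frame(.y = y, x, check.names = FALSE)
    model <- suppressWarnings(
      stats::glm(.y ~ ., data = df, family = stats::binomial()))
  } else if (spec$name == "GAM") {
    # cap smooth terms so the additive model stays identifiable at small n
    k <- hp(spec, "k", 4)
    max_p <- max(1L, floor((n / 2 - 1) / (k - 1)))
    vars <- colnames(x)
    if (length(vars) > max_p) {
      sc <- abs(apply(x, 2L, function(v) stats::cor(v, y)))
      vars <- names(sort(sc, decreasing = TRUE))[seq_len(max_p)]
    }
    df <- data.frame(.y = y, x, check.names = FALSE)
    fml <- stats::as.formula(paste(
      ".y ~", paste(sprintf("s(`%s`, k = %d)", vars, k), collapse = " + ")))
    model <- mgcv::gam(fml, data = df, family = stats::binomial(),
                       method = "REML")
  } else if (spec$name == "MARS") {
    model <- fit_mars_basis(x, y,
                            max_pairs = hp(spec, "max_pairs", 8),
                            n_knots = hp(spec, "n_knots", 5))
  } else if (spec$name == "RF") {
    model <- randomForest::randomForest(
      x, factor(y, levels = c(0, 1)), ntree = hp(spec, "ntree", 100))
  } else if (spec$name == "GBM") {
    model <- xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = hp(spec, "max_depth", 3),
                    eta = hp(spec, "eta", 0.1), nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = hp(spec, "nrounds", 50))
  } else if (spec$name == "CTA") {
    df <- data.frame(.y = factor(y, levels = c(0, 1)), x,
                     check.names = FALSE)
    model <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            cp = hp(spec, "cp", 0.01),
                            minsplit = hp(spec, "minsplit", 10)))
  } else if (spec$name == "ANN") {
    model <- nnet::nnet(x, y, size = hp(spec, "size", 5),
                        decay = hp(spec, "decay", 0.01),
                        maxit = hp(spec, "maxit", 200), trace = FALSE)
  } else if (spec$name == "FDA") {
    feats <- fda_features(x, n)
    extra$fda_cols <- colnames(feats)
    model <- suppressWarnings(
      MASS::lda(feats, grouping = factor(y, levels = c(0, 1))))
  } else if (spec$name == "MAXENT") {
    feats <- maxent_features(x)
    model <- suppressWarnings(
      glmnet::cv.glmnet(feats, y, family = "binomial", alpha = 1,
                        nfolds = hp(spec, "nfolds", 5)))
  } else if (spec$name == "SRE") {
    q <- hp(spec, "q", 0.025)
    pres <- x[y == 1, , drop = FALSE]
    if (nrow(pres) < 1) stop("SRE needs at least one presence", call. = FALSE)
    extra$lo <- apply(pres, 2L, stats::quantile, probs = q)
    extra$hi <- apply(pres, 2L, stats::quantile, probs = 1 - q)
  }

  structure(list(name = spec$name, model = model, extra = extra,
                 feature_names = colnames(x)),
            class = "fitted_learner")
}

#' Score new cells with a fitted learner
#'
#' @param fit A `fitted_learner` from [fit_learner()].
#' @param newx Feature matrix with the training columns.
#' @return Suitability scores in `[0, 1]`, one per row of `newx`.
#' @export
predict_suitability <- function(fit, newx) {
  stopifnot(inherits(fit, "fitted_learner"))
  newx <- as.matrix(newx)
  if (is.null(colnames(newx))) colnames(newx) <- fit$feature_names
  newx <- newx[, fit$feature_names, drop = FALSE]
  out <- switch(
    fit$name,
    GLM = stats::predict(fit$model,
                         newdata = as.data.frame(newx), type = "response"),
    GAM = as.numeric(mgcv::predict.gam(fit$model,
                                       newdata = as.data.frame(newx),
                                       type = "response")),
    MARS = stats::plogis(drop(mars_basis_matrix(newx, fit$model$terms) %*%
                                fit$model$coef)),
    RF = stats::predict(fit$model, newx, type = "prob")[, "1"],
    GBM = stats::predict(fit$model,
                         xgboost::xgb.DMatrix(newx, nthread = 1)),
    CTA = stats::predict(fit$model, newdata = as.data.frame(newx))[, "1"],
    ANN = as.numeric(stats::predict(fit$model, newx)),
    FDA = {
      feats <- cbind(newx, newx^2)
      colnames(feats) <- c(colnames(newx), paste0(colnames(newx), "_sq"))
      feats <- feats[, fit$extra$fda_cols, drop = FALSE]
      stats::predict(fit$model, feats)$posterior[, "1"]
    },
    MAXENT = as.numeric(stats::predict(fit$model, maxent_features(newx),
                                       type = "response",
                                       s = "lambda.min")),
    SRE = {
      inside <- rep(TRUE, nrow(newx))
      for (j in seq_len(ncol(newx))) {
        inside <- inside & newx[, j] >= fit$extra$lo[j] &
          newx[, j] <= fit$extra$hi[j]
      }
      as.numeric(inside)
    },
    stop("unknown learner: ", fit$name, call. = FALSE)
  )
  pmin(1, pmax(0, as.numeric(out)))
}
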