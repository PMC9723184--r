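#' Write a layer as an ESRI ASCII grid
#'
#' Plain-text raster interchange format: a 6-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of values
#' from the top row of the grid down, matching the row-major cell-id order
#' used throughout the package. Registration is cell-corner at the origin
#' with cell-center sample semantics. `NA` cells are written as the nodata
#' value and restored as `NA` on reading.
#'
#' @param values Numeric vector in row-major cell order (or a matrix).
#' @param grid The [grid_definition()].
#' @param path Output file path.
#' @param nodata Sentinel written for `NA` cells. Default -9999.
#' @export
write_ascii_grid <- function(values, grid, path, nodata = -9999) {
  if (is.matrix(values)) values <- as.vector(t(values))
  if (length(values) != n_cells(grid)) {
    stop("values length does not match the grid", call. = FALSE)
  }
  m <- matrix(values, grid$n_rows, grid$n_cols, byrow = TRUE)
  m[is.na(m)] <- nodata
  header <- c(
    paste("ncols", grid$n_cols),
    paste("nrows", grid$n_rows),
    "xllcorner 0",
    "yllcorner 0",
    paste("cellsize", grid$cell_size),
    paste("NODATA_value", nodata)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @return `read_ascii_grid()`: list with `grid` and `values` (row-major,
#'   `NA` for nodata cells).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  header <- lines[1:6]
  kv <- strsplit(trimws(header), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  grid <- grid_definition(vals[["nrows"]], vals[["ncols"]],
                          vals[["cellsize"]])
  body <- scan(text = lines[-(1:6)], quiet = TRUE)
  if (length(body) != n_cells(grid)) {
    stop("ASCII grid body does not match its header dimensions",
         call. = FALSE)
  }
  body[body == vals[["nodata_value"]]] <- NA_real_
  list(grid = grid, values = body)
}

#' Occurrence CSV round trip
#'
#' Columns: `species_code`, `x`, `y`, `source`, `cell_id`.
#'
#' @param occ An `occurrence_set`.
#' @param path CSV file path.
#' @export
write_occurrences_csv <- function(occ, path) {
  utils::write.csv(occ$records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_occurrences_csv
#' @param grid The grid to attach (cell ids are recomputed from x, y).
#' @export
read_occurrences_csv <- function(path, grid) {
  occurrence_set(utils::read.csv(path, stringsAsFactors = FALSE), grid)
}

#' Write an overlap matrix mirroring the published layout
#'
#' Upper triangle holds Schoener's D, lower triangle the Hellinger-based I,
#' diagonal 1.
#'
#' @param om An `overlap_matrix`.
#' @param path CSV file path.
#' @export
write_overlap_csv <- function(om, path) {
  m <- om$D
  m[lower.tri(m)] <- om$I[lower.tri(om$I)]
  utils::write.csv(m, path)
  invisible(path)
}

#' Assemble and validate a pipeline configuration
#'
#' One structured object driving [run_pipeline()] end to end. Unknown keys
#' are rejected so configuration typos fail loudly.
#'
#' @param landscape A [landscape_config()].
#' @param prevalence Landscape-mean true suitability of each synthetic
#'   species.
#' @param learners Learner names (subset of [learner_registry()]).
#' @param gate_threshold Strict validation gate on kappa/TSS/ROC.
#' @param cutpoints Suitability class cutpoints.
#' @param screen_r_max Collinearity ceiling for predictor screening.
#' @param n_top_predictors Per-species predictor budget when the merit
#'   screen selects fewer influential variables.
#' @param overlap_n_perm Permutations per species pair (0 disables tests).
#' @param prioritization List: `thresholds` (see [flag_grid()]) and `rule`
#'   (see [prioritize()]).
#' @param seed Master seed; every stage derives its own seed from it.
#' @param output_dir Optional directory for CSV/ASCII-grid outputs and the
#'   run manifest.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(landscape = landscape_config(),
                            prevalence = 0.12,
                            learners = learner_registry(),
                            gate_threshold = 0.75,
                            cutpoints = c(0.25, 0.5, 0.75),
                            screen_r_max = 0.8,
                            n_top_predictors = 6,
                            overlap_n_perm = 49,
                            prioritization = list(),
                            seed = 1L,
                            output_dir = NULL) {
  prioritization <- utils::modifyList(
    list(thresholds = list(), rule = "veto-and-one"), prioritization)
  bad <- setdiff(names(prioritization), c("thresholds", "rule"))
  if (length(bad)) {
    stop("unknown prioritization keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!all(learners %in% learner_registry())) {
    stop("unknown learners in config", call. = FALSE)
  }
  structure(
    list(landscape = landscape, prevalence = prevalence,
         learners = learners, gate_threshold = gate_threshold,
         cutpoints = cutpoints, screen_r_max = screen_r_max,
         n_top_predictors = n_top_predictors,
         overlap_n_perm = overlap_n_perm,
         prioritization = prioritization,
         seed = as.integer(seed), output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Accepts the keys of [pipeline_config()]; the `landscape` key holds the
#' [landscape_config()] arguments. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(y$landscape)) {
    lk <- setdiff(names(y$landscape), names(formals(landscape_config)))
    if (length(lk)) {
      stop("unknown landscape keys: ", paste(lk, collapse = ", "),
           call. = FALSE)
    }
    y$landscape <- do.call(landscape_config, y$landscape)
  }
  do.call(pipeline_config, y)
}

#' Run the whole pipeline on a synthetic landscape
#'
#' Chains every stage end to end with ground truth known throughout:
#' generate the predictor stack; sample archival and field occurrences per
#' registered species from its true suitability; merge and spatially
#' rarefy them; screen predictors per species by linear-SVM merit; fit,
#' gate and ensemble the learner suite ([run_all()]); generate the
#' two-date land-cover pair and compute the change matrix and per-grid
#' mangrove statistics; compute disturbance components and HDR; compute
#' the pairwise niche-overlap matrix with permutation significance; rank
#' species for restoration priority; and evaluate the indicator flags and
#' prioritization rule per species and grid, with grid-level categories.
#'
#' @param config A [pipeline_config()].
#' @param lulc_spec Optional [lulc_transition_spec()]; the default degrades
#'   a fifth of date-1 mangrove to swamp/water and accretes some sandbar
#'   back.
#' @return A `pipeline_result` list with each stage's outputs and a
#'   `manifest` (inputs, seeds, fit counts, prioritized-grid counts).
#' @export
run_pipeline <- function(config = pipeline_config(), lulc_spec = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  stack <- generate_env_stack(config$landscape)
  grid <- stack$grid
  reg <- mangrove_species()
  truths <- default_species_truths(stack, prevalence = config$prevalence)

  # occurrences: archive + field per species, then merge and rarefy
  occ_list <- lapply(seq_len(nrow(reg)), function(i) {
    code <- reg$code[i]
    arch <- sample_occurrences(stack, truths[[code]],
                               n = reg$archive_occurrences[i],
                               seed = seed + 100 + i, source = "archive")
    fld <- sample_occurrences(stack, truths[[code]],
                              n = reg$gps_verified_points[i],
                              seed = seed + 200 + i, source = "field")
    merge_sources(arch, fld)
  })
  rec <- do.call(rbind, lapply(occ_list, function(o) o$records))
  occ_raw <- occurrence_set(rec, grid)
  occ <- rarefy_to_grid(occ_raw, grid, seed = seed + 300)

  # predictor screening: collinearity then per-species LSVM merit
  retained <- collinearity_filter(stack, r_max = config$screen_r_max)
  stack_s <- subset_stack(stack, retained)
  merit <- lsvm_average_merit(occ, stack_s, seed = seed + 400)
  per_species <- split(merit, merit$species_code)
  predictors <- lapply(per_species, function(tab) {
    sel <- tab$predictor[tab$influential]
    if (length(sel) < config$n_top_predictors) {
      sel <- tab$predictor[order(-tab$average_merit)][
        seq_len(min(config$n_top_predictors, nrow(tab)))]
    }
    sel
  })

  run <- run_all(occ, stack_s, learners = config$learners,
                 predictors = predictors,
                 gate_threshold = config$gate_threshold,
                 cutpoints = config$cutpoints, seed = seed + 500)

  # land-cover change and per-grid mangrove statistics
  if (is.null(lulc_spec)) {
    lulc_spec <- default_lulc_spec()
  }
  pair <- generate_lulc_pair(config$landscape, lulc_spec, seed = seed + 600)
  cm <- change_matrix(pair)
  gstats <- gridwise_mangrove_stats(grid, pair$t1, pair$t2)

  # disturbance and HDR
  dist_c <- generate_disturbance_components(config$landscape,
                                            seed = seed + 700)
  hdr <- human_disturbance_rate(dist_c)

  # niche overlap with permutation significance
  om <- overlap_matrix(run$surfaces, occ = occ, stack = stack_s,
                       n_perm = config$overlap_n_perm, seed = seed + 800)

  # species priority rank
  attrs <- species_priority_attributes(run, occ, gstats, registry = reg)
  ranked <- species_priority_rank(attrs)

  # indicator flags and prioritization per species
  modelled <- names(run$surfaces)
  n_half <- ceiling(length(modelled) / 2)
  prioritized <- list()
  flags_list <- list()
  for (code in modelled) {
    rank_i <- ranked$priority_rank[ranked$species_code == code]
    p2 <- overlap_significant_cells(code, om, run$class_maps)
    fl <- flag_grid(
      cover_pct = gstats$mangrove_cover_pct_t2, hdr = hdr,
      class_map = run$class_maps[[code]],
      accretion_pct = gstats$accretion_rate_pct,
      degradation_pct = gstats$degradation_rate_pct,
      overlap_significant = p2,
      rank_top_half = rank_i <= n_half,
      thresholds = config$prioritization$thresholds)
    flags_list[[code]] <- fl
    prioritized[[code]] <- prioritize(fl, rule = config$prioritization$rule)
  }
  categories <- grid_category(prioritized)
  prior_grids <- Reduce(`|`, prioritized)

  manifest <- c(run$manifest, list(
    n_cells = n_cells(grid),
    n_predictors = ncol(stack$values),
    n_predictor_groups = length(unique(stack$groups)),
    n_occurrences_raw = nrow(occ_raw$records),
    n_occurrences_rarefied = nrow(occ$records),
    n_prioritized_grids = sum(prior_grids),
    master_seed = seed))

  result <- structure(
    list(stack = stack, occurrences_raw = occ_raw, occurrences = occ,
         merit = merit, predictors = predictors, run = run,
         lulc_pair = pair, change_matrix = cm, grid_stats = gstats,
         disturbance = dist_c, hdr = hdr, overlap = om,
         priority_rank = ranked, flags = flags_list,
         prioritized = prioritized, categories = categories,
         manifest = manifest),
    class = "pipeline_result"
  )
  if (!is.null(config$output_dir)) write_pipeline_outputs(result, config)
  result
}

# the default two-date transition process: part of the mangrove degrades
# to swamp and open water, some regenerates elsewhere
default_lulc_spec <- function() {
  classes <- c("mangrove", "swamp", "water", "settlement", "wetland",
               "sandbar", "cropland", "other")
  k <- length(classes)
  tp <- diag(k)
  dimnames(tp) <- list(classes, classes)
  tp["mangrove", ] <- 0
  tp["mangrove", "mangrove"] <- 0.80
  tp["mangrove", "swamp"] <- 0.10
  tp["mangrove", "water"] <- 0.07
  tp["mangrove", "settlement"] <- 0.01
  tp["mangrove", "wetland"] <- 0.01
  tp["mangrove", "sandbar"] <- 0.01
  tp["sandbar", ] <- 0
  tp["sandbar", "sandbar"] <- 0.85
  tp["sandbar", "mangrove"] <- 0.15   # natural accretion on new bars
  tp["swamp", ] <- 0
  tp["swamp", "swamp"] <- 0.95
  tp["swamp", "mangrove"] <- 0.05
  lulc_transition_spec(classes, tp)
}

# per-grid p2 indicator: the species sits in >= 1 significant overlap pair
# and the grid lies in the pair's joint moderately/highly suitable region
overlap_significant_cells <- function(code, om, class_maps) {
  n <- length(class_maps[[code]])
  out <- rep(FALSE, n)
  if (is.null(om$p_value)) return(out)
  partners <- om$species[which(om$p_value[code, ] < 0.05)]
  partners <- setdiff(partners, code)
  own <- class_maps[[code]] %in% c("moderately", "highly")
  for (p in partners) {
    if (is.null(class_maps[[p]])) next
    out <- out | (own & class_maps[[p]] %in% c("moderately", "highly"))
  }
  out
}

write_pipeline_outputs <- function(result, config) {
  dir <- config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- result$stack$grid
  write_occurrences_csv(result$occurrences,
                        file.path(dir, "occurrences_rarefied.csv"))
  utils::write.csv(result$merit, file.path(dir, "merit_table.csv"),
                   row.names = FALSE)
  utils::write.csv(result$run$evaluation,
                   file.path(dir, "evaluation_report.csv"),
                   row.names = FALSE)
  utils::write.csv(result$grid_stats, file.path(dir, "grid_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(result$change_matrix$counts,
                   file.path(dir, "change_matrix.csv"))
  write_overlap_csv(result$overlap, file.path(dir, "overlap_matrix.csv"))
  utils::write.csv(result$priority_rank,
                   file.path(dir, "priority_rank.csv"), row.names = FALSE)
  for (code in names(result$run$surfaces)) {
    write_ascii_grid(result$run$surfaces[[code]]$values, grid,
                     file.path(dir, paste0("suitability_", code, ".asc")))
  }
  prior_tab <- data.frame(
    cell_id = seq_len(n_cells(grid)),
    category = result$categories,
    do.call(cbind, result$prioritized))
  utils::write.csv(prior_tab, file.path(dir, "prioritization.csv"),
                   row.names = FALSE)
  yaml::write_yaml(result$manifest, file.path(dir, "manifest.yml"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<pipeline_result> %d cells, %d predictors, %d rarefied occurrences\n",
    "  %d intrinsic fits, %d ensembles, %d prioritized grids\n"),
    x$manifest$n_cells, x$manifest$n_predictors,
    x$manifest$n_occurrences_rarefied, x$manifest$n_fits,
    length(x$run$surfaces), x$manifest$n_prioritized_grids))
  invisible(x)
}
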