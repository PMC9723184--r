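#' Classification confusion matrix
#'
#' @param counts Square non-negative integer matrix, rows = reference
#'   labels, columns = predicted labels.
#' @param labels Optional class labels (defaults to existing dimnames or
#'   integer labels).
#' @return A `confusion_matrix`.
#' @export
confusion_matrix <- function(counts, labels = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) {
    stop("confusion matrix must be square", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) < 1) stop("confusion matrix is empty", call. = FALSE)
  if (is.null(labels)) {
    labels <- rownames(counts)
    if (is.null(labels)) labels <- as.character(seq_len(nrow(counts)))
  }
  dimnames(counts) <- list(reference = labels, predicted = labels)
  structure(list(labels = labels, counts = counts),
            class = "confusion_matrix")
}

#' Overall classification accuracy
#'
#' Fraction of reference samples whose predicted class agrees:
#' trace / total.
#'
#' @param cm A [confusion_matrix()] (or a bare square count matrix).
#' @return Accuracy in `[0, 1]`.
#' @export
#' @examples
#' overall_accuracy(confusion_matrix(rbind(c(40, 10), c(5, 45))))  # 0.85
overall_accuracy <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) cm <- confusion_matrix(cm)
  sum(diag(cm$counts)) / sum(cm$counts)
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with expected
#' agreement `p_e` from the row and column margins. Returns 0 in the
#' degenerate case `p_e = 1` (all mass in one margin cell).
#'
#' @inheritParams overall_accuracy
#' @return Kappa in `[-1, 1]`.
#' @export
#' @examples
#' kappa_coefficient(confusion_matrix(rbind(c(40, 10), c(20, 30))))  # 0.4
kappa_coefficient <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) cm <- confusion_matrix(cm)
  n <- sum(cm$counts)
  p_o <- sum(diag(cm$counts)) / n
  p_e <- sum(rowSums(cm$counts) * colSums(cm$counts)) / n^2
  if (abs(1 - p_e) < .Machine$double.eps^0.5) return(0)
  (p_o - p_e) / (1 - p_e)
}

# Coerce a LULC map argument to a factor vector over given/derived levels.
as_lulc_vector <- function(m) {
  if (is.matrix(m)) m <- as.vector(t(m))  # row-major like cell ids
  if (!is.factor(m)) m <- factor(m)
  m
}

#' Post-classification land-cover change matrix
#'
#' Cross-tabulates two co-registered categorical maps:
#' `counts[i, j]` = number of cells labelled `i` at date 1 and `j` at
#' date 2. Row sums therefore equal the date-1 class counts and column sums
#' the date-2 counts, exactly.
#'
#' @param t1,t2 Categorical maps (factor vectors in row-major cell order,
#'   matrices, or taken from a `lulc_pair`), same length.
#' @param cell_area Area of one map cell in km^2 (default 1).
#' @return A `change_matrix`: class lists, the count matrix, and
#'   `cell_area`.
#' @export
change_matrix <- function(t1, t2, cell_area = 1) {
  if (inherits(t1, "lulc_pair")) {
    pair <- t1
    t1 <- pair$t1
    t2 <- pair$t2
  }
  t1 <- as_lulc_vector(t1)
  t2 <- as_lulc_vector(t2)
  if (length(t1) != length(t2)) {
    stop("maps differ in cell count", call. = FALSE)
  }
  lev <- union(levels(t1), levels(t2))
  counts <- table(factor(as.character(t1), levels = lev),
                  factor(as.character(t2), levels = lev))
  counts <- matrix(as.integer(counts), length(lev), length(lev),
                   dimnames = list(t1 = lev, t2 = lev))
  structure(list(classes_t1 = lev, classes_t2 = lev, counts = counts,
                 cell_area = cell_area),
            class = "change_matrix")
}

#' Per-grid mangrove cover, degradation and accretion rates
#'
#' For each analysis grid cell: mangrove cover at date 2 (percent of cell
#' area), degradation rate (percent of the cell's date-1 mangrove area lost
#' by date 2) and accretion rate (percent of the cell's date-2 mangrove
#' area newly gained since date 1). At the 1-km analysis resolution each
#' grid holds a single land-cover cell; finer maps (e.g. reclassified 30-m
#' products) are supplied as matrices whose dimensions are integer
#' multiples of the grid's, and rates are computed from sub-cell area
#' fractions. Cells with no mangrove in the relevant denominator get a rate
#' of 0 and are flagged.
#'
#' @param grid A [grid_definition()].
#' @param t1,t2 Categorical maps as factor matrices (grid-resolution
#'   `n_rows x n_cols`, or an integer multiple of both).
#' @param mangrove_class Label of the mangrove class. Default `"mangrove"`.
#' @return A data.frame with one row per grid cell: `cell_id`,
#'   `mangrove_cover_pct_t2`, `degradation_rate_pct`, `accretion_rate_pct`,
#'   `no_t1_mangrove`, `no_t2_mangrove`.
#' @export
gridwise_mangrove_stats <- function(grid, t1, t2,
                                    mangrove_class = "mangrove") {
  to_mat <- function(m) {
    if (inherits(m, "factor") || is.vector(m)) {
      if (length(m) != n_cells(grid)) {
        stop("vector map length must equal the grid cell count",
             call. = FALSE)
      }
      m <- matrix(as.character(m), grid$n_rows, grid$n_cols, byrow = TRUE)
    } else {
      m <- matrix(as.character(m), nrow(m), ncol(m))
    }
    m
  }
  m1 <- to_mat(t1)
  m2 <- to_mat(t2)
  if (!all(dim(m1) == dim(m2))) stop("maps differ in shape", call. = FALSE)
  f_r <- nrow(m1) / grid$n_rows
  f_c <- ncol(m1) / grid$n_cols
  if (f_r != round(f_r) || f_c != round(f_c) || f_r != f_c) {
    stop("map dimensions must be an integer multiple of the grid",
         call. = FALSE)
  }
  f <- as.integer(f_r)

  man1 <- m1 == mangrove_class
  man2 <- m2 == mangrove_class
  # aggregate sub-cell counts into grid cells (row-major cell order)
  agg <- function(b) {
    gr <- (row(b) - 1L) %/% f
    gc <- (col(b) - 1L) %/% f
    idx <- gr * grid$n_cols + gc + 1L
    out <- numeric(n_cells(grid))
    tab <- tapply(as.numeric(b), idx, sum)
    out[as.integer(names(tab))] <- tab
    out
  }
  n_sub <- f * f
  t1_m <- agg(man1)                  # sub-cells mangrove at t1
  t2_m <- agg(man2)                  # sub-cells mangrove at t2
  lost <- agg(man1 & !man2)          # mangrove at t1, not at t2
  gained <- agg(!man1 & man2)        # mangrove only at t2

  degr <- ifelse(t1_m > 0, 100 * lost / t1_m, 0)
  accr <- ifelse(t2_m > 0, 100 * gained / t2_m, 0)
  data.frame(
    cell_id = seq_len(n_cells(grid)),
    mangrove_cover_pct_t2 = 100 * t2_m / n_sub,
    degradation_rate_pct = degr,
    accretion_rate_pct = accr,
    no_t1_mangrove = t1_m == 0,
    no_t2_mangrove = t2_m == 0
  )
}
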