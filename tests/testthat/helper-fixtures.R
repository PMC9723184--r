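# Shared small fixtures and independent oracles, built in code.

small_config <- function(n = 20, range = 3, seed = 11) {
  landscape_config(n_rows = n, n_cols = n,
                   spatial_autocorrelation_range = range, seed = seed)
}

# single-species truth on named layers of a stack
toy_truth <- function(stack, coefs, prevalence = 0.15, code = "AR") {
  species_truth(code, coefs, prevalence = prevalence,
                iucn_status = "NT", intertidal_position = "low")
}

# occurrence_set from bare cell ids
occ_from_cells <- function(grid, cells, code = "AR", source = "field") {
  xy <- cell_center(grid, cells)
  occurrence_set(data.frame(species_code = code, x = xy$x, y = xy$y,
                            source = source), grid)
}

# brute-force Moran's I with rook neighbours (weight 1), direct double sum
morans_i_oracle <- function(m) {
  z <- m - mean(m)
  num <- 0
  s0 <- 0
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      for (d in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
          num <- num + z[i, j] * z[ii, jj]
          s0 <- s0 + 1
        }
      }
    }
  }
  (length(m) / s0) * num / sum(z^2)
}

# brute-force AUC: enumerate all (positive, negative) pairs, ties count 1/2
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# confusion-cell oracles for TSS and kappa at a threshold
tss_oracle <- function(scores, labels, t) {
  tp <- sum(scores >= t & labels == 1); fn <- sum(scores < t & labels == 1)
  tn <- sum(scores < t & labels == 0); fp <- sum(scores >= t & labels == 0)
  tp / (tp + fn) + tn / (tn + fp) - 1
}
kappa_oracle <- function(scores, labels, t) {
  tp <- sum(scores >= t & labels == 1); fn <- sum(scores < t & labels == 1)
  tn <- sum(scores < t & labels == 0); fp <- sum(scores >= t & labels == 0)
  n <- tp + fn + tn + fp
  po <- (tp + tn) / n
  pe <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  if (abs(1 - pe) < 1e-12) return(0)
  (po - pe) / (1 - pe)
}

# data with (approximately) a prescribed correlation matrix, exact via QR
correlated_layers <- function(n, R, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * ncol(R)), n)
  x <- qr.Q(qr(x))                 # orthonormal columns
  x %*% chol(R)
}

# presence/background design on a stack for ensemble recovery tests
build_design <- function(stack, truth, n, seed) {
  occ <- sample_occurrences(stack, truth, n, seed = seed)
  pres <- occ$records$cell_id
  bg <- generate_pseudo_absences(stack$grid, pres, n, seed = seed + 1)
  list(cells = c(pres, bg),
       labels = c(rep(1L, n), rep(0L, n)))
}
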