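#' Build an occurrence set
#'
#' A tagged table of presence records: species code, planar coordinates,
#' source (`"archive"` for database/literature records, `"field"` for
#' GPS-verified survey points), and the id of the 1-km grid cell the point
#' falls in. Cell ids are (re)computed from coordinates on construction
#' using the half-open cell convention, so boundary points belong to exactly
#' one cell.
#'
#' @param records A data.frame with columns `species_code`, `x`, `y`,
#'   `source`; a `cell_id` column is recomputed if present.
#' @param grid The [grid_definition()] the coordinates live on.
#' @param crs_note Free-text note on the planar coordinate system.
#' @return An `occurrence_set`.
#' @export
occurrence_set <- function(records, grid, crs_note = "planar km grid") {
  needed <- c("species_code", "x", "y", "source")
  if (!all(needed %in% names(records))) {
    stop("records need columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) > 0 && !all(records$source %in% c("archive", "field"))) {
    stop('source must be "archive" or "field"', call. = FALSE)
  }
  records$cell_id <- if (nrow(records) > 0) {
    cell_id_at(grid, records$x, records$y)
  } else integer(0)
  rownames(records) <- NULL
  structure(list(records = records, grid = grid, crs_note = crs_note),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %d records, %d species\n",
              nrow(x$records), length(unique(x$records$species_code))))
  invisible(x)
}

#' Merge archival and field occurrence sources
#'
#' Union of the two record sets with source tags preserved. Exact
#' coordinate duplicates (same species, same x, same y) collapse to a
#' single record; when the duplicate spans both sources the GPS-verified
#' field copy is kept.
#'
#' @param archive,field `occurrence_set`s on the same grid.
#' @return A merged `occurrence_set`.
#' @export
#' @examples
#' g <- grid_definition(10, 10)
#' a <- occurrence_set(data.frame(species_code = "AR", x = 1.5, y = 1.5,
#'                                source = "archive"), g)
#' f <- occurrence_set(data.frame(species_code = "AR", x = 1.5, y = 1.5,
#'                                source = "field"), g)
#' nrow(merge_sources(a, f)$records)  # 1, field copy kept
merge_sources <- function(archive, field) {
  stopifnot(inherits(archive, "occurrence_set"),
            inherits(field, "occurrence_set"))
  if (!same_grid(archive$grid, field$grid)) {
    stop("occurrence sets are on different grids", call. = FALSE)
  }
  rec <- rbind(field$records, archive$records)  # field first wins dedup
  key <- paste(rec$species_code, rec$x, rec$y, sep = "\r")
  rec <- rec[!duplicated(key), , drop = FALSE]
  occurrence_set(rec, archive$grid, archive$crs_note)
}

#' Spatially rarefy occurrences to one point per species per cell
#'
#' For every (species, cell) combination holding at least one record,
#' exactly one record is retained. GPS-verified field records are preferred
#' over archival ones; remaining ties are broken uniformly at random under
#' the seed. This reproduces the standard spatial-thinning step that limits
#' clustered sampling bias before distribution modelling.
#'
#' @param occ An `occurrence_set`.
#' @param grid Grid to rarefy on (defaults to the set's own grid).
#' @param seed Integer seed for within-cell tie-breaks.
#' @return A rarefied `occurrence_set`. Idempotent: rarefying twice gives
#'   the same set.
#' @export
rarefy_to_grid <- function(occ, grid = occ$grid, seed = 1L) {
  stopifnot(inherits(occ, "occurrence_set"))
  rec <- occ$records
  if (nrow(rec) == 0) return(occurrence_set(rec, grid, occ$crs_note))
  rec$cell_id <- cell_id_at(grid, rec$x, rec$y)
  set.seed(seed)
  # field < archive sorts field first; random jitter settles within-source ties
  ord <- order(rec$species_code, rec$cell_id,
               match(rec$source, c("field", "archive")),
               stats::runif(nrow(rec)))
  rec <- rec[ord, , drop = FALSE]
  keep <- !duplicated(paste(rec$species_code, rec$cell_id, sep = "\r"))
  occurrence_set(rec[keep, , drop = FALSE], grid, occ$crs_note)
}
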