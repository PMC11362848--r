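# Cortex-restricted per-pixel density vectors: the long-format table the
# group-level statistics consume.

MARKER_COLUMN_ORDER <- c("tumor_cell", "neun", "abeta", "ptau", "iba1")

#' Extract cortex-restricted density row vectors
#'
#' One row per map pixel satisfying tissue = 1 AND cortex = 1, with one
#' density column per supplied marker (per mm^2). Markers without a slide
#' are simply absent — never filled with zeros. All maps must share the
#' map grid; a mismatching marker aborts with its name.
#'
#' @param maps named list of `density_map` objects coregistered to the
#'   common map grid; canonical names: `tumor_cell`, `neun`, `abeta`,
#'   `ptau`, `iba1` (others are kept in given order after the canonical
#'   ones).
#' @param cortex_mask,tissue_mask logical matrices on the map grid.
#' @return data.frame with `pixel_id` (1-based linear index into the map),
#'   `x`, `y` (0-based pixel coordinates) and `<marker>_density` columns.
#' @export
extract_cortex_vectors <- function(maps, cortex_mask, tissue_mask) {
  stopifnot(is.list(maps), length(maps) >= 1, !is.null(names(maps)),
            is.matrix(cortex_mask), is.matrix(tissue_mask),
            all(dim(cortex_mask) == dim(tissue_mask)))
  shape <- dim(cortex_mask)
  for (nm in names(maps)) {
    m <- maps[[nm]]
    if (!inherits(m, "density_map")) stop("map '", nm, "' is not a density_map")
    if (!all(dim(m$values) == shape)) {
      stop(sprintf("grid mismatch for marker '%s': %d x %d vs %d x %d",
                   nm, nrow(m$values), ncol(m$values), shape[1], shape[2]))
    }
  }
  sel <- which(cortex_mask & tissue_mask)
  ord <- c(intersect(MARKER_COLUMN_ORDER, names(maps)),
           setdiff(names(maps), MARKER_COLUMN_ORDER))
  out <- data.frame(
    pixel_id = sel,
    x = (sel - 1L) %/% shape[1],
    y = (sel - 1L) %% shape[1]
  )
  for (nm in ord) out[[paste0(nm, "_density")]] <- maps[[nm]]$values[sel]
  out
}

#' Write a cortex pixel table as CSV
#'
#' The header carries the unit (objects per mm^2) as a comment line.
#'
#' @param table output of [extract_cortex_vectors()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cortex_table_csv <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# density columns in objects per mm^2", con)
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}
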