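# File formats. All coordinates are written in micrometres and all angles in
# degrees; every CSV carries a header comment line stating the units.

units_header <- "# units: um (coordinates/displacements), hours (t), degrees (angles)"

#' Read and write bead-track tables
#'
#' CSV dialect for bead trajectories: columns `bead_id` (string), `t`
#' (hours), `x, y, z` (um), one row per bead per timepoint, `(bead_id, t)`
#' unique. A leading `#` comment line carries the unit declaration. Columns
#' exported from tracking software can be mapped with `col_map`, e.g.
#' `c(bead_id = "TrackID", t = "Time", x = "Position X", ...)`.
#'
#' @param path File path.
#' @param col_map Optional named character vector mapping required column
#'   names to those present in the file.
#' @return `read_bead_tracks()`: validated tibble sorted by bead and time.
#' @export
read_bead_tracks <- function(path, col_map = NULL) {
  # numeric columns are parsed with base R's strtod (via as.numeric below),
  # which is correctly rounded, so write -> read -> write is bit identical
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE,
                        col_types = readr::cols(.default = "c"))
  if (!is.null(col_map)) {
    for (want in names(col_map)) {
      if (!col_map[[want]] %in% names(df)) {
        abort(sprintf("mapped column '%s' not found", col_map[[want]]))
      }
    }
    df <- rename(df, !!!setNames(col_map, names(col_map)))
  }
  required <- c("bead_id", "t", "x", "y", "z")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    abort(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")))
  }
  df <- select(df, all_of(required))
  num <- c("t", "x", "y", "z")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v)) {
      abort(sprintf("non-numeric value in column '%s' (row %d)",
                    cn, which(is.na(v))[1]))
    }
    df[[cn]] <- v
  }
  df$bead_id <- as.character(df$bead_id)
  dup <- duplicated(df[, c("bead_id", "t")])
  if (any(dup)) {
    abort(sprintf("duplicated (bead_id, t) pair at row %d", which(dup)[1]))
  }
  arrange(df, .data$bead_id, .data$t)
}

#' @rdname read_bead_tracks
#' @param tracks Bead-track tibble (`bead_id, t, x, y, z`).
#' @export
write_bead_tracks <- function(tracks, path) {
  required <- c("bead_id", "t", "x", "y", "z")
  stopifnot(all(required %in% names(tracks)))
  body <- readr::format_csv(as_tibble(tracks)[, required])
  writeLines(c(units_header, sub("\n$", "", body)), path)
  invisible(path)
}

#' Write a tabular field as CSV with a unit header
#'
#' Used for displacement fields, strain tables and traction tables.
#' @param table Data frame.
#' @param path Output path.
#' @export
write_field_csv <- function(table, path) {
  body <- readr::format_csv(as_tibble(table))
  writeLines(c(units_header, sub("\n$", "", body)), path)
  invisible(path)
}

#' Read/write grayscale images and binary masks as TIFF
#'
#' Images are written as 32-bit float single-channel TIFF; masks as 0/1.
#' @param image Numeric matrix (or logical for masks).
#' @param path File path.
#' @return `read_image_tiff()` returns a numeric matrix; `read_mask_tiff()`
#'   a logical matrix.
#' @export
write_image_tiff <- function(image, path) {
  tiff::writeTIFF(image * 1, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img
}

#' @rdname write_image_tiff
#' @export
write_mask_tiff <- function(image, path) write_image_tiff(image * 1, path)

#' @rdname write_image_tiff
#' @export
read_mask_tiff <- function(path) read_image_tiff(path) > 0.5

#' Write point data in legacy VTK format
#'
#' Minimal legacy-ASCII VTK polydata writer for visualizing scattered point
#' fields (displacements, tractions) in ParaView.
#'
#' @param points n x 3 matrix or data frame with `x, y, z` (um).
#' @param path Output path.
#' @param vectors Optional named list of n x 3 matrices (vector point data).
#' @param scalars Optional named list of length-n numerics (scalar point
#'   data).
#' @export
write_vtk_points <- function(points, path, vectors = list(), scalars = list()) {
  p <- as_point_matrix(points)
  n <- nrow(p)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "tfm3d point data (um, Pa)", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", n)), con)
  writeLines(apply(p, 1, paste, collapse = " "), con)
  writeLines(c(sprintf("VERTICES %d %d", n, 2 * n)), con)
  writeLines(paste(1, seq_len(n) - 1), con)
  if (length(vectors) + length(scalars) > 0) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(vectors)) {
      v <- as.matrix(vectors[[nm]])
      writeLines(sprintf("VECTORS %s double", nm), con)
      writeLines(apply(v, 1, paste, collapse = " "), con)
    }
    for (nm in names(scalars)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(as.character(scalars[[nm]]), con)
    }
  }
  invisible(path)
}
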