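# The cell map: one row per segmented nucleus, the substrate of all spatial
# computation. Coordinates are 0-based pixels, x to the right, y downward.

#' Nucleus descriptor column sets
#'
#' Column names of the per-nucleus descriptors a cell map may carry:
#' morphology (\code{area}, \code{perimeter}, \code{eccentricity},
#' \code{equiv_diameter}, \code{solidity}), per-channel color means
#' (\code{mean_R}, \code{mean_G}, \code{mean_B}; image scale \code{[0, 1]}),
#' and the twelve co-occurrence texture statistics (prefix \code{har_}).
#'
#' @return character vector of column names.
#' @export
descriptor_columns <- function() {
  c(morphology_columns(), color_columns(), haralick_columns())
}

morphology_columns <- function() {
  c("area", "perimeter", "eccentricity", "equiv_diameter", "solidity")
}

color_columns <- function() c("mean_R", "mean_G", "mean_B")

#' @rdname descriptor_columns
#' @export
haralick_columns <- function() paste0("har_", haralick_names())

#' Construct a cell map
#'
#' A cell map is a tibble with one row per nucleus (columns \code{cell_id},
#' \code{x}, \code{y}, \code{class} plus optional descriptor columns, see
#' [descriptor_columns()]) carrying tile metadata as attributes. \code{class}
#' takes values \code{"TIL"}, \code{"nonTIL"} or \code{"unassigned"}.
#'
#' @param cells data frame of nuclei.
#' @param tile_id identifier of the source tile.
#' @param microns_per_pixel physical pixel size (default 0.5, i.e. 20x).
#' @param width,height tile dimensions in pixels.
#' @return a \code{cell_map} tibble.
#' @export
cell_map <- function(cells, tile_id = "tile", microns_per_pixel = 0.5,
                     width = 2048L, height = 2048L) {
  cells <- tibble::as_tibble(cells)
  required <- c("cell_id", "x", "y", "class")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols) > 0L) {
    rlang::abort(paste0("cell map is missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(cells$cell_id)) rlang::abort("cell_ids must be unique")
  bad <- !cells$class %in% c("TIL", "nonTIL", "unassigned")
  if (any(bad)) rlang::abort("class must be TIL, nonTIL or unassigned")
  if (nrow(cells) > 0L &&
      (any(cells$x < 0 | cells$x > width - 1) ||
       any(cells$y < 0 | cells$y > height - 1))) {
    rlang::abort("centroids must lie inside the tile bounds")
  }
  structure(cells,
            class = c("cell_map", class(cells)),
            tile_id = tile_id,
            microns_per_pixel = microns_per_pixel,
            tile_width = as.integer(width),
            tile_height = as.integer(height))
}

#' @export
print.cell_map <- function(x, ...) {
  cat(sprintf("<cell_map> tile '%s' (%d x %d px, %.3g um/px): %d cells (%d TIL, %d nonTIL)\n",
              attr(x, "tile_id"), attr(x, "tile_width"),
              attr(x, "tile_height"), attr(x, "microns_per_pixel"),
              nrow(x), sum(x$class == "TIL"), sum(x$class == "nonTIL")))
  NextMethod()
}

microns_per_pixel <- function(cm) attr(cm, "microns_per_pixel") %||% 0.5

tile_dims <- function(cm) {
  c(width = attr(cm, "tile_width") %||% 2048L,
    height = attr(cm, "tile_height") %||% 2048L)
}

#' Read / write a cell map as CSV
#'
#' The CSV schema is one row per nucleus with columns \code{cell_id, x, y,
#' class} followed by any descriptor columns present.
#'
#' @param cm a \code{cell_map}.
#' @param path file path.
#' @param ... metadata passed to [cell_map()] on read.
#' @return \code{write_cell_map} returns \code{path} invisibly;
#'   \code{read_cell_map} returns a \code{cell_map}.
#' @export
write_cell_map <- function(cm, path) {
  utils::write.csv(as.data.frame(cm), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_map
#' @export
read_cell_map <- function(path, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cell_map(df, ...)
}

#' Plot a cell map as a point pattern
#'
#' @param cm a \code{cell_map}.
#' @param point_size point size passed to \code{geom_point}.
#' @return a ggplot object (y axis reversed to match image coordinates).
#' @export
plot_cell_map <- function(cm, point_size = 0.8) {
  ggplot2::ggplot(tibble::as_tibble(cm),
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data$class)) +
    ggplot2::geom_point(size = point_size) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = attr(cm, "tile_id"), x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}
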