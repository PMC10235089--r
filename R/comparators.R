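# Comparator feature families: denTIL tile-level density features, a
# reduced spaTIL spatial-architecture family, and the 4-moment patient
# aggregation shared by both.

#' Tile-level TIL density features (denTIL)
#'
#' Nineteen density descriptors of a tile: the three canonical ratios
#' (TILs per tissue area, TIL fraction of nuclei, TIL area fraction of
#' tissue) completed by a fixed set of counts, areas, and ratios. Areas are
#' in mm^2 via the cell map's pixel size. Ratios with zero denominators are
#' emitted as 0 and recorded in the \code{"guarded"} attribute.
#'
#' @param cm a [cell_map()] with an \code{area} column.
#' @param tissue_mask optional logical/integer matrix of tissue pixels;
#'   default treats the whole tile as tissue.
#' @return one-row tibble with 19 named features (attribute
#'   \code{"guarded"} lists the zero-guarded ones).
#' @export
dentil_features <- function(cm, tissue_mask = NULL) {
  mpp <- microns_per_pixel(cm)
  dims <- tile_dims(cm)
  px_to_mm2 <- mpp^2 / 1e6
  tissue_px <- if (is.null(tissue_mask)) {
    as.numeric(dims[["width"]]) * dims[["height"]]
  } else sum(tissue_mask > 0)
  tissue_mm2 <- tissue_px * px_to_mm2
  is_til <- cm$class == "TIL"
  n_til <- sum(is_til); n_nontil <- sum(cm$class == "nonTIL")
  n_nuclei <- nrow(cm)
  til_area <- sum(cm$area[is_til]) * px_to_mm2
  nontil_area <- sum(cm$area[cm$class == "nonTIL"]) * px_to_mm2
  nuc_area <- sum(cm$area) * px_to_mm2
  guarded <- character(0)
  ratio <- function(num, den, name) {
    if (den <= 0) {
      guarded <<- c(guarded, name)
      0
    } else num / den
  }
  out <- tibble::tibble(
    n_til_per_mm2 = ratio(n_til, tissue_mm2, "n_til_per_mm2"),
    frac_til_nuclei = ratio(n_til, n_nuclei, "frac_til_nuclei"),
    til_area_frac = ratio(til_area, tissue_mm2, "til_area_frac"),
    n_til = n_til,
    n_nontil = n_nontil,
    n_nuclei = n_nuclei,
    tissue_area_mm2 = tissue_mm2,
    til_area_mm2 = til_area,
    nontil_area_mm2 = nontil_area,
    nuclear_area_frac = ratio(nuc_area, tissue_mm2, "nuclear_area_frac"),
    n_nontil_per_mm2 = ratio(n_nontil, tissue_mm2, "n_nontil_per_mm2"),
    frac_nontil_nuclei = ratio(n_nontil, n_nuclei, "frac_nontil_nuclei"),
    nontil_area_frac = ratio(nontil_area, tissue_mm2, "nontil_area_frac"),
    til_area_share_nuclear = ratio(til_area, nuc_area,
                                   "til_area_share_nuclear"),
    til_nontil_count_ratio = ratio(n_til, n_nontil,
                                   "til_nontil_count_ratio"),
    til_nontil_area_ratio = ratio(til_area, nontil_area,
                                  "til_nontil_area_ratio"),
    mean_til_area = ratio(sum(cm$area[is_til]), n_til, "mean_til_area"),
    mean_nontil_area = ratio(sum(cm$area[cm$class == "nonTIL"]), n_nontil,
                             "mean_nontil_area"),
    til_per_1000_nuclei = 1000 * ratio(n_til, n_nuclei,
                                       "til_per_1000_nuclei"))
  attr(out, "guarded") <- unique(guarded)
  out
}

#' Spatial TIL-architecture features (spaTIL, reduced family)
#'
#' Builds, per class, the within-class centroid graph at
#' \code{linkage_radius} and takes its connected components as TIL /
#' non-TIL clusters. Reports cluster counts, convex-hull area statistics
#' (mean/sd/max) per class, the fraction of TIL clusters whose hull
#' intersects at least one non-TIL hull (intermixing), and the mean
#' pairwise hull-centroid distance between classes. This is a deliberately
#' reduced family; the full published catalog of several hundred items
#' belongs to prior work.
#'
#' @param cm a [cell_map()].
#' @param linkage_radius linkage distance in pixels.
#' @return one-row tibble with 10 named features.
#' @export
spatil_features <- function(cm, linkage_radius = 50) {
  til <- cm[cm$class == "TIL", c("x", "y")]
  non <- cm[cm$class == "nonTIL", c("x", "y")]
  ct <- point_components(til$x, til$y, linkage_radius)
  cn <- point_components(non$x, non$y, linkage_radius)
  hull_t <- component_hulls(til$x, til$y, ct)
  hull_n <- component_hulls(non$x, non$y, cn)
  a_t <- stat3(vapply(hull_t, function(hl) hl$area, numeric(1)))
  a_n <- stat3(vapply(hull_n, function(hl) hl$area, numeric(1)))
  intermix <- if (length(hull_t) == 0L) 0 else {
    mean(vapply(hull_t, function(ht) {
      any(vapply(hull_n, function(hn) hulls_intersect(ht$pts, hn$pts),
                 logical(1)))
    }, logical(1)))
  }
  cent_dist <- if (length(hull_t) > 0L && length(hull_n) > 0L) {
    ct_m <- t(vapply(hull_t, function(hl) hl$centroid, numeric(2)))
    cn_m <- t(vapply(hull_n, function(hl) hl$centroid, numeric(2)))
    mean(sqrt(outer(ct_m[, 1], cn_m[, 1], `-`)^2 +
                outer(ct_m[, 2], cn_m[, 2], `-`)^2))
  } else 0
  tibble::tibble(
    n_til_clusters = length(hull_t),
    n_nontil_clusters = length(hull_n),
    til_hull_area_mean = a_t[["mean"]],
    til_hull_area_sd = a_t[["sd"]],
    til_hull_area_max = a_t[["max"]],
    nontil_hull_area_mean = a_n[["mean"]],
    nontil_hull_area_sd = a_n[["sd"]],
    nontil_hull_area_max = a_n[["max"]],
    intermix_frac = intermix,
    hull_centroid_dist = cent_dist)
}

# Connected components of the centroid graph with edges at distance <=
# linkage_radius (igraph).
point_components <- function(x, y, linkage_radius) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  d <- as.matrix(stats::dist(cbind(x, y)))
  adj <- d <= linkage_radius
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  as.integer(igraph::components(g)$membership)
}

component_hulls <- function(x, y, membership) {
  if (length(membership) == 0L) return(list())
  lapply(split(seq_along(membership), membership), function(idx) {
    pts <- unique(cbind(x[idx], y[idx]))
    area <- 0
    if (nrow(pts) >= 3L) {
      hull <- grDevices::chull(pts)
      hp <- pts[hull, , drop = FALSE]
      j <- c(2:nrow(hp), 1L)
      area <- abs(sum(hp[, 1] * hp[j, 2] - hp[j, 1] * hp[, 2])) / 2
      pts <- hp
    }
    list(pts = pts, area = area,
         centroid = c(mean(pts[, 1]), mean(pts[, 2])))
  })
}

# Separating-axis intersection test for convex point sets (handles
# degenerate hulls: points and segments). Candidate axes are the edge
# normals and edge directions of both hulls, plus the centroid difference.
hulls_intersect <- function(p, q, eps = 1e-9) {
  axes <- rbind(edge_axes(p), edge_axes(q),
                matrix(colMeans(q) - colMeans(p), 1L))
  nrm <- sqrt(rowSums(axes^2))
  axes <- axes[nrm > eps, , drop = FALSE]
  if (nrow(axes) == 0L) {
    return(all(abs(colMeans(p) - colMeans(q)) < eps))
  }
  for (i in seq_len(nrow(axes))) {
    pp <- p %*% axes[i, ]
    qq <- q %*% axes[i, ]
    if (max(pp) < min(qq) - eps || max(qq) < min(pp) - eps) return(FALSE)
  }
  TRUE
}

edge_axes <- function(p) {
  n <- nrow(p)
  if (n < 2L) return(matrix(numeric(0), 0L, 2L))
  j <- c(2:n, 1L)
  e <- cbind(p[j, 1] - p[, 1], p[j, 2] - p[, 2])
  rbind(e, cbind(-e[, 2], e[, 1]))
}

#' Patient-level 4-moment aggregation of tile features
#'
#' Aggregates each tile-level feature across a patient's tiles into exactly
#' four statistics: mean, median, skewness and kurtosis (adjusted sample
#' estimators). Moments that are undefined for the available tile count
#' (skewness below 3 tiles, kurtosis below 4) or for zero spread are
#' emitted as 0 and listed in the \code{"flagged"} attribute.
#'
#' @param tile_table tibble with a \code{patient_id} column and numeric
#'   tile-level feature columns.
#' @return tibble, one row per patient, columns
#'   \code{<feature>_<mean|median|skewness|kurtosis>}.
#' @export
aggregate_patient <- function(tile_table) {
  tile_table <- tibble::as_tibble(tile_table)
  if (!"patient_id" %in% names(tile_table)) {
    rlang::abort("tile_table needs a patient_id column")
  }
  feats <- setdiff(names(tile_table), c("patient_id", "tile_id"))
  flagged <- character(0)
  out <- tile_table |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(dplyr::across(
      dplyr::all_of(feats),
      list(mean = mean,
           median = stats::median,
           skewness = sample_skewness,
           kurtosis = sample_kurtosis),
      .names = "{.col}_{.fn}"), .groups = "drop")
  for (cc in names(out)[-1L]) {
    bad <- is.na(out[[cc]])
    if (any(bad)) {
      flagged <- c(flagged, cc)
      out[[cc]][bad] <- 0
    }
  }
  attr(out, "flagged") <- flagged
  out
}
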