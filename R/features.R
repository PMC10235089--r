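# Contextual TIL features: 96 descriptors per neighborhood radius, three
# nested radii, 288 features per TIL.

#' Neighborhood specification
#'
#' Three nested closed discs centered on each TIL, with radii
#' \code{dL * c(10, 20, 30)} pixels where \code{dL} is the average
#' lymphocyte diameter at 20x (20 px), i.e. 200 / 400 / 600 px by default.
#' Discs are cumulative (not annular) and the index cell is excluded.
#'
#' @param dL average lymphocyte diameter in pixels.
#' @param multipliers radius multipliers (strictly increasing).
#' @return object of class \code{neighborhood_spec} with elements \code{dL}
#'   and \code{radii}.
#' @export
neighborhood_spec <- function(dL = 20, multipliers = c(10, 20, 30)) {
  if (dL <= 0) rlang::abort("dL must be positive")
  radii <- dL * multipliers
  if (any(radii <= 0) || is.unsorted(radii, strictly = TRUE)) {
    rlang::abort("radii must be positive and strictly increasing")
  }
  structure(list(dL = dL, radii = radii), class = "neighborhood_spec")
}

#' The ordered catalog of contextual TIL features
#'
#' Per radius, 96 descriptors in five families: A density (6), B neighbor
#' distance (8), C neighbor morphology (40), D neighbor color (18), and E
#' neighbor co-occurrence texture (24). Across the three radii this yields
#' the full 288-feature catalog. Names encode family content, statistic,
#' neighbor class and radius, e.g. \code{nbr_area_mean_til_r200}.
#'
#' @param spec a [neighborhood_spec()].
#' @return character vector of 288 unique feature names in canonical order.
#' @export
feature_catalog <- function(spec = neighborhood_spec()) {
  per_radius <- radius_catalog()
  unlist(lapply(spec$radii, function(r) paste0(per_radius, "_r", r)),
         use.names = FALSE)
}

# The 96 per-radius descriptor names (radius suffix applied on top).
radius_catalog <- function() {
  a <- c("n_til", "n_nontil", "n_total", "frac_til", "til_per_mm2",
         "nontil_per_mm2")
  b <- as.vector(t(outer(c("til", "nontil"), c("mean", "sd", "min", "max"),
                         function(cl, st) paste0("dist_", cl, "_", st))))
  cfam <- unlist(lapply(c("til", "nontil"), function(cl)
    unlist(lapply(morphology_columns(), function(m)
      paste0("nbr_", m, "_", c("mean", "sd", "min", "max"), "_", cl)))))
  dfam <- unlist(lapply(c("til", "nontil"), function(cl)
    unlist(lapply(c("R", "G", "B"), function(ch)
      paste0("color_", ch, "_", c("mean", "sd", "max"), "_", cl)))))
  e <- unlist(lapply(c("til", "nontil"), function(cl)
    paste0("har_", haralick_names(), "_", cl)))
  c(a, b, cfam, dfam, e)
}

#' Contextual feature vector of one TIL
#'
#' Computes the 288 contextual features of a single TIL from its
#' neighborhoods at the three radii. Neighbors are cells whose centroid lies
#' within the closed disc (distance <= r), excluding the index cell. Empty
#' neighbor groups follow the zero-fill convention: counts, densities and
#' all group statistics are 0.
#'
#' @param cm a [cell_map()] whose rows carry the descriptor columns (see
#'   [descriptor_columns()]).
#' @param til_id \code{cell_id} of a TIL-class cell.
#' @param spec a [neighborhood_spec()].
#' @return tibble with one row: \code{til_id} plus the 288 features.
#' @export
compute_til_features <- function(cm, til_id, spec = neighborhood_spec()) {
  i <- match(til_id, cm$cell_id)
  if (is.na(i)) rlang::abort("til_id not found in cell map")
  if (cm$class[i] != "TIL") {
    rlang::abort(sprintf("cell %s is not TIL-class", til_id))
  }
  check_descriptors(cm)
  row <- til_feature_row(i, cm, spec, microns_per_pixel(cm))
  names(row) <- feature_catalog(spec)
  dplyr::bind_cols(tibble::tibble(til_id = til_id),
                   tibble::as_tibble(as.list(row)))
}

#' Contextual feature table for all TILs of a cell map
#'
#' Batched application of [compute_til_features()] to every TIL, in
#' \code{cell_id} order. With zero TILs an empty table with the full
#' 288-column catalog is returned.
#'
#' @inheritParams compute_til_features
#' @return tibble (number of TILs x 289): \code{til_id} plus the catalog.
#' @export
extract_all <- function(cm, spec = neighborhood_spec()) {
  check_descriptors(cm)
  catalog <- feature_catalog(spec)
  tidx <- which(cm$class == "TIL")
  if (length(tidx) == 0L) {
    empty <- matrix(numeric(0), 0L, length(catalog),
                    dimnames = list(NULL, catalog))
    return(dplyr::bind_cols(tibble::tibble(til_id = integer(0)),
                            tibble::as_tibble(empty)))
  }
  mpp <- microns_per_pixel(cm)
  rows <- t(vapply(tidx, til_feature_row, numeric(length(catalog)),
                   cm = cm, spec = spec, mpp = mpp))
  colnames(rows) <- catalog
  dplyr::bind_cols(tibble::tibble(til_id = cm$cell_id[tidx]),
                   tibble::as_tibble(rows))
}

check_descriptors <- function(cm) {
  missing_cols <- setdiff(descriptor_columns(), names(cm))
  if (length(missing_cols) > 0L) {
    rlang::abort(paste0("cell map lacks descriptor column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  invisible(cm)
}

# One TIL's 288 features as a numeric vector (catalog order).
til_feature_row <- function(i, cm, spec, mpp) {
  d <- sqrt((cm$x - cm$x[i])^2 + (cm$y - cm$y[i])^2)
  til_mask <- cm$class == "TIL"
  out <- numeric(0)
  for (r in spec$radii) {
    nb <- which(d <= r)
    nb <- nb[nb != i]
    is_t <- til_mask[nb]
    n_t <- sum(is_t); n_n <- sum(!is_t); n_tot <- n_t + n_n
    disc_mm2 <- pi * r^2 * mpp^2 / 1e6
    fam_a <- c(n_t, n_n, n_tot,
               if (n_tot > 0L) n_t / n_tot else 0,
               n_t / disc_mm2, n_n / disc_mm2)
    fam_b <- c(stat4(d[nb[is_t]]), stat4(d[nb[!is_t]]))
    fam_c <- unlist(lapply(list(nb[is_t], nb[!is_t]), function(g)
      unlist(lapply(morphology_columns(), function(m) stat4(cm[[m]][g])))))
    fam_d <- unlist(lapply(list(nb[is_t], nb[!is_t]), function(g)
      unlist(lapply(color_columns(), function(ch) stat3(cm[[ch]][g])))))
    fam_e <- unlist(lapply(list(nb[is_t], nb[!is_t]), function(g)
      vapply(haralick_columns(),
             function(hc) if (length(g) > 0L) mean(cm[[hc]][g]) else 0,
             numeric(1))))
    out <- c(out, fam_a, fam_b, fam_c, fam_d, fam_e)
  }
  unname(out)
}
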