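# Single-cell molecular pairing: membrane marker quantification on
# co-registered IF stacks with AQUA normalization, argmax subtype labels,
# and cluster x subtype composition summaries.

#' Quantify TIL subtypes from a co-registered IF stack
#'
#' For every TIL in the cell map, isolates the membrane as a morphological
#' ring (dilation of the nucleus by \code{ring_width} minus the nucleus),
#' maps the ring pixels into the IF frame through the registration
#' transform, averages each marker channel over the ring, normalizes by the
#' per-marker AQUA scalar, and labels the cell with the argmax marker.
#' Exact ties are left \code{unassigned}; confidence is the top-to-second
#' ratio of normalized intensities.
#'
#' @param if_stack array (width x height x 3), channels CD4, CD8, CD20.
#' @param nucleus_mask integer label matrix in the H&E frame
#'   (labels = \code{cell_id}).
#' @param cm a [cell_map()] identifying the TIL-class cells.
#' @param transform optional \code{piecewise_linear_transform} mapping H&E
#'   to IF coordinates (NULL = identity).
#' @param ring_width membrane ring width in pixels (default 2 px at 20x,
#'   about 1 um).
#' @param aqua positive per-marker normalization scalars, names CD4, CD8,
#'   CD20.
#' @return tibble: \code{til_id}, raw and normalized per-marker
#'   intensities, \code{label} (CD4/CD8/CD20/unassigned), \code{confidence}.
#' @export
quantify_subtype <- function(if_stack, nucleus_mask, cm, transform = NULL,
                             ring_width = 2,
                             aqua = c(CD4 = 1, CD8 = 1, CD20 = 1)) {
  markers <- c("CD4", "CD8", "CD20")
  aqua <- aqua[markers]
  if (any(is.na(aqua)) || any(aqua <= 0)) {
    rlang::abort("aqua scalars must be positive and named CD4, CD8, CD20")
  }
  w <- dim(if_stack)[1]; h <- dim(if_stack)[2]
  til_ids <- cm$cell_id[cm$class == "TIL"]
  til_xy <- cbind(cm$x[cm$class == "TIL"], cm$y[cm$class == "TIL"])
  brush_r <- ceiling(ring_width)
  rows <- lapply(til_ids, function(id) {
    idx <- which(nucleus_mask == id)
    if (length(idx) == 0L) {
      return(stats::setNames(
        c(id, rep(NA_real_, 6), NA, NA),
        c("til_id", paste0("raw_", markers), paste0("norm_", markers),
          "label", "confidence")))
    }
    ring <- ring_pixels(nucleus_mask, idx, brush_r)
    xy <- cbind((ring - 1L) %% nrow(nucleus_mask),
                (ring - 1L) %/% nrow(nucleus_mask))
    # membrane isolation: contested pixels go to the nearest TIL
    i_own <- match(id, til_ids)
    own <- owned_by(xy[, 1], xy[, 2], i_own, til_xy[, 1], til_xy[, 2])
    if (any(own)) xy <- xy[own, , drop = FALSE]
    if (!is.null(transform)) {
      mapped <- predict(transform, xy)
      xy <- cbind(mapped$x, mapped$y)
    }
    px <- round(xy[, 1]) + 1L
    py <- round(xy[, 2]) + 1L
    keep <- px >= 1L & px <= w & py >= 1L & py <= h
    raw <- if (any(keep)) {
      vapply(1:3, function(ch) {
        mean(if_stack[cbind(px[keep], py[keep], ch)])
      }, numeric(1))
    } else rep(0, 3)
    norm <- raw / as.numeric(aqua)
    ord <- order(norm, decreasing = TRUE)
    tie <- abs(norm[ord[1]] - norm[ord[2]]) <= 1e-12
    label <- if (tie) NA_integer_ else ord[1]
    conf <- if (norm[ord[2]] > 0) norm[ord[1]] / norm[ord[2]] else Inf
    stats::setNames(c(id, raw, norm, label, conf),
                    c("til_id", paste0("raw_", markers),
                      paste0("norm_", markers), "label", "confidence"))
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  out$label <- ifelse(is.na(out$label), "unassigned", markers[out$label])
  out
}

# Pixels of the membrane ring: dilation of the nucleus pixel set by a disc
# of radius r, minus the nucleus itself.
ring_pixels <- function(mask, idx, r) {
  w <- nrow(mask); h <- ncol(mask)
  xs <- (idx - 1L) %% w
  ys <- (idx - 1L) %/% w
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 <= r^2, ]
  px <- outer(xs, offs$dx, `+`)
  py <- outer(ys, offs$dy, `+`)
  keep <- px >= 0L & px < w & py >= 0L & py < h
  lin <- unique(px[keep] + py[keep] * w + 1L)
  setdiff(lin, idx)
}

#' Cluster-by-subtype composition table
#'
#' Cross-tabulates cluster assignments with subtype calls. Percentages are
#' over assigned cells so each cluster row sums to 100; unassigned cells
#' are reported separately. The raw contingency counts (the chord-diagram
#' export) are attached as the \code{"counts"} attribute.
#'
#' @param cluster_labels tibble with \code{til_id} and \code{cluster}, or
#'   an integer vector aligned with \code{subtype_calls}.
#' @param subtype_calls output of [quantify_subtype()].
#' @param K number of clusters.
#' @return tibble: \code{cluster}, \code{CD4}, \code{CD8}, \code{CD20}
#'   (percent), \code{n_assigned}, \code{n_unassigned}; empty clusters get
#'   zero rows and are listed in the \code{"empty_clusters"} attribute.
#' @export
cluster_subtype_composition <- function(cluster_labels, subtype_calls,
                                        K = 8L) {
  markers <- c("CD4", "CD8", "CD20")
  if (is.atomic(cluster_labels)) {
    df <- tibble::tibble(til_id = subtype_calls$til_id,
                         cluster = as.integer(cluster_labels))
  } else {
    df <- tibble::as_tibble(cluster_labels)
  }
  joined <- dplyr::inner_join(df, subtype_calls[, c("til_id", "label")],
                              by = "til_id")
  counts <- table(factor(joined$cluster, levels = seq_len(K)),
                  factor(joined$label, levels = markers))
  counts <- matrix(as.integer(counts), K, 3L,
                   dimnames = list(paste0("C", seq_len(K)), markers))
  unassigned <- tapply(joined$label == "unassigned",
                       factor(joined$cluster, levels = seq_len(K)), sum)
  unassigned[is.na(unassigned)] <- 0L
  tot <- rowSums(counts)
  pct <- counts / ifelse(tot > 0, tot, 1) * 100
  out <- tibble::tibble(
    cluster = rownames(counts),
    CD4 = unname(pct[, "CD4"]), CD8 = unname(pct[, "CD8"]),
    CD20 = unname(pct[, "CD20"]),
    n_assigned = unname(tot),
    n_unassigned = as.integer(unassigned))
  attr(out, "counts") <- counts
  attr(out, "empty_clusters") <- rownames(counts)[tot == 0]
  out
}

#' Stacked-bar plot of cluster subtype composition
#'
#' @param composition output of [cluster_subtype_composition()].
#' @return a ggplot object.
#' @export
plot_cluster_composition <- function(composition) {
  long <- tidyr::pivot_longer(
    composition[, c("cluster", "CD4", "CD8", "CD20")],
    cols = c("CD4", "CD8", "CD20"),
    names_to = "subtype", values_to = "percent")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cluster, y = .data$percent,
                                     fill = .data$subtype)) +
    ggplot2::geom_col() +
    ggplot2::labs(y = "% of assigned TILs", x = NULL) +
    ggplot2::theme_minimal()
}
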