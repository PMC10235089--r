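# Synthetic tissue generators: clustered TIL/non-TIL point patterns with
# planted phenotypes, rendered H&E-like tiles, survival outcomes with a
# planted cluster effect, co-registered IF stacks, and expression matrices.

#' Generate a synthetic cell map with planted phenotypes
#'
#' TIL centroids follow a Thomas cluster process (hotspot parents uniform in
#' the tile, Poisson offspring with isotropic Gaussian dispersion); non-TIL
#' centroids follow a homogeneous Poisson process. Each hotspot is assigned
#' a planted phenotype and its TILs draw their per-nucleus descriptors from
#' that phenotype's Gaussian; non-TILs draw from a separate profile.
#' Overlapping nuclei are resolved by rejection sampling with a minimum
#' centroid separation of \code{0.8 * (r1 + r2)} (nuclear radii from the
#' equivalent diameter), bounded at 50 retries per cell.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to \code{config$seed}).
#' @return list with elements \code{cell_map} (a [cell_map()]) and
#'   \code{truth} (planted phenotype per cell, subtype per TIL, hotspot
#'   table, and the planted \code{beta_star}).
#' @export
gen_cell_map <- function(config, seed = config$seed) {
  validate_sim_config(config)
  local_seed(seed, {
    ts <- config$tile_size
    k <- length(config$phenotypes)
    area_mm2 <- (ts * config$microns_per_pixel / 1000)^2

    # hotspot parents and offspring
    n_hot <- config$n_til_hotspots
    # parents keep an edge margin so offspring stay in-tile
    margin <- min(2 * config$hotspot_dispersion, ts / 4)
    hotspots <- if (n_hot > 0L) {
      tibble::tibble(
        hotspot = seq_len(n_hot),
        hx = stats::runif(n_hot, margin, ts - 1 - margin),
        hy = stats::runif(n_hot, margin, ts - 1 - margin),
        phenotype = sample.int(k, n_hot, replace = TRUE))
    } else {
      tibble::tibble(hotspot = integer(), hx = numeric(), hy = numeric(),
                     phenotype = integer())
    }
    til_parent <- integer(0)
    if (n_hot > 0L) {
      counts <- stats::rpois(n_hot, config$til_per_hotspot)
      til_parent <- rep(seq_len(n_hot), counts)
    }
    n_til <- length(til_parent)
    n_nontil <- stats::rpois(1L, config$lambda_nontil * area_mm2)

    phen <- c(if (n_til > 0L) hotspots$phenotype[til_parent],
              rep(NA_integer_, n_nontil))
    is_til <- c(rep(TRUE, n_til), rep(FALSE, n_nontil))
    n <- n_til + n_nontil

    desc <- draw_descriptors(phen, is_til, config)

    pos <- place_cells(is_til, til_parent, hotspots, desc$equiv_diameter,
                       config)

    subtype <- rep(NA_character_, n)
    if (n_til > 0L) {
      markers <- colnames(config$subtype_mix)
      subtype[is_til] <- vapply(phen[is_til], function(p) {
        sample(markers, 1L, prob = config$subtype_mix[p, ])
      }, character(1))
    }

    cells <- tibble::tibble(
      cell_id = seq_len(n),
      x = pos$x, y = pos$y,
      class = ifelse(is_til, "TIL", "nonTIL"),
      orientation = stats::runif(n, 0, pi))
    cells <- dplyr::bind_cols(cells, desc)

    cm <- cell_map(cells, tile_id = sprintf("sim-seed%s", seed),
                   microns_per_pixel = config$microns_per_pixel,
                   width = ts, height = ts)
    truth <- list(true_phenotype = phen,
                  true_subtype = subtype,
                  hotspots = hotspots,
                  true_beta = config$beta_star)
    list(cell_map = cm, truth = truth)
  })
}

# Draw per-nucleus descriptors from the planted Gaussians, clamped to the
# domain of each descriptor.
draw_descriptors <- function(phen, is_til, config) {
  cols <- descriptor_columns()
  n <- length(is_til)
  out <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  draw_from <- function(profile, m) {
    sweep(m * matrix(stats::rnorm(nrow(m) * ncol(m)), nrow(m)), 2,
          profile$mean[cols], `+`)
  }
  for (p in unique(phen[is_til])) {
    idx <- which(is_til & phen == p)
    prof <- config$phenotypes[[p]]
    sds <- matrix(prof$sd[cols], length(idx), length(cols), byrow = TRUE)
    out[idx, ] <- draw_from(prof, sds)
  }
  idx <- which(!is_til)
  if (length(idx) > 0L) {
    prof <- config$nontil_profile
    sds <- matrix(prof$sd[cols], length(idx), length(cols), byrow = TRUE)
    out[idx, ] <- draw_from(prof, sds)
  }
  d <- tibble::as_tibble(out)
  if (n > 0L) {
    d$area <- pmax(d$area, 30)
    d$equiv_diameter <- pmax(d$equiv_diameter, 4)
    d$perimeter <- pmax(d$perimeter, 10)
    d$eccentricity <- clamp(d$eccentricity, 0, 0.98)
    d$solidity <- clamp(d$solidity, 0.5, 1)
    for (cc in color_columns()) d[[cc]] <- clamp(d[[cc]], 0.02, 0.98)
    d$har_asm <- clamp(d$har_asm, 1e-4, 1)
    d$har_idm <- clamp(d$har_idm, 1e-4, 1)
    for (cc in c("har_contrast", "har_variance", "har_sum_variance",
                 "har_sum_entropy", "har_entropy", "har_diff_variance",
                 "har_diff_entropy")) d[[cc]] <- pmax(d[[cc]], 0)
    d$har_correlation <- clamp(d$har_correlation, -1, 1)
    d$har_imc1 <- clamp(d$har_imc1, -1, 0)
  }
  d
}

# Sequential placement with minimum centroid separation 0.8*(r1+r2),
# resolved by rejection sampling bounded at 50 retries per cell. Uses a
# uniform grid for neighbor lookups.
place_cells <- function(is_til, til_parent, hotspots, equiv_diameter,
                        config) {
  n <- length(is_til)
  ts <- config$tile_size
  if (n == 0L) return(list(x = numeric(0), y = numeric(0)))
  r <- equiv_diameter / 2
  cell_px <- max(16, ceiling(0.8 * 2 * max(r)))
  ngrid <- max(1L, ceiling(ts / cell_px))
  grid <- vector("list", ngrid * ngrid)
  gkey <- function(x, y) {
    gi <- pmin(pmax(floor(x / cell_px), 0), ngrid - 1)
    gj <- pmin(pmax(floor(y / cell_px), 0), ngrid - 1)
    gi * ngrid + gj + 1
  }
  x <- numeric(n); y <- numeric(n)
  propose <- function(i) {
    if (is_til[i]) {
      p <- til_parent[i]
      c(stats::rnorm(1, hotspots$hx[p], config$hotspot_dispersion),
        stats::rnorm(1, hotspots$hy[p], config$hotspot_dispersion))
    } else {
      stats::runif(2, 0, ts - 1)
    }
  }
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(50L)) {
      pr <- propose(i)
      if (pr[1] < 0 || pr[1] > ts - 1 || pr[2] < 0 || pr[2] > ts - 1) next
      gi <- floor(pr[1] / cell_px); gj <- floor(pr[2] / cell_px)
      ok <- TRUE
      for (di in -1:1) for (dj in -1:1) {
        ci <- gi + di; cj <- gj + dj
        if (ci < 0 || ci >= ngrid || cj < 0 || cj >= ngrid) next
        for (j in grid[[ci * ngrid + cj + 1]]) {
          minsep <- 0.8 * (r[i] + r[j])
          if ((pr[1] - x[j])^2 + (pr[2] - y[j])^2 < minsep^2) {
            ok <- FALSE
            break
          }
        }
        if (!ok) break
      }
      if (ok) {
        x[i] <- pr[1]; y[i] <- pr[2]
        key <- gkey(pr[1], pr[2])
        grid[[key]] <- c(grid[[key]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rlang::abort(paste0(
        "degenerate configuration: could not place cell ", i,
        " without overlap after 50 retries (expected cell count exceeds ",
        "tile capacity)"))
    }
  }
  list(x = x, y = y)
}

#' Render a cell map as an H&E-like tile
#'
#' Paints each nucleus as an anti-aliased ellipse over an eosin-pink
#' background with additive Gaussian noise: TILs are smaller, rounder and
#' hematoxylin-dark; non-TILs larger and paler (colors come from each
#' nucleus's \code{mean_R/G/B} descriptors). The label mask assigns each
#' painted pixel its \code{cell_id}.
#'
#' @param cm a [cell_map()] with descriptor columns.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param background background RGB triple in \code{[0, 1]}.
#' @param seed RNG seed for the noise.
#' @return list with \code{image} (array width x height x 3 in \code{[0, 1]})
#'   and \code{mask} (integer matrix width x height of cell ids).
#' @export
render_tile <- function(cm, noise_sd = 0.01,
                        background = c(0.92, 0.80, 0.86), seed = 1L) {
  dims <- tile_dims(cm)
  w <- dims[["width"]]; h <- dims[["height"]]
  img <- array(rep(background, each = w * h), dim = c(w, h, 3))
  mask <- matrix(0L, w, h)
  local_seed(seed, {
    for (i in seq_len(nrow(cm))) {
      ecc <- cm$eccentricity[i]
      a <- sqrt(cm$area[i] / (pi * sqrt(1 - ecc^2)))
      b <- a * sqrt(1 - ecc^2)
      th <- if ("orientation" %in% names(cm)) cm$orientation[i] else 0
      col <- c(cm$mean_R[i], cm$mean_G[i], cm$mean_B[i])
      paint <- paint_ellipse(w, h, cm$x[i], cm$y[i], a, b, th)
      if (is.null(paint)) next
      px <- paint$px; py <- paint$py; alpha <- paint$alpha
      tex <- stats::rnorm(length(alpha), 0, 0.03)
      for (ch in 1:3) {
        idx <- cbind(px, py, ch)
        img[idx] <- img[idx] * (1 - alpha) + clamp(col[ch] + tex, 0, 1) * alpha
      }
      core <- alpha > 0.5
      mask[cbind(px[core], py[core])] <- cm$cell_id[i]
    }
    if (noise_sd > 0) {
      img <- clamp(img + stats::rnorm(length(img), 0, noise_sd), 0, 1)
    }
  })
  list(image = img, mask = mask)
}

# Anti-aliased coverage of an ellipse over the pixel grid: pixels within the
# bounding box get alpha from a soft step on the normalized ellipse metric.
paint_ellipse <- function(w, h, cx, cy, a, b, theta) {
  ext <- ceiling(a + 1.5)
  x0 <- max(0, floor(cx - ext)); x1 <- min(w - 1, ceiling(cx + ext))
  y0 <- max(0, floor(cy - ext)); y1 <- min(h - 1, ceiling(cy + ext))
  if (x1 < x0 || y1 < y0) return(NULL)
  gx <- x0:x1; gy <- y0:y1
  u <- outer(gx - cx, rep(1, length(gy)))
  v <- outer(rep(1, length(gx)), gy - cy)
  ru <- u * cos(theta) + v * sin(theta)
  rv <- -u * sin(theta) + v * cos(theta)
  m <- sqrt((ru / a)^2 + (rv / b)^2)
  # soft edge roughly one pixel wide
  alpha <- clamp((1 - m) * a + 0.5, 0, 1)
  keep <- which(alpha > 0)
  if (length(keep) == 0L) return(NULL)
  list(px = (row(alpha)[keep] + x0 - 1) + 1L,
       py = (col(alpha)[keep] + y0 - 1) + 1L,
       alpha = alpha[keep])
}

#' Simulate survival outcomes from cluster counts with a planted effect
#'
#' Event times are exponential with log-hazard proportional to the planted
#' linear predictor over column-standardized cluster counts; censoring is an
#' independent exponential clock calibrated so that roughly
#' \code{censor_rate} of patients are censored.
#'
#' @param cluster_counts matrix (patients x clusters) of TIL counts.
#' @param beta_star planted log-hazard weights (per standard deviation of
#'   each count column).
#' @param censor_rate expected censored fraction in \code{[0, 1)}.
#' @param seed RNG seed.
#' @param median_survival baseline median survival in months.
#' @return tibble with \code{patient_id}, \code{time} (months, > 0) and
#'   \code{event} (1 = death, 0 = censored).
#' @export
gen_survival <- function(cluster_counts, beta_star, censor_rate = 0.2,
                         seed = 1L, median_survival = 30) {
  N <- as.matrix(cluster_counts)
  stopifnot(ncol(N) == length(beta_star), censor_rate >= 0, censor_rate < 1)
  z <- scale(N)
  z[, attr(z, "scaled:scale") < 1e-12] <- 0
  eta <- drop(z %*% beta_star)
  lambda0 <- log(2) / median_survival
  local_seed(seed, {
    t_event <- stats::rexp(nrow(N), rate = lambda0 * exp(eta))
    if (censor_rate > 0) {
      lambda_c <- lambda0 * censor_rate / (1 - censor_rate)
      t_cens <- stats::rexp(nrow(N), rate = lambda_c)
    } else {
      t_cens <- rep(Inf, nrow(N))
    }
    tibble::tibble(
      patient_id = rownames(N) %||% paste0("P", seq_len(nrow(N))),
      time = pmax(pmin(t_event, t_cens), 1e-6),
      event = as.integer(t_event <= t_cens))
  })
}

#' Simulate a co-registered immunofluorescence stack
#'
#' Each TIL contributes a bright membrane ring in the channel of its planted
#' subtype (CD4/CD8/CD20) at its distorted position; the other channels see
#' only noise. The distortion is a known control-point displacement applied
#' through the same piecewise-linear model the registration module fits, so
#' that recovery is exact in the noise-free limit.
#'
#' @param cm a [cell_map()].
#' @param truth truth list from [gen_cell_map()] (uses \code{true_subtype}).
#' @param distortion either NULL (identity) or a list with matrices
#'   \code{src} and \code{dst} of control points (H&E frame to IF frame).
#' @param nucleus_mask optional label mask (e.g. from [render_tile()]);
#'   when given, each TIL's membrane is the dilation of its actual nucleus
#'   shape, otherwise a circular annulus around the centroid is used.
#' @param ring_width membrane ring width in pixels.
#' @param intensity peak membrane intensity.
#' @param noise_sd channel noise standard deviation (0 = noise-free).
#' @param seed RNG seed.
#' @return list with \code{stack} (width x height x 3 array, channels CD4,
#'   CD8, CD20), \code{coords} (tibble of distorted TIL centroids) and
#'   \code{transform} (the H&E-to-IF transform used, or NULL).
#' @export
gen_if_stack <- function(cm, truth, distortion = NULL, nucleus_mask = NULL,
                         ring_width = 2, intensity = 0.9, noise_sd = 0,
                         seed = 1L) {
  dims <- tile_dims(cm)
  w <- dims[["width"]]; h <- dims[["height"]]
  markers <- c("CD4", "CD8", "CD20")
  stack <- array(0, dim = c(w, h, 3), dimnames = list(NULL, NULL, markers))
  tr <- NULL
  til <- cm[cm$class == "TIL", , drop = FALSE]
  sub <- truth$true_subtype[cm$class == "TIL"]
  xy <- cbind(til$x, til$y)
  if (!is.null(distortion)) {
    tr <- fit_registration(distortion$src, distortion$dst)
    pred <- predict(tr, xy)
    xy <- cbind(pred$x, pred$y)
  }
  local_seed(seed, {
    if (nrow(til) > 0L) {
      for (i in seq_len(nrow(til))) {
        ch <- match(sub[i], markers)
        if (is.null(nucleus_mask)) {
          r_in <- til$equiv_diameter[i] / 2
          ring <- annulus_pixels(w, h, xy[i, 1], xy[i, 2], r_in,
                                 r_in + ring_width)
          rx <- ring$px - 1L; ry <- ring$py - 1L
        } else {
          idx <- which(nucleus_mask == til$cell_id[i])
          if (length(idx) == 0L) next
          lin <- ring_pixels(nucleus_mask, idx, ceiling(ring_width))
          rx <- (lin - 1L) %% nrow(nucleus_mask)
          ry <- (lin - 1L) %/% nrow(nucleus_mask)
        }
        if (length(rx) == 0L) next
        # contested membrane pixels belong to the nearest TIL only
        own <- owned_by(rx, ry, i, til$x, til$y)
        if (!is.null(distortion)) {
          mapped <- predict(tr, cbind(rx, ry))
          rx <- round(mapped$x); ry <- round(mapped$y)
        }
        keep <- own & rx >= 0 & rx < w & ry >= 0 & ry < h
        if (any(keep)) {
          stack[cbind(rx[keep] + 1L, ry[keep] + 1L, ch)] <- intensity
        }
      }
    }
    if (noise_sd > 0) {
      stack <- clamp(stack + stats::rnorm(length(stack), 0, noise_sd), 0, 1)
    }
  })
  list(stack = stack,
       coords = tibble::tibble(til_id = til$cell_id,
                               x = xy[, 1], y = xy[, 2],
                               subtype = sub),
       transform = tr)
}

# TRUE where (px, py) (0-based) is at least as close to cell i as to any
# other cell in (cx, cy).
owned_by <- function(px, py, i, cx, cy) {
  d_own <- (px - cx[i])^2 + (py - cy[i])^2
  own <- rep(TRUE, length(px))
  for (j in seq_along(cx)) {
    if (j == i) next
    own <- own & d_own <= (px - cx[j])^2 + (py - cy[j])^2
  }
  own
}

annulus_pixels <- function(w, h, cx, cy, r_in, r_out) {
  ext <- ceiling(r_out + 1)
  x0 <- max(0, floor(cx - ext)); x1 <- min(w - 1, ceiling(cx + ext))
  y0 <- max(0, floor(cy - ext)); y1 <- min(h - 1, ceiling(cy + ext))
  if (x1 < x0 || y1 < y0) return(list(px = integer(0), py = integer(0)))
  gx <- x0:x1; gy <- y0:y1
  d2 <- outer((gx - cx)^2, rep(1, length(gy))) +
    outer(rep(1, length(gx)), (gy - cy)^2)
  keep <- which(d2 >= r_in^2 & d2 <= r_out^2)
  list(px = (row(d2)[keep] + x0 - 1) + 1L,
       py = (col(d2)[keep] + y0 - 1) + 1L)
}

#' Simulate a gene-expression matrix with planted cluster correlations
#'
#' Planted genes are linear in the standardized counts of one target cluster
#' plus Gaussian noise calibrated so the population Pearson correlation is
#' \code{effect_r}; background genes are independent standard normals.
#'
#' @param cluster_counts matrix (patients x clusters).
#' @param planted_gene_count,background_gene_count numbers of genes.
#' @param effect_r planted population correlation in \code{[-1, 1]}.
#' @param target_cluster which cluster column carries the signal.
#' @param seed RNG seed.
#' @return list with \code{expr} (genes x patients matrix, planted genes
#'   named \code{PGENE*}, background \code{BGENE*}) and
#'   \code{planted_genes} (character vector).
#' @export
gen_expression <- function(cluster_counts, planted_gene_count = 10L,
                           background_gene_count = 990L, effect_r = 0.9,
                           target_cluster = 1L, seed = 1L) {
  N <- as.matrix(cluster_counts)
  stopifnot(abs(effect_r) <= 1)
  n <- nrow(N)
  z <- as.numeric(scale(N[, target_cluster]))
  if (anyNA(z)) z <- rep(0, n)
  local_seed(seed, {
    planted <- matrix(
      effect_r * rep(z, each = planted_gene_count) +
        sqrt(1 - effect_r^2) * stats::rnorm(planted_gene_count * n),
      nrow = planted_gene_count, ncol = n)
    background <- matrix(stats::rnorm(background_gene_count * n),
                         nrow = background_gene_count, ncol = n)
    expr <- rbind(planted, background)
    rownames(expr) <- c(sprintf("PGENE%03d", seq_len(planted_gene_count)),
                        sprintf("BGENE%04d", seq_len(background_gene_count)))
    colnames(expr) <- rownames(N) %||% paste0("P", seq_len(n))
    list(expr = expr, planted_genes = rownames(expr)[seq_len(planted_gene_count)])
  })
}

#' Simulate per-patient cluster-count matrices
#'
#' Cohort-level shortcut past tile simulation: each patient's niche counts
#' are Poisson with per-patient log-normal heterogeneity around
#' cluster-specific mean abundances, emulating the variation of niche
#' composition across tumors.
#'
#' @param n_patients cohort size.
#' @param mean_counts expected TIL count per cluster (length K).
#' @param heterogeneity standard deviation of the per-patient log-normal
#'   abundance factor (per cluster).
#' @param seed RNG seed.
#' @return integer matrix (patients x K) with dimnames.
#' @export
gen_cluster_counts <- function(n_patients, mean_counts = c(20, 15, 25, 10,
                                                           30, 12, 18, 22),
                               heterogeneity = 0.4, seed = 1L) {
  K <- length(mean_counts)
  local_seed(seed, {
    lam <- matrix(mean_counts, n_patients, K, byrow = TRUE) *
      exp(matrix(stats::rnorm(n_patients * K, 0, heterogeneity),
                 n_patients, K))
    m <- matrix(stats::rpois(n_patients * K, lam), n_patients, K,
                dimnames = list(sprintf("P%04d", seq_len(n_patients)),
                                paste0("C", seq_len(K))))
    m
  })
}
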