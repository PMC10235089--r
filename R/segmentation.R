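# Stain normalization, watershed nuclei segmentation, per-nucleus
# descriptors and TIL/non-TIL classification.
#
# Images are numeric arrays (width x height x 3) in [0, 1]; masks are
# integer label matrices (width x height). An ingest path exists for
# externally produced masks/classes: extract_descriptors() accepts any
# label mask and classify_tils() any record table, so deep-learned
# segmentations can be loaded from file and fed through the same surface.

# Standard H&E optical-density stain vectors (hematoxylin, eosin), used as
# the fallback deconvolution basis and reference profile.
ruifrok_stains <- function() {
  m <- cbind(h = c(0.650, 0.704, 0.286), e = c(0.072, 0.990, 0.105))
  sweep(m, 2, sqrt(colSums(m^2)), `/`)
}

od_transform <- function(img) -log(pmax(img, 1 / 255))

#' Estimate a Macenko stain profile from a tile
#'
#' Spectral estimation of the two dominant stain vectors: optical densities
#' of tissue pixels (OD above \code{beta}) are projected onto their
#' top-two principal plane and the extreme-angle directions (robust 1st and
#' 99th percentiles) are taken as the hematoxylin and eosin vectors.
#' Also records the robust (99th percentile) stain concentrations used to
#' scale images during normalization.
#'
#' @param img RGB array (width x height x 3) in \code{[0, 1]}.
#' @param beta optical-density threshold below which pixels are considered
#'   background and excluded from estimation.
#' @param alpha percentile (in percent) for the robust angle extremes.
#' @return list with \code{stains} (3 x 2 matrix, columns hematoxylin and
#'   eosin) and \code{max_conc} (length-2 robust concentrations).
#' @export
macenko_fit_reference <- function(img, beta = 0.15, alpha = 1) {
  od <- matrix(od_transform(img), ncol = 3L)
  tissue <- od[rowSums(od) > beta * 3, , drop = FALSE]
  if (nrow(tissue) < 0.01 * nrow(od) || nrow(tissue) < 10L) {
    rlang::abort("insufficient tissue: fewer than 1% of pixels above the OD threshold")
  }
  v <- eigen(stats::cov(tissue), symmetric = TRUE)$vectors[, 1:2]
  # orient the plane so projections are mostly positive
  proj <- tissue %*% v
  for (j in 1:2) if (sum(proj[, j]) < 0) {
    v[, j] <- -v[, j]; proj[, j] <- -proj[, j]
  }
  phi <- atan2(proj[, 2], proj[, 1])
  q <- stats::quantile(phi, c(alpha / 100, 1 - alpha / 100), names = FALSE)
  dirs <- vapply(q, function(a) v %*% c(cos(a), sin(a)), numeric(3))
  dirs <- pmax(dirs, 0)
  dirs <- sweep(dirs, 2, sqrt(colSums(dirs^2)), `/`)
  # hematoxylin has the larger red optical density
  if (dirs[1, 1] < dirs[1, 2]) dirs <- dirs[, 2:1]
  colnames(dirs) <- c("h", "e")
  conc <- stain_concentrations(od, dirs)
  list(stains = dirs,
       max_conc = apply(conc, 2, stats::quantile, 0.99, names = FALSE))
}

stain_concentrations <- function(od, stains) {
  od %*% t(MASS_ginv(stains))
}

# Moore-Penrose pseudoinverse via SVD (3 x 2 stain matrices).
MASS_ginv <- function(m, tol = 1e-10) {
  s <- svd(m)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Macenko stain normalization
#'
#' Maps a tile's stain appearance onto a reference profile: estimates the
#' tile's own stain vectors and robust concentrations ([macenko_fit_reference()]),
#' rescales the per-pixel concentrations to the reference maxima, and
#' reconstructs the image in the reference stain basis. Tiles with less
#' than 1% tissue pixels raise an insufficient-tissue error.
#'
#' @param img RGB array (width x height x 3) in \code{[0, 1]}.
#' @param reference a profile as returned by [macenko_fit_reference()];
#'   default is the standard H&E basis with unit robust concentrations.
#' @param beta background OD threshold.
#' @return normalized RGB array, same dimensions.
#' @export
macenko_normalize <- function(img, reference = NULL, beta = 0.15) {
  if (is.null(reference)) {
    reference <- list(stains = ruifrok_stains(), max_conc = c(1, 1))
  }
  src <- macenko_fit_reference(img, beta = beta)
  od <- matrix(od_transform(img), ncol = 3L)
  conc <- stain_concentrations(od, src$stains)
  conc <- sweep(conc, 2, reference$max_conc / pmax(src$max_conc, 1e-8), `*`)
  od_new <- conc %*% t(reference$stains)
  out <- exp(-od_new)
  array(clamp(out, 0, 1), dim = dim(img))
}

#' Hematoxylin concentration map
#'
#' Color-deconvolves the tile against a stain basis and returns the
#' hematoxylin channel, the substrate for nuclei segmentation.
#'
#' @inheritParams macenko_normalize
#' @param stains 3 x 2 stain matrix (default standard H&E vectors).
#' @return matrix (width x height) of hematoxylin concentrations.
#' @export
hematoxylin_channel <- function(img, stains = ruifrok_stains()) {
  od <- matrix(od_transform(img), ncol = 3L)
  conc <- stain_concentrations(od, stains)
  matrix(conc[, 1], dim(img)[1], dim(img)[2])
}

#' Watershed-based nuclei segmentation
#'
#' Pipeline: hematoxylin-channel deconvolution, Gaussian smoothing,
#' foreground thresholding against the background level (median plus
#' 3 robust standard deviations, with an absolute concentration floor;
#' robust to tiles where dark lymphocyte and paler epithelial nuclei form
#' separate intensity modes), distance transform, and distance-driven
#' watershed to split touching nuclei. Objects below \code{min_area}
#' (16 px^2 at 20x, sub-lymphocyte debris) are removed and labels are
#' renumbered consecutively.
#'
#' @param img RGB array (width x height x 3) in \code{[0, 1]}, ideally
#'   stain-normalized.
#' @param min_area minimum object area in px^2.
#' @param sigma Gaussian smoothing sigma in pixels.
#' @param floor_od absolute hematoxylin-concentration floor for foreground.
#' @param tolerance watershed tolerance (minimum object depth).
#' @return integer label matrix (width x height); empty (all-zero) masks
#'   are allowed.
#' @export
segment_nuclei <- function(img, min_area = 16, sigma = 1, floor_od = 0.3,
                           tolerance = 0.5) {
  h <- hematoxylin_channel(img)
  hs <- as.matrix(EBImage::gblur(EBImage::Image(h), sigma = sigma))
  rng <- range(hs)
  if (rng[2] - rng[1] < 1e-6 || rng[2] < floor_od) {
    return(matrix(0L, nrow(h), ncol(h)))
  }
  thr <- max(stats::median(hs) + 3 * stats::mad(hs), floor_od)
  fg <- hs > thr
  if (!any(fg)) return(matrix(0L, nrow(h), ncol(h)))
  dm <- EBImage::distmap(EBImage::Image(fg))
  labels <- EBImage::watershed(dm, tolerance = tolerance, ext = 1)
  lab <- matrix(as.integer(EBImage::imageData(labels)), nrow(h), ncol(h))
  drop_small_objects(lab, min_area)
}

drop_small_objects <- function(lab, min_area) {
  if (max(lab) == 0L) return(lab)
  sizes <- tabulate(lab, nbins = max(lab))
  keep <- which(sizes >= min_area)
  remap <- integer(max(lab))
  remap[keep] <- seq_along(keep)
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

#' Per-nucleus descriptors from an image and label mask
#'
#' Computes, for every labeled object: centroid (0-based pixels), area,
#' perimeter, eccentricity, equivalent diameter, solidity (pixel count over
#' the lattice-point count of the convex hull), orientation, per-channel
#' color statistics, and the twelve co-occurrence texture statistics of the
#' grayscale bounding-box patch ([glcm_stats()]). Class is set to
#' \code{"unassigned"}.
#'
#' @param img RGB array (width x height x 3) in \code{[0, 1]}.
#' @param mask integer label matrix (width x height).
#' @param ... metadata passed to [cell_map()].
#' @return a [cell_map()] with one row per label.
#' @export
extract_descriptors <- function(img, mask, ...) {
  w <- nrow(mask); h <- ncol(mask)
  n <- max(mask)
  if (n == 0L) {
    empty <- tibble::tibble(cell_id = integer(0), x = numeric(0),
                            y = numeric(0), class = character(0),
                            orientation = numeric(0))
    for (cc in descriptor_columns()) empty[[cc]] <- numeric(0)
    extras <- descriptor_extras()
    for (cc in extras) empty[[cc]] <- numeric(0)
    return(cell_map(empty, width = w, height = h, ...))
  }
  m_img <- EBImage::Image(mask)
  shape <- EBImage::computeFeatures.shape(m_img)
  gray <- 0.2989 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  mom <- EBImage::computeFeatures.moment(m_img, EBImage::Image(gray))
  labels <- sort(unique(mask[mask > 0L]))
  px_list <- split(which(mask > 0L), mask[mask > 0L])
  rows <- lapply(labels, function(l) {
    idx <- px_list[[as.character(l)]]
    xs <- (idx - 1L) %% w          # 0-based x
    ys <- (idx - 1L) %/% w         # 0-based y
    area <- length(idx)
    sol <- convex_solidity(xs, ys, area)
    chans <- lapply(1:3, function(ch) img[idx + (ch - 1L) * w * h])
    patch <- gray[(min(xs) + 1L):(max(xs) + 1L),
                  (min(ys) + 1L):(max(ys) + 1L), drop = FALSE]
    har <- glcm_stats(patch)
    c(cell_id = l,
      x = mom[l, "m.cx"] - 1, y = mom[l, "m.cy"] - 1,
      orientation = mom[l, "m.theta"],
      area = area,
      perimeter = shape[l, "s.perimeter"],
      eccentricity = min(mom[l, "m.eccentricity"], 1),
      equiv_diameter = 2 * sqrt(area / pi),
      solidity = sol,
      mean_R = mean(chans[[1]]), mean_G = mean(chans[[2]]),
      mean_B = mean(chans[[3]]),
      stats::setNames(as.numeric(har), haralick_columns()),
      sd_R = stats::sd(chans[[1]]) %|NA|% 0,
      sd_G = stats::sd(chans[[2]]) %|NA|% 0,
      sd_B = stats::sd(chans[[3]]) %|NA|% 0,
      min_R = min(chans[[1]]), min_G = min(chans[[2]]),
      min_B = min(chans[[3]]),
      max_R = max(chans[[1]]), max_G = max(chans[[2]]),
      max_B = max(chans[[3]]),
      mean_gray = mean(gray[idx]))
  })
  df <- tibble::as_tibble(do.call(rbind, rows))
  df$class <- "unassigned"
  cell_map(df, width = w, height = h, ...)
}

descriptor_extras <- function() {
  c("sd_R", "sd_G", "sd_B", "min_R", "min_G", "min_B",
    "max_R", "max_G", "max_B", "mean_gray")
}

`%|NA|%` <- function(x, y) if (is.na(x)) y else x

# Solidity = pixel area / lattice-point count of the convex hull of pixel
# centers. The hull lattice count uses Pick's theorem (A = I + B/2 - 1 so
# I + B = A + B/2 + 1) with B from gcds along hull edges, which makes
# solidity exactly 1 for convex pixel regions.
convex_solidity <- function(xs, ys, area) {
  pts <- unique(cbind(xs, ys))
  if (nrow(pts) <= 2L) return(1)
  hull <- grDevices::chull(pts)
  hp <- pts[hull, , drop = FALSE]
  nh <- nrow(hp)
  if (nh < 3L) return(1)
  j <- c(2:nh, 1L)
  a2 <- abs(sum(hp[, 1] * hp[j, 2] - hp[j, 1] * hp[, 2]))
  shoelace <- a2 / 2
  b <- sum(mapply(function(i1, i2) {
    dgcd(abs(hp[i2, 1] - hp[i1, 1]), abs(hp[i2, 2] - hp[i1, 2]))
  }, seq_len(nh), j))
  hull_count <- shoelace + b / 2 + 1
  min(area / hull_count, 1)
}

dgcd <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  max(a, 1L)
}

#' Default TIL classification rule
#'
#' Thresholds on nuclear area, solidity and gray-level darkness that
#' separate small round hematoxylin-dark lymphocyte nuclei from larger,
#' paler epithelial/stromal nuclei.
#'
#' @param max_area maximum TIL area in px^2.
#' @param max_intensity maximum mean grayscale intensity (darkness).
#' @param min_solidity minimum solidity (roundness/compactness).
#' @return a rule object for [classify_tils()].
#' @export
til_rule <- function(max_area = 450, max_intensity = 0.52,
                     min_solidity = 0.8) {
  structure(list(max_area = max_area, max_intensity = max_intensity,
                 min_solidity = min_solidity), class = "til_rule")
}

#' Classify nuclei into TIL vs non-TIL
#'
#' Rule mode (default) applies [til_rule()] thresholds to each nucleus
#' record; model mode applies any fitted classifier with a
#' \code{predict(model, records)} method returning \code{"TIL"}/
#' \code{"nonTIL"} labels (e.g. a linear SVM trained on the descriptor
#' columns). Every record is assigned; the result is deterministic for a
#' fixed rule or model.
#'
#' @param records a [cell_map()] (or nucleus record table).
#' @param model a [til_rule()] or a fitted classifier.
#' @return the input with \code{class} filled with \code{"TIL"}/\code{"nonTIL"}.
#' @export
classify_tils <- function(records, model = til_rule()) {
  if (nrow(records) == 0L) return(records)
  if (inherits(model, "til_rule")) {
    gray <- if ("mean_gray" %in% names(records)) records$mean_gray else
      0.2989 * records$mean_R + 0.587 * records$mean_G +
        0.114 * records$mean_B
    is_til <- records$area <= model$max_area &
      gray <= model$max_intensity &
      records$solidity >= model$min_solidity
  } else {
    pred <- stats::predict(model, records)
    is_til <- as.character(pred) == "TIL"
  }
  records$class <- ifelse(is_til, "TIL", "nonTIL")
  records
}

#' Fit a maximum-margin TIL classifier
#'
#' Trains a linear support-vector machine on the descriptor columns of
#' labeled nucleus records (requires the \pkg{e1071} package).
#'
#' @param records record table with descriptor columns.
#' @param labels factor/character vector of \code{"TIL"}/\code{"nonTIL"}.
#' @return fitted classifier usable as \code{model} in [classify_tils()].
#' @export
fit_til_classifier <- function(records, labels) {
  if (!requireNamespace("e1071", quietly = TRUE)) {
    rlang::abort("fit_til_classifier requires the e1071 package")
  }
  x <- as.matrix(records[, descriptor_columns()])
  fit <- e1071::svm(x, factor(labels, levels = c("TIL", "nonTIL")),
                    kernel = "linear", scale = TRUE)
  structure(list(svm = fit), class = "til_svm")
}

#' @export
predict.til_svm <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, descriptor_columns()])
  stats::predict(object$svm, x)
}

#' Write a label mask as 16-bit TIFF
#'
#' @param mask integer label matrix (width x height).
#' @param path output path.
#' @return \code{path}, invisibly. Requires the \pkg{tiff} package.
#' @export
write_mask_tiff <- function(mask, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    rlang::abort("write_mask_tiff requires the tiff package")
  }
  tiff::writeTIFF(t(mask) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
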