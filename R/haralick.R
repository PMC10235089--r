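#' Gray-level co-occurrence (Haralick) statistics of an image patch
#'
#' Computes twelve co-occurrence texture statistics on a grayscale patch:
#' angular second moment, contrast, correlation, sum-of-squares variance,
#' inverse difference moment, sum average, sum variance, sum entropy,
#' entropy, difference variance, difference entropy, and information
#' measure of correlation 1. Intensities in \code{[0, 1]} are quantized to
#' \code{levels} gray levels; the symmetric co-occurrence matrix is built at
#' distance 1 and the statistics are averaged over the four standard
#' directions (0, 45, 90, 135 degrees).
#'
#' Degenerate inputs follow a fixed convention: a constant patch yields
#' angular second moment 1, inverse difference moment 1, contrast 0 and all
#' entropies 0; statistics whose definition involves a zero standard
#' deviation (correlation) are reported as 0.
#'
#' @param patch numeric matrix with values in \code{[0, 1]}.
#' @param levels number of gray levels for quantization (default 32).
#' @return named numeric vector of length 12 (names \code{asm},
#'   \code{contrast}, \code{correlation}, \code{variance}, \code{idm},
#'   \code{sum_average}, \code{sum_variance}, \code{sum_entropy},
#'   \code{entropy}, \code{diff_variance}, \code{diff_entropy},
#'   \code{imc1}).
#' @export
glcm_stats <- function(patch, levels = 32L) {
  stopifnot(is.matrix(patch), levels >= 2L)
  q <- pmin(floor(pmin(pmax(patch, 0), 1) * levels), levels - 1L) + 1L
  nr <- nrow(q); nc <- ncol(q)
  offsets <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  acc <- numeric(12L)
  n_used <- 0L
  for (off in offsets) {
    dr <- off[1L]; dc <- off[2L]
    if (nr - dr < 1L || nc - abs(dc) < 1L) next
    r1 <- seq_len(nr - dr)
    c1 <- if (dc >= 0L) seq_len(nc - dc) else seq.int(1L - dc, nc)
    if (length(r1) == 0L || length(c1) == 0L) next
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dr, c1 + dc, drop = FALSE]
    p <- glcm_matrix(a, b, levels)
    acc <- acc + glcm_statistics(p)
    n_used <- n_used + 1L
  }
  out <- if (n_used == 0L) {
    # single-pixel patch: treat as constant
    c(1, 0, 0, 0, 1, 2 * q[1L, 1L], 0, 0, 0, 0, 0, 0)
  } else acc / n_used
  names(out) <- haralick_names()
  out
}

haralick_names <- function() {
  c("asm", "contrast", "correlation", "variance", "idm", "sum_average",
    "sum_variance", "sum_entropy", "entropy", "diff_variance",
    "diff_entropy", "imc1")
}

glcm_matrix <- function(a, b, levels) {
  idx <- (as.integer(a) - 1L) * levels + as.integer(b)
  counts <- tabulate(idx, nbins = levels * levels)
  p <- matrix(counts, levels, levels, byrow = TRUE)
  p <- p + t(p)
  p / sum(p)
}

glcm_statistics <- function(p) {
  L <- nrow(p)
  i <- seq_len(L)
  I <- matrix(i, L, L)
  J <- t(I)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(i * px); muy <- sum(i * py)
  sdx <- sqrt(sum((i - mux)^2 * px)); sdy <- sqrt(sum((i - muy)^2 * py))

  asm <- sum(p^2)
  contrast <- sum((I - J)^2 * p)
  correlation <- if (sdx > 1e-12 && sdy > 1e-12)
    (sum(I * J * p) - mux * muy) / (sdx * sdy) else 0
  variance <- sum((I - mux)^2 * p)
  idm <- sum(p / (1 + (I - J)^2))

  # p_{x+y}(k), k = 2..2L and p_{|x-y|}(k), k = 0..L-1
  ksum <- 2:(2 * L)
  psum <- vapply(ksum, function(k) sum(p[I + J == k]), numeric(1))
  kdiff <- 0:(L - 1)
  pdiff <- vapply(kdiff, function(k) sum(p[abs(I - J) == k]), numeric(1))

  sum_average <- sum(ksum * psum)
  sum_variance <- sum((ksum - sum_average)^2 * psum)
  sum_entropy <- -sum(psum[psum > 0] * log(psum[psum > 0]))
  entropy <- -sum(p[p > 0] * log(p[p > 0]))
  dmean <- sum(kdiff * pdiff)
  diff_variance <- sum((kdiff - dmean)^2 * pdiff)
  diff_entropy <- -sum(pdiff[pdiff > 0] * log(pdiff[pdiff > 0]))

  pxy <- outer(px, py)
  ok <- p > 0 & pxy > 0
  hxy1 <- -sum(p[ok] * log(pxy[ok]))
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  imc1 <- if (max(hx, hy) > 1e-12) (entropy - hxy1) / max(hx, hy) else 0

  c(asm, contrast, correlation, variance, idm, sum_average, sum_variance,
    sum_entropy, entropy, diff_variance, diff_entropy, imc1)
}
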