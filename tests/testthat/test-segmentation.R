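# Stain normalization, watershed segmentation and TIL classification.

# A pure two-stain synthetic tile: H&E concentrations -> transmitted RGB.
two_stain_tile <- function(seed = 1, n = 64, scale = 1) {
  set.seed(seed)
  stains <- phenotil:::ruifrok_stains()
  ch <- matrix(runif(n * n, 0, 1.2), n * n) * scale
  ce <- matrix(runif(n * n, 0, 0.8), n * n) * scale
  od <- cbind(ch, ce) %*% t(stains)
  array(exp(-od), dim = c(n, n, 3))
}

test_that("self-normalization is a near-identity", {
  img <- two_stain_tile(seed = 2)
  ref <- macenko_fit_reference(img)
  out <- macenko_normalize(img, reference = ref)
  # max change no more than 2 gray levels on the 8-bit scale
  expect_lt(max(abs(out - img)) * 255, 2)
})

test_that("a pure-white tile raises an insufficient-tissue error", {
  white <- array(1, dim = c(32, 32, 3))
  expect_error(macenko_normalize(white), "insufficient tissue")
  expect_error(macenko_fit_reference(white), "insufficient tissue")
})

test_that("globally scaled stain concentrations normalize back to the original", {
  img <- two_stain_tile(seed = 5)
  ref <- macenko_fit_reference(img)
  scaled <- two_stain_tile(seed = 5, scale = 1.35)
  out <- macenko_normalize(scaled, reference = ref)
  base <- macenko_normalize(img, reference = ref)
  expect_lt(mean(abs(out - base)), 0.02)
  expect_lt(max(abs(out - base)), 0.1)
})

test_that("a blank tile segments to an empty mask", {
  blank <- array(0.95, dim = c(64, 64, 3))
  mask <- segment_nuclei(blank)
  expect_true(all(mask == 0L))
})

test_that("rendered tiles re-segment with object F1 >= 0.9 at IoU 0.5", {
  cfg <- sim_config(tile_size = 512L, n_til_hotspots = 3L,
                    til_per_hotspot = 25, lambda_nontil = 800,
                    hotspot_dispersion = 40)
  g <- gen_cell_map(cfg, seed = 42)
  r <- render_tile(g$cell_map, seed = 7)
  lab <- segment_nuclei(r$image)
  expect_gte(object_f1(lab, r$mask, iou = 0.5), 0.9)
})

test_that("two touching nuclei are split by the watershed", {
  cm <- toy_cell_map(x = c(100, 117), y = c(100, 100),
                     class = c("TIL", "TIL"),
                     area = 200, eccentricity = 0.1,
                     mean_R = 0.35, mean_G = 0.3, mean_B = 0.55,
                     width = 220, height = 220)
  cm$orientation <- 0
  r <- render_tile(cm, noise_sd = 0.005, seed = 3)
  lab <- segment_nuclei(r$image)
  expect_equal(max(lab), 2L)
})

test_that("segmented object counts are invariant to 90-degree rotation", {
  cfg <- sim_config(tile_size = 384L, n_til_hotspots = 2L,
                    til_per_hotspot = 15, lambda_nontil = 500,
                    hotspot_dispersion = 40)
  g <- gen_cell_map(cfg, seed = 12)
  r <- render_tile(g$cell_map, seed = 5)
  lab0 <- segment_nuclei(r$image)
  rot <- array(0, dim = dim(r$image))
  for (ch in 1:3) rot[, , ch] <- t(r$image[, dim(r$image)[2]:1, ch])
  lab90 <- segment_nuclei(rot)
  expect_equal(max(lab90), max(lab0))
})

test_that("analytic shapes yield the expected descriptors", {
  # a disc: eccentricity near 0, solidity near 1
  n <- 64
  img <- array(0.9, dim = c(n, n, 3))
  mask <- matrix(0L, n, n)
  cx <- 32; cy <- 32; rad <- 12
  for (i in 1:n) for (j in 1:n) {
    if ((i - cx)^2 + (j - cy)^2 <= rad^2) mask[i, j] <- 1L
  }
  cm <- extract_descriptors(img, mask)
  expect_lte(cm$eccentricity[1], 0.05)
  expect_gte(cm$solidity[1], 0.98)
  expect_equal(cm$equiv_diameter[1], 2 * sqrt(cm$area[1] / pi))

  # a 10x10 square: area exactly 100, solidity 1
  mask2 <- matrix(0L, n, n)
  mask2[20:29, 30:39] <- 1L
  cm2 <- extract_descriptors(img, mask2)
  expect_equal(cm2$area[1], 100)
  expect_equal(cm2$solidity[1], 1)
})

test_that("color descriptors equal brute-force per-pixel recomputation", {
  set.seed(21)
  n <- 40
  img <- array(runif(n * n * 3), dim = c(n, n, 3))
  mask <- matrix(0L, n, n)
  mask[5:12, 7:15] <- 1L
  mask[25:33, 20:30] <- 2L
  cm <- extract_descriptors(img, mask)
  for (l in 1:2) {
    idx <- which(mask == l)
    for (ch in 1:3) {
      vals <- img[, , ch][idx]
      expect_equal(cm[[c("mean_R", "mean_G", "mean_B")[ch]]][l], mean(vals))
      expect_equal(cm[[c("max_R", "max_G", "max_B")[ch]]][l], max(vals))
    }
    expect_equal(cm$area[l], length(idx))
  }
})

test_that("rule-mode classification partitions all records and is accurate", {
  cfg <- sim_config(tile_size = 512L, n_til_hotspots = 3L,
                    til_per_hotspot = 25, lambda_nontil = 800,
                    hotspot_dispersion = 40)
  accs <- sapply(c(42, 43), function(s) {
    g <- gen_cell_map(cfg, seed = s)
    r <- render_tile(g$cell_map, seed = s + 100)
    cm <- classify_tils(extract_descriptors(r$image, segment_nuclei(r$image)))
    expect_true(all(cm$class %in% c("TIL", "nonTIL")))
    near <- apply(cbind(cm$x, cm$y), 1, function(p)
      which.min((g$cell_map$x - p[1])^2 + (g$cell_map$y - p[2])^2))
    mean(cm$class == g$cell_map$class[near])
  })
  expect_true(all(accs >= 0.95))
})

test_that("an empty record table classifies to an empty cell map", {
  blank <- array(0.95, dim = c(32, 32, 3))
  cm <- extract_descriptors(blank, matrix(0L, 32, 32))
  out <- classify_tils(cm)
  expect_equal(nrow(out), 0L)
})

test_that("a trained margin classifier beats chance and scores training >= holdout", {
  skip_if_not_installed("e1071")
  cfg <- sim_config(tile_size = 512L, n_til_hotspots = 3L,
                    til_per_hotspot = 25, lambda_nontil = 800,
                    hotspot_dispersion = 40)
  g1 <- gen_cell_map(cfg, seed = 31)
  g2 <- gen_cell_map(cfg, seed = 32)
  fit <- fit_til_classifier(g1$cell_map, g1$cell_map$class)
  train_acc <- mean(as.character(predict(fit, g1$cell_map)) ==
                      g1$cell_map$class)
  test_acc <- mean(as.character(predict(fit, g2$cell_map)) ==
                     g2$cell_map$class)
  expect_gte(train_acc, test_acc - 0.02)
  expect_gt(test_acc, 0.9)
})
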