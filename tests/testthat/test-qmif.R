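# Control-point registration and single-cell subtype pairing.

test_that("identical control points give the identity map", {
  set.seed(1)
  pts <- cbind(x = runif(10, 0, 100), y = runif(10, 0, 100))
  tr <- fit_registration(pts, pts)
  q <- cbind(runif(30, 10, 90), runif(30, 10, 90))
  pred <- predict(tr, q)
  expect_lt(max(abs(cbind(pred$x, pred$y) - q)), 1e-9)
})

test_that("a known affine distortion is recovered exactly inside the hull", {
  set.seed(2)
  src <- cbind(x = runif(15, 0, 400), y = runif(15, 0, 400))
  A <- matrix(c(0.97, 0.05, -0.04, 1.03), 2)
  b <- c(12, -8)
  dst <- t(A %*% t(src)) + rep(b, each = nrow(src))
  tr <- fit_registration(src, dst)
  # exact at the control points
  at_cp <- predict(tr, src)
  expect_lt(max(abs(cbind(at_cp$x, at_cp$y) - dst)), 1e-9)
  # and everywhere inside the hull
  q <- cbind(runif(100, 100, 300), runif(100, 100, 300))
  pred <- predict(tr, q)
  want <- t(A %*% t(q)) + rep(b, each = 100)
  inside <- !pred$out_of_hull
  expect_gt(sum(inside), 50)
  expect_lt(max(abs(cbind(pred$x, pred$y)[inside, ] - want[inside, ])),
            1e-6)
})

test_that("degenerate control-point geometry is rejected", {
  tri <- cbind(c(0, 1, 0), c(0, 0, 1))
  expect_error(fit_registration(tri, tri), "at least 4")
  line <- cbind(1:5, 2 * (1:5))
  expect_error(fit_registration(line, line), "collinear")
  dup <- cbind(c(0, 0, 1, 2), c(0, 0, 1, 0))
  expect_error(fit_registration(dup, dup), "duplicate")
})

test_that("composing a transform with its swapped-role inverse is identity", {
  set.seed(3)
  src <- cbind(x = runif(12, 0, 200), y = runif(12, 0, 200))
  dst <- src + cbind(rnorm(12, 5, 2), rnorm(12, -3, 2))
  fwd <- fit_registration(src, dst)
  inv <- fit_registration(dst, src)
  q <- cbind(runif(40, 50, 150), runif(40, 50, 150))
  there <- predict(fwd, q)
  back <- predict(inv, cbind(there$x, there$y))
  ok <- !there$out_of_hull & !back$out_of_hull
  expect_gt(sum(ok), 10)
  expect_lt(max(abs(cbind(back$x, back$y)[ok, ] - q[ok, ])), 1e-6)
})

test_that("a uniform single-marker ring is labeled with that marker", {
  w <- 64
  stack <- array(0, dim = c(w, w, 3))
  mask <- matrix(0L, w, w)
  for (i in 1:w) for (j in 1:w) {
    d2 <- (i - 32)^2 + (j - 32)^2
    if (d2 <= 8^2) mask[i, j] <- 1L
    if (d2 > 8^2 && d2 <= 10^2) stack[i, j, 2] <- 100  # CD8 on the ring
  }
  cm <- toy_cell_map(x = 31, y = 31, class = "TIL", width = w, height = w)
  calls <- quantify_subtype(stack, mask, cm, ring_width = 2)
  expect_equal(calls$label, "CD8")
  expect_equal(calls$norm_CD8, 100)
  expect_equal(calls$raw_CD4, 0)

  # all channels equal: the tie rule leaves the cell unassigned
  stack_tie <- array(0.5, dim = c(w, w, 3))
  calls_tie <- quantify_subtype(stack_tie, mask, cm)
  expect_equal(calls_tie$label, "unassigned")
})

test_that("labels are invariant to common channel scaling; AQUA rescales", {
  cfg <- sim_config(tile_size = 256L, n_til_hotspots = 2L,
                    til_per_hotspot = 10, lambda_nontil = 300,
                    hotspot_dispersion = 30)
  g <- gen_cell_map(cfg, seed = 4)
  ifs <- gen_if_stack(g$cell_map, g$truth, noise_sd = 0.01, seed = 2)
  r <- render_tile(g$cell_map, noise_sd = 0, seed = 1)
  c1 <- quantify_subtype(ifs$stack, r$mask, g$cell_map)
  c2 <- quantify_subtype(ifs$stack * 3.7, r$mask, g$cell_map)
  expect_equal(c2$label, c1$label)
  # a very large AQUA scalar on one marker suppresses it
  c3 <- quantify_subtype(ifs$stack, r$mask, g$cell_map,
                         aqua = c(CD4 = 1, CD8 = 1e6, CD20 = 1))
  expect_false(any(c3$label == "CD8"))
  expect_error(quantify_subtype(ifs$stack, r$mask, g$cell_map,
                                aqua = c(CD4 = -1, CD8 = 1, CD20 = 1)),
               "positive")
})

test_that("noise-free synthetic IF reproduces the planted subtypes exactly", {
  cfg <- sim_config(tile_size = 384L, n_til_hotspots = 2L,
                    til_per_hotspot = 15, lambda_nontil = 400,
                    hotspot_dispersion = 35)
  g <- gen_cell_map(cfg, seed = 3)
  r <- render_tile(g$cell_map, noise_sd = 0, seed = 1)
  ifs <- gen_if_stack(g$cell_map, g$truth, nucleus_mask = r$mask,
                      noise_sd = 0)
  calls <- quantify_subtype(ifs$stack, r$mask, g$cell_map)
  truth_sub <- g$truth$true_subtype[g$cell_map$class == "TIL"]
  expect_equal(calls$label, truth_sub)
})

test_that("composition percentages reconcile with contingency counts", {
  calls <- tibble::tibble(til_id = 1:4,
                          label = c("CD8", "CD8", "CD4", "CD20"))
  comp <- cluster_subtype_composition(rep(1L, 4), calls, K = 2)
  expect_equal(comp$CD4[1], 25)
  expect_equal(comp$CD8[1], 50)
  expect_equal(comp$CD20[1], 25)
  expect_equal(sum(comp[1, c("CD4", "CD8", "CD20")]), 100)
  # empty cluster: zero row, flagged
  expect_equal(comp$n_assigned[2], 0)
  expect_true("C2" %in% attr(comp, "empty_clusters"))
  # percentages x counts reconcile
  counts <- attr(comp, "counts")
  expect_equal(unname(counts["C1", ]), c(1L, 2L, 1L))
  expect_equal(unname(rowSums(counts)), comp$n_assigned)
  # unassigned reported separately
  calls2 <- tibble::tibble(til_id = 1:3,
                           label = c("CD4", "unassigned", "unassigned"))
  comp2 <- cluster_subtype_composition(rep(1L, 3), calls2, K = 1)
  expect_equal(comp2$n_assigned, 1)
  expect_equal(comp2$n_unassigned, 2L)
})
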