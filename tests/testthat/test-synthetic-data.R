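# The generators define the study conditions every downstream stage is
# exercised under; these tests pin their distributional behavior.

small_cfg <- function(...) {
  sim_config(tile_size = 512L, n_til_hotspots = 3L, til_per_hotspot = 40,
             lambda_nontil = 800, hotspot_dispersion = 50, ...)
}

test_that("an empty configuration yields an empty cell map without error", {
  cfg <- sim_config(tile_size = 256L, n_til_hotspots = 0L,
                    lambda_nontil = 0)
  g <- gen_cell_map(cfg, seed = 1)
  expect_s3_class(g$cell_map, "cell_map")
  expect_equal(nrow(g$cell_map), 0L)
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- small_cfg()
  expect_identical(gen_cell_map(cfg, seed = 7), gen_cell_map(cfg, seed = 7))
  N <- gen_cluster_counts(40, seed = 5)
  expect_identical(N, gen_cluster_counts(40, seed = 5))
  expect_identical(gen_survival(N, rep(1, 8), seed = 2),
                   gen_survival(N, rep(1, 8), seed = 2))
  ge <- gen_expression(N, 5, 50, effect_r = 0.5, seed = 3)
  expect_identical(ge, gen_expression(N, 5, 50, effect_r = 0.5, seed = 3))
})

test_that("TIL counts fall in the Poisson 99% band of the planted mean", {
  # 3 hotspots x mean 40 offspring: total count is Poisson(120)
  band <- qpois(c(0.005, 0.995), lambda = 120)
  counts <- sapply(1:10, function(s) {
    g <- gen_cell_map(small_cfg(), seed = s)
    sum(g$cell_map$class == "TIL")
  })
  expect_true(all(counts >= band[1] & counts <= band[2]))
})

test_that("subtype fractions converge to the planted mix", {
  mix <- matrix(c(0.1, 0.86, 0.04), 1, dimnames = list("P1", c("CD4", "CD8", "CD20")))
  cfg <- sim_config(tile_size = 1024L, n_til_hotspots = 8L,
                    til_per_hotspot = 60, lambda_nontil = 0,
                    hotspot_dispersion = 60,
                    phenotypes = default_phenotypes(1),
                    subtype_mix = mix, beta_star = 1)
  g <- gen_cell_map(cfg, seed = 2)
  sub <- g$truth$true_subtype[g$cell_map$class == "TIL"]
  n <- length(sub)
  for (m in colnames(mix)) {
    # binomial 99% band around the planted probability
    band <- qbinom(c(0.005, 0.995), n, mix[1, m]) / n
    expect_gte(mean(sub == m), band[1])
    expect_lte(mean(sub == m), band[2])
  }
})

test_that("overcrowded configurations raise a degenerate-config error", {
  cfg <- sim_config(tile_size = 64L, n_til_hotspots = 4L,
                    til_per_hotspot = 200, hotspot_dispersion = 5,
                    lambda_nontil = 0)
  expect_error(gen_cell_map(cfg, seed = 1), "degenerate")
})

test_that("zero censoring yields all events; null effect yields HR near 1", {
  N <- gen_cluster_counts(500, seed = 8)
  s0 <- gen_survival(N, rep(1, 8), censor_rate = 0, seed = 1)
  expect_true(all(s0$event == 1))
  expect_true(all(s0$time > 0))

  # beta_star = 0: the group hazard ratio estimate should cover 1
  snull <- gen_survival(N, rep(0, 8), censor_rate = 0.2, seed = 4)
  scores <- compute_osrs(N, rep(1, 8))  # arbitrary scores, no true effect
  gr <- stratify(scores, median(scores))
  ev <- evaluate_survival(snull, gr, scores)
  expect_gt(ev$hr_ci[["upper"]], 1)
  expect_lt(ev$hr_ci[["lower"]], 1)
})

test_that("a noise-free IF stack encodes the planted subtypes exactly", {
  cfg <- small_cfg()
  g <- gen_cell_map(cfg, seed = 3)
  ifs <- gen_if_stack(g$cell_map, g$truth, noise_sd = 0)
  til <- g$cell_map[g$cell_map$class == "TIL", ]
  expect_equal(nrow(ifs$coords), nrow(til))
  # zero distortion: IF coordinates equal H&E coordinates
  expect_equal(ifs$coords$x, til$x)
  expect_equal(ifs$coords$y, til$y)
  # each TIL's subtype channel is lit at its ring, others dark
  markers <- c("CD4", "CD8", "CD20")
  for (i in seq_len(min(nrow(til), 20))) {
    ch <- match(ifs$coords$subtype[i], markers)
    r <- til$equiv_diameter[i] / 2 + 1
    px <- round(til$x[i] + r) + 1
    py <- round(til$y[i]) + 1
    if (px <= dim(ifs$stack)[1]) {
      vals <- ifs$stack[px, py, ]
      expect_equal(unname(which.max(vals)), ch)
    }
  }
})

test_that("null expression matrices show no spurious strong correlations", {
  N <- gen_cluster_counts(400, seed = 6)
  ge <- gen_expression(N, planted_gene_count = 0,
                       background_gene_count = 300, effect_r = 0, seed = 9)
  corr <- correlate_expression(ge$expr, N[, 1, drop = FALSE])
  # Bonferroni null bound at alpha = 0.01 for 300 genes, n = 400:
  # |r| < r_crit where t_crit = qt(1 - alpha/(2*300), n - 2)
  tcrit <- qt(1 - 0.01 / (2 * 300), 398)
  rcrit <- tcrit / sqrt(398 + tcrit^2)
  expect_lt(max(abs(unclass(corr))), rcrit)
})

test_that("planted expression effects reach the calibrated correlation", {
  N <- gen_cluster_counts(400, seed = 10)
  ge <- gen_expression(N, 10, 990, effect_r = 0.9, seed = 11)
  corr <- correlate_expression(ge$expr, N[, 1, drop = FALSE])
  planted_r <- abs(unclass(corr)[ge$planted_genes, 1])
  expect_gt(min(planted_r), 0.8)
})
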