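# The Gaussian-mixture phenotype model.

sep_gaussians <- function(n_per = 150, K = 3, p = 6, sep = 10, seed = 1) {
  set.seed(seed)
  mu <- matrix(rnorm(K * p), K, p) * sep
  x <- do.call(rbind, lapply(seq_len(K), function(k)
    sweep(matrix(rnorm(n_per * p), n_per, p), 2, mu[k, ], `+`)))
  colnames(x) <- paste0("f", seq_len(p))
  list(x = tibble::as_tibble(x), labels = rep(seq_len(K), each = n_per))
}

test_that("paper-mode fits have exactly 8 components with unit weights", {
  d <- sep_gaussians(n_per = 20, K = 8, sep = 6, seed = 2)
  fit <- fit_phenotype_model(d$x, K = 8, seed = 1, n_restarts = 2)
  expect_equal(fit$K, 8L)
  expect_length(fit$weights, 8L)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
})

test_that("well-separated planted mixtures are recovered (ARI >= 0.99)", {
  d <- sep_gaussians(n_per = 200, K = 3, sep = 8, seed = 3)
  fit <- fit_phenotype_model(d$x, K = 3, seed = 5)
  lab <- assign_clusters(fit, d$x)
  expect_gte(adjusted_rand(lab, d$labels), 0.99)
})

test_that("fits agree with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  d <- sep_gaussians(n_per = 150, K = 3, sep = 8, seed = 9)
  fit <- fit_phenotype_model(d$x, K = 3, seed = 2)
  lab <- assign_clusters(fit, d$x)
  mc <- mclust::Mclust(as.matrix(d$x), G = 3, modelNames = "VVI",
                       verbose = FALSE)
  expect_gte(adjusted_rand(lab, mc$classification), 0.99)
})

test_that("fitting is deterministic for a fixed seed", {
  d <- sep_gaussians(n_per = 60, K = 4, sep = 4, seed = 4)
  f1 <- fit_phenotype_model(d$x, K = 4, seed = 11)
  f2 <- fit_phenotype_model(d$x, K = 4, seed = 11)
  expect_identical(f1, f2)
})

test_that("EM log-likelihood is non-decreasing", {
  d <- sep_gaussians(n_per = 80, K = 3, sep = 2, seed = 6)
  fit <- fit_phenotype_model(d$x, K = 3, seed = 3, n_restarts = 1)
  expect_true(all(diff(fit$loglik_trace) >= -1e-6))
})

test_that("posterior responsibilities sum to one per TIL", {
  d <- sep_gaussians(n_per = 70, K = 3, sep = 3, seed = 7)
  fit <- fit_phenotype_model(d$x, K = 3, seed = 4)
  post <- predict(fit, d$x, type = "posterior")
  expect_equal(rowSums(post), rep(1, nrow(d$x)), tolerance = 1e-9)
})

test_that("assignments equal the brute-force per-component argmax", {
  d <- sep_gaussians(n_per = 50, K = 3, sep = 3, seed = 8)
  fit <- fit_phenotype_model(d$x, K = 3, seed = 6)
  lab <- assign_clusters(fit, d$x)
  z <- phenotil:::standardize_for_model(fit, d$x)
  want <- apply(z, 1, function(row) {
    ll <- sapply(seq_len(fit$K), function(k) {
      log(fit$weights[k]) +
        sum(dnorm(row, fit$means[k, ], sqrt(fit$variances[k, ]),
                  log = TRUE))
    })
    which.max(ll)
  })
  expect_equal(lab, want)
})

test_that("assigning the training set reproduces training-time labels", {
  d <- sep_gaussians(n_per = 90, K = 3, sep = 6, seed = 10)
  fit <- fit_phenotype_model(d$x, K = 3, seed = 7)
  l1 <- assign_clusters(fit, d$x)
  l2 <- assign_clusters(fit, d$x)
  expect_identical(l1, l2)
  # a point placed exactly at a (de-standardized) component mean gets that
  # component's label
  for (k in seq_len(fit$K)) {
    raw <- fit$means[k, ] * fit$scale[fit$kept_features] +
      fit$center[fit$kept_features]
    pt <- tibble::as_tibble(as.list(raw))
    expect_equal(assign_clusters(fit, pt), k)
  }
})

test_that("degenerate inputs are rejected or handled", {
  d <- sep_gaussians(n_per = 5, K = 2, seed = 12)
  expect_error(fit_phenotype_model(d$x, K = 8), "insufficient")
  fit <- fit_phenotype_model(sep_gaussians(n_per = 100, K = 2, seed = 13)$x,
                             K = 2, seed = 1)
  expect_identical(predict(fit, fit$means[0, , drop = FALSE] |>
                             tibble::as_tibble()), integer(0))
})

test_that("zero-variance features are dropped and recorded", {
  d <- sep_gaussians(n_per = 80, K = 2, seed = 14)
  d$x$dead <- 1
  fit <- fit_phenotype_model(d$x, K = 2, seed = 2)
  expect_true("dead" %in% fit$dropped_features)
  expect_false("dead" %in% fit$kept_features)
})

test_that("patient cluster matrices tally labels per patient", {
  m <- patient_cluster_matrix(c(1, 1, 4), rep("A", 3), K = 8)
  expect_equal(unname(m["A", ]), c(2, 0, 0, 1, 0, 0, 0, 0))

  labels <- c(1, 2, 2, 8, 3, 3, 3)
  pats <- c("A", "A", "B", "B", "B", "C", "C")
  m2 <- patient_cluster_matrix(labels, pats, K = 8)
  expect_equal(rowSums(m2), c(A = 2, B = 3, C = 2))
  # permutation invariance (fixed roster so row order is comparable)
  set.seed(1)
  o <- sample(seq_along(labels))
  expect_identical(
    patient_cluster_matrix(labels[o], pats[o], K = 8,
                           patients = c("A", "B", "C")),
    patient_cluster_matrix(labels, pats, K = 8,
                           patients = c("A", "B", "C")))
  # zero-TIL patients warn
  expect_warning(patient_cluster_matrix(labels, pats, K = 8,
                                        patients = c("A", "B", "C", "D")),
                 "zero")
})

test_that("models serialize losslessly through JSON", {
  d <- sep_gaussians(n_per = 60, K = 2, seed = 15)
  fit <- fit_phenotype_model(d$x, K = 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_phenotype_model(fit, path)
  back <- read_phenotype_model(path)
  expect_equal(assign_clusters(back, d$x), assign_clusters(fit, d$x))
  expect_equal(back$weights, unname(fit$weights), tolerance = 1e-12)
})
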