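# The risk score, its elastic-net Cox fit, and survival evaluation.

# Published coefficient vectors of the adenocarcinoma and squamous models.
beta_ad <- c(C1 = 4.0, C2 = -3.2, C3 = -10.2, C4 = 15.4, C5 = 0.2,
             C6 = 0.5, C7 = 0.2, C8 = -12.7)
beta_scc <- c(C1 = -2.5, C2 = 9.9, C3 = 0.2, C4 = 5.2, C5 = 1.8,
              C6 = 8.9, C7 = -2.6, C8 = 2.1)

test_that("the risk score is the exact linear combination", {
  e4 <- c(0, 0, 0, 1, 0, 0, 0, 0)
  expect_equal(compute_osrs(e4, beta_ad), 15.4)
  expect_equal(compute_osrs(rep(0, 8), beta_ad), 0)

  set.seed(1)
  N <- matrix(rpois(40, 10), 5, 8)
  b <- rnorm(8)
  want <- sapply(1:5, function(i) {
    acc <- 0
    for (j in 1:8) acc <- acc + N[i, j] * b[j]
    acc
  })
  expect_equal(compute_osrs(N, b), want)
  # linearity
  N2 <- matrix(rpois(40, 6), 5, 8)
  expect_equal(compute_osrs(2 * N + 3 * N2, b),
               2 * compute_osrs(N, b) + 3 * compute_osrs(N2, b))
})

test_that("stratification follows the strict-above-median convention", {
  g <- stratify(c(1, 2, 3, 4), 2.5)
  expect_equal(as.character(g), c("low", "low", "high", "high"))
  # ties at the cutoff go low; all-equal scores are all low
  expect_true(all(stratify(rep(3, 5), 3) == "low"))
  # groups partition the cohort
  s <- rnorm(101)
  g2 <- stratify(s, median(s))
  expect_equal(sum(table(g2)), 101)
  expect_equal(unname(table(g2)["high"]), 50)
})

test_that("the sign rule reproduces the published cluster roles", {
  roles_ad <- cluster_roles(beta_ad)
  expect_equal(roles_ad$cluster[roles_ad$role == "constructive"],
               c("C1", "C4", "C5", "C6", "C7"))
  expect_equal(roles_ad$cluster[roles_ad$role == "obstructive"],
               c("C2", "C3", "C8"))
  roles_scc <- cluster_roles(beta_scc)
  expect_equal(roles_scc$cluster[roles_scc$role == "constructive"],
               c("C2", "C3", "C4", "C5", "C6", "C8"))
  expect_equal(roles_scc$cluster[roles_scc$role == "obstructive"],
               c("C1", "C7"))
  expect_true(all(cluster_roles(rep(0, 8))$role == "neutral"))
})

test_that("planted coefficient signs are recovered on synthetic cohorts", {
  hits <- sapply(1:5, function(s) {
    N <- gen_cluster_counts(300, seed = s)
    bstar <- rep_len(c(1.25, -1.25), 8)
    surv <- gen_survival(N, bstar, censor_rate = 0.2, seed = s + 100)
    fit <- fit_risk_model(N, surv, seed = s)
    sum(sign(fit$beta) == sign(bstar))
  })
  expect_true(all(hits >= 7))
})

test_that("duplicating every patient leaves the coefficients unchanged", {
  N <- gen_cluster_counts(120, seed = 3)
  surv <- gen_survival(N, rep_len(c(1.25, -1.25), 8), seed = 4)
  N2 <- rbind(N, N)
  rownames(N2) <- c(rownames(N), paste0(rownames(N), "b"))
  surv2 <- dplyr::bind_rows(surv,
                            dplyr::mutate(surv,
                                          patient_id = paste0(patient_id, "b")))
  # the normalized partial likelihood is invariant to replicating the
  # cohort, so at a fixed penalty the coefficients are too
  fit1f <- fit_risk_model(N, surv, seed = 5, lambda = 0.01)
  fit2f <- fit_risk_model(N2, surv2, seed = 5, lambda = 0.01)
  expect_equal(unname(fit2f$beta), unname(fit1f$beta), tolerance = 1e-6)
})

test_that("fitting is deterministic and validates its inputs", {
  N <- gen_cluster_counts(80, seed = 6)
  surv <- gen_survival(N, rep_len(c(1.25, -1.25), 8), seed = 7)
  f1 <- fit_risk_model(N, surv, seed = 2)
  f2 <- fit_risk_model(N, surv, seed = 2)
  expect_identical(f1$beta, f2$beta)

  all_cens <- dplyr::mutate(surv, event = 0)
  expect_error(fit_risk_model(N, all_cens), "events|censored")
  expect_error(fit_risk_model(N[1:10, ], surv[1:10, ]), "insufficient|events")
})

test_that("zero-variance columns are retained with coefficient zero", {
  N <- gen_cluster_counts(100, seed = 8)
  N[, 5] <- 7L
  surv <- gen_survival(N, rep_len(c(1.25, -1.25), 8), seed = 9)
  expect_warning(fit <- fit_risk_model(N, surv, seed = 1), "zero-variance")
  expect_equal(unname(fit$beta[5]), 0)
  expect_length(fit$beta, 8L)
})

test_that("identical groups evaluate to the symmetric null", {
  surv <- tibble::tibble(patient_id = paste0("P", 1:40),
                         time = rep(c(3, 6, 9, 12, 15, 18, 21, 24, 27, 30), 4),
                         event = rep(c(1, 0), 20))
  groups <- factor(rep(c("low", "high"), each = 20),
                   levels = c("low", "high"))
  # both groups carry the identical set of records
  surv$time <- rep(surv$time[1:20], 2)
  surv$event <- rep(surv$event[1:20], 2)
  ev <- evaluate_survival(surv, groups)
  expect_equal(ev$hr, 1, tolerance = 1e-6)
  expect_gt(ev$logrank_p, 0.99)
})

test_that("perfectly ordering scores give concordance 1", {
  surv <- tibble::tibble(patient_id = paste0("P", 1:12),
                         time = 12:1, event = 1)
  scores <- 1:12  # higher score = earlier death
  groups <- stratify(scores, median(scores))
  ev <- evaluate_survival(surv, groups, scores)
  expect_equal(ev$cindex, 1)
})

test_that("the log-rank statistic equals the hand-computed form", {
  surv <- eight_patient_survival()
  groups <- factor(c("low", "high", "low", "high", "low", "high", "low",
                     "high"), levels = c("low", "high"))
  # observed-minus-expected over event times, variance by the
  # hypergeometric form; computed by explicit enumeration
  times <- sort(unique(surv$time[surv$event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in times) {
    at_risk <- surv$time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & groups == "high")
    d <- sum(surv$time == t & surv$event == 1)
    d1 <- sum(surv$time == t & surv$event == 1 & groups == "high")
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  want_chisq <- o_minus_e^2 / v
  ev <- evaluate_survival(surv, groups)
  expect_equal(ev$logrank_chisq, want_chisq, tolerance = 1e-9)
  expect_equal(ev$logrank_p, pchisq(want_chisq, 1, lower.tail = FALSE))
})

test_that("KM curves are non-increasing step functions starting at 1", {
  N <- gen_cluster_counts(60, seed = 11)
  surv <- gen_survival(N, rep_len(c(1.25, -1.25), 8), seed = 12)
  scores <- compute_osrs(N, rep_len(c(1, -1), 8))
  groups <- stratify(scores, median(scores))
  ev <- evaluate_survival(surv, groups, scores)
  for (g in c("low", "high")) {
    curve <- ev$km[ev$km$group == g, ]
    expect_equal(curve$surv[1], 1)
    expect_true(all(diff(curve$surv) <= 1e-12))
    expect_true(all(diff(curve$time) >= 0))
  }
  expect_true(ev$hr > 0)
  expect_true(ev$cindex >= 0 && ev$cindex <= 1)
})

test_that("empty risk groups are a degenerate-stratification error", {
  surv <- eight_patient_survival()
  groups <- factor(rep("low", 8), levels = c("low", "high"))
  expect_error(evaluate_survival(surv, groups), "degenerate")
})

test_that("risk models serialize through JSON", {
  N <- gen_cluster_counts(80, seed = 13)
  surv <- gen_survival(N, rep_len(c(1.25, -1.25), 8), seed = 14)
  fit <- fit_risk_model(N, surv, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_risk_model(fit, path)
  back <- read_risk_model(path)
  expect_equal(back$beta, fit$beta)
  expect_equal(back$cutoff, fit$cutoff)
})
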