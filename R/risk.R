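# Elastic-net Cox risk model over per-patient cluster counts, the
# overall-survival risk score (OSRS), median-cutoff stratification, cluster
# roles, and survival evaluation.

check_survival <- function(survival) {
  survival <- tibble::as_tibble(survival)
  req <- c("patient_id", "time", "event")
  if (!all(req %in% names(survival))) {
    rlang::abort("survival table needs columns patient_id, time, event")
  }
  if (any(survival$time <= 0)) rlang::abort("survival times must be > 0")
  if (!all(survival$event %in% c(0, 1))) {
    rlang::abort("event must be 0 (censored) or 1 (death)")
  }
  survival
}

#' Fit the elastic-net Cox risk model on cluster counts
#'
#' Fits a Cox proportional-hazards model with elastic-net regularization
#' over the patients x K cluster-count matrix; the penalty strength is
#' chosen by k-fold cross-validated partial likelihood with seeded folds.
#' The stratification cutoff is the median training OSRS. Raw counts are
#' used by default, per the risk-score definition; set
#' \code{proportions = TRUE} to use within-patient cluster fractions.
#' Zero-variance columns are retained with their coefficient forced to 0
#' (with a warning). Ties in the partial likelihood use the Efron
#' approximation (the \pkg{glmnet} Cox default).
#'
#' @param N matrix (patients x K) of cluster counts, rownames = patient ids.
#' @param survival survival table (\code{patient_id}, \code{time} in
#'   months > 0, \code{event} 0/1).
#' @param alpha elastic-net mixing weight (1 = lasso, 0 = ridge;
#'   default 0.5).
#' @param nfolds folds for cross-validated penalty selection.
#' @param seed RNG seed for the fold assignment.
#' @param proportions use within-patient proportions instead of raw counts.
#' @param lambda_rule \code{"lambda.min"} or \code{"lambda.1se"}.
#' @param lambda optional fixed penalty strength; skips cross-validation.
#' @return object of class \code{risk_model} with \code{beta} (named
#'   K-vector), penalty record, and training-median \code{cutoff}.
#' @export
fit_risk_model <- function(N, survival, alpha = 0.5, nfolds = 5L,
                           seed = 1L, proportions = FALSE,
                           lambda_rule = c("lambda.min", "lambda.1se"),
                           lambda = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  survival <- check_survival(survival)
  N <- as.matrix(N)
  if (is.null(colnames(N))) colnames(N) <- paste0("C", seq_len(ncol(N)))
  if (!is.null(rownames(N))) {
    survival <- survival[match(rownames(N), survival$patient_id), ]
    if (anyNA(survival$patient_id)) {
      rlang::abort("survival table does not cover all patients in N")
    }
  }
  n <- nrow(N)
  n_events <- sum(survival$event)
  if (n_events == 0L) rlang::abort("no events: all patients censored")
  if (n < 30L || n_events < 10L) {
    rlang::abort("insufficient data: need n >= 30 patients with >= 10 events")
  }
  x <- if (proportions) {
    tot <- pmax(rowSums(N), 1)
    N / tot
  } else N
  const <- apply(x, 2L, function(col) stats::sd(col) < 1e-12)
  if (any(const)) {
    rlang::warn(paste0("zero-variance column(s) retained with beta = 0: ",
                       paste(colnames(x)[const], collapse = ", ")))
  }
  xa <- x[, !const, drop = FALSE]
  y <- survival::Surv(survival$time, survival$event)
  if (is.null(lambda)) {
    foldid <- local_seed(seed, sample(rep_len(seq_len(nfolds), n)))
    cv <- glmnet::cv.glmnet(xa, y, family = "cox", alpha = alpha,
                            foldid = foldid, standardize = TRUE)
    b <- as.numeric(stats::coef(cv, s = lambda_rule))
    lambda_used <- unname(cv[[lambda_rule]])
    cv_lambdas <- cv$lambda
    cv_mean <- cv$cvm
  } else {
    # fit along a short descending path ending at the requested penalty so
    # the coefficients at `lambda` are computed, not interpolated
    fit <- glmnet::glmnet(xa, y, family = "cox", alpha = alpha,
                          standardize = TRUE, thresh = 1e-14,
                          lambda = lambda * c(16, 8, 4, 2, 1))
    b <- as.numeric(stats::coef(fit, s = lambda))
    lambda_used <- lambda
    lambda_rule <- "fixed"
    cv_lambdas <- numeric(0)
    cv_mean <- numeric(0)
  }
  beta <- stats::setNames(rep(0, ncol(x)), colnames(x))
  beta[!const] <- b
  scores <- drop(x %*% beta)
  structure(list(
    beta = beta,
    alpha = alpha,
    lambda = lambda_used,
    lambda_rule = lambda_rule,
    cv_lambdas = cv_lambdas,
    cv_mean = cv_mean,
    cutoff = stats::median(scores),
    proportions = proportions,
    n = n, n_events = n_events,
    seed = as.integer(seed)), class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model> elastic-net Cox (alpha %.2f, lambda %.4g), n = %d (%d events)\n",
              x$alpha, x$lambda, x$n, x$n_events))
  print(round(x$beta, 4))
  cat(sprintf("cutoff (training median OSRS): %.4g\n", x$cutoff))
  invisible(x)
}

#' Overall-survival risk score
#'
#' \code{OSRS_i = sum_j N_ij beta_j}: the exact linear combination of a
#' patient's cluster counts and the model coefficients, with no intercept.
#'
#' @param N matrix (patients x K) of cluster counts (or a single count
#'   vector).
#' @param beta coefficient K-vector, or a \code{risk_model}.
#' @return numeric vector of risk scores.
#' @export
compute_osrs <- function(N, beta) {
  if (inherits(beta, "risk_model")) beta <- beta$beta
  if (is.null(dim(N))) N <- matrix(N, nrow = 1L)
  N <- as.matrix(N)
  stopifnot(ncol(N) == length(beta))
  drop(N %*% beta)
}

#' Stratify risk scores at a cutoff
#'
#' Scores strictly above the cutoff are \code{"high"} risk; scores at or
#' below are \code{"low"} (fixed tie convention, so identical scores all
#' fall in the low group).
#'
#' @param scores numeric OSRS vector.
#' @param cutoff numeric cutoff, or a \code{risk_model} (uses its training
#'   median).
#' @return factor with levels \code{low}, \code{high}.
#' @export
stratify <- function(scores, cutoff) {
  if (inherits(cutoff, "risk_model")) cutoff <- cutoff$cutoff
  factor(ifelse(scores > cutoff, "high", "low"), levels = c("low", "high"))
}

#' Constructive / obstructive cluster roles
#'
#' The sign of each coefficient assigns the cluster's role: positive =
#' constructive, negative = obstructive, exactly zero = neutral.
#'
#' @param beta coefficient vector or \code{risk_model}.
#' @return tibble with \code{cluster}, \code{beta}, \code{role}.
#' @export
cluster_roles <- function(beta) {
  if (inherits(beta, "risk_model")) beta <- beta$beta
  nm <- names(beta) %||% paste0("C", seq_along(beta))
  tibble::tibble(
    cluster = nm,
    beta = unname(beta),
    role = dplyr::case_when(beta > 0 ~ "constructive",
                            beta < 0 ~ "obstructive",
                            TRUE ~ "neutral"))
}

#' Evaluate survival separation of risk groups and scores
#'
#' Computes the two-sided Mantel-Haenszel log-rank test between the risk
#' groups, the hazard ratio (high vs low) with 95\% CI from a univariable
#' Cox fit on the binary group, Harrell's concordance index over the
#' continuous scores with its standard error, and the Kaplan-Meier
#' product-limit curves per group.
#'
#' @param survival survival table (\code{patient_id}, \code{time},
#'   \code{event}).
#' @param groups factor of \code{low}/\code{high} risk per patient.
#' @param scores optional continuous risk scores (used for the C-index;
#'   defaults to the binary group indicator).
#' @return object of class \code{eval_report}: \code{logrank_p},
#'   \code{logrank_chisq}, \code{hr}, \code{hr_ci}, \code{cindex},
#'   \code{cindex_se}, \code{km} (curve points tibble), \code{n_groups}.
#' @export
evaluate_survival <- function(survival, groups, scores = NULL) {
  survival <- check_survival(survival)
  groups <- factor(groups, levels = c("low", "high"))
  stopifnot(length(groups) == nrow(survival))
  sizes <- table(groups)
  if (any(sizes == 0L)) {
    rlang::abort("degenerate stratification: a risk group has zero members")
  }
  if (is.null(scores)) scores <- as.numeric(groups == "high")
  y <- survival::Surv(survival$time, survival$event)

  sd_fit <- survival::survdiff(y ~ groups)
  logrank_chisq <- sd_fit$chisq
  logrank_p <- stats::pchisq(logrank_chisq, df = 1L, lower.tail = FALSE)

  # monotone-separated groups give an infinite-coefficient warning from the
  # partial likelihood; the finite iterate is still the reported HR
  cox <- suppressWarnings(survival::coxph(y ~ I(groups == "high")))
  hr <- unname(exp(stats::coef(cox)))
  ci <- exp(stats::confint(cox))

  conc <- survival::concordance(y ~ scores, reverse = TRUE)
  cindex <- unname(conc$concordance)
  cindex_se <- sqrt(unname(conc$var))

  sf <- survival::survfit(y ~ groups)
  strata_names <- sub("^groups=", "", rep(names(sf$strata), sf$strata))
  km <- tibble::tibble(group = strata_names, time = sf$time,
                       surv = sf$surv, n_risk = sf$n.risk,
                       n_event = sf$n.event)
  km0 <- tibble::tibble(group = sub("^groups=", "", names(sf$strata)),
                        time = 0, surv = 1, n_risk = as.numeric(sf$n),
                        n_event = 0)
  km <- dplyr::arrange(dplyr::bind_rows(km0, km), .data$group, .data$time)

  structure(list(logrank_p = logrank_p, logrank_chisq = logrank_chisq,
                 hr = hr, hr_ci = c(lower = ci[1L], upper = ci[2L]),
                 cindex = cindex, cindex_se = cindex_se,
                 km = km, n_groups = as.integer(sizes)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> log-rank p = %.3g; HR (high vs low) = %.3g (95%% CI %.3g-%.3g); C-index = %.3f (SE %.3f)\n",
              x$logrank_p, x$hr, x$hr_ci[1], x$hr_ci[2], x$cindex,
              x$cindex_se))
  invisible(x)
}

#' Serialize a risk model as JSON
#'
#' @param model a \code{risk_model}.
#' @param path file path.
#' @return \code{path} invisibly / the restored model.
#' @export
write_risk_model <- function(model, path) {
  obj <- unclass(model)
  obj$beta <- as.list(obj$beta)   # keep names through JSON
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$beta <- unlist(obj$beta)
  structure(obj, class = "risk_model")
}
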