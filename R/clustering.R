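# Gaussian-mixture phenotype model over TIL feature vectors.
#
# Diagonal covariances with a variance floor: at 288 dimensions a full
# covariance per component is ill-conditioned at realistic TIL counts.
# Initialization is k-means++ seeding with multiple restarts, all driven by
# one seed; the best log-likelihood fit is kept.

ID_COLUMNS <- c("til_id", "tile_id", "patient_id", "cell_id")

feature_matrix <- function(features) {
  df <- tibble::as_tibble(features)
  keep <- setdiff(names(df), ID_COLUMNS)
  m <- as.matrix(df[, keep, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

#' Fit the Gaussian-mixture phenotype model
#'
#' Standardizes the feature table (z-scores fit on the input;
#' zero-variance features are dropped and recorded), then fits a K-component
#' Gaussian mixture with diagonal covariances by expectation-maximization:
#' k-means++ seeding, \code{n_restarts} seeded restarts, bounded iterations,
#' variance floor \code{1e-6}. Non-convergence within \code{max_iter} is
#' flagged and the best fit so far returned. Id columns
#' (\code{til_id}, \code{tile_id}, \code{patient_id}, \code{cell_id}) are
#' ignored automatically.
#'
#' @param features feature table or matrix (n x p), n >= 10 K.
#' @param K number of mixture components; 8 in the paper-mode
#'   configuration.
#' @param seed RNG seed controlling all restarts.
#' @param n_restarts number of k-means++ restarts.
#' @param max_iter EM iteration cap per restart.
#' @param tol relative log-likelihood convergence tolerance.
#' @param var_floor variance floor applied each M-step.
#' @return object of class \code{phenotype_model}: mixture weights, means
#'   and variances on the standardized scale, the standardization
#'   statistics, kept-feature names, log-likelihood trace and convergence
#'   flag.
#' @export
fit_phenotype_model <- function(features, K = 8L, seed = 1L,
                                n_restarts = 5L, max_iter = 200L,
                                tol = 1e-8, var_floor = 1e-6) {
  x <- feature_matrix(features)
  if (!all(is.finite(x))) rlang::abort("features must be finite")
  n <- nrow(x)
  if (n < 10L * K) {
    rlang::abort(sprintf("insufficient data: need at least %d rows for K = %d, got %d",
                         10L * K, K, n))
  }
  center <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  kept <- which(scl > 1e-12)
  dropped <- colnames(x)[setdiff(seq_len(ncol(x)), kept)]
  z <- sweep(sweep(x[, kept, drop = FALSE], 2L, center[kept], `-`),
             2L, scl[kept], `/`)
  best <- NULL
  local_seed(seed, {
    for (rs in seq_len(n_restarts)) {
      fit <- em_diag_gmm(z, K, max_iter, tol, var_floor)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  structure(list(
    K = as.integer(K),
    weights = best$weights,
    means = best$means,
    variances = best$variances,
    center = center, scale = scl,
    kept_features = colnames(x)[kept],
    dropped_features = dropped,
    loglik = best$loglik,
    loglik_trace = best$trace,
    converged = best$converged,
    n_obs = n,
    seed = as.integer(seed)), class = "phenotype_model")
}

# One EM run on standardized data; consumes RNG for the k-means++ seeding.
em_diag_gmm <- function(z, K, max_iter, tol, var_floor) {
  n <- nrow(z); p <- ncol(z)
  centers <- kmeanspp_centers(z, K)
  d2 <- pairwise_sqdist(z, centers)
  assign0 <- max.col(-d2, ties.method = "first")
  means <- centers
  vars <- matrix(1, K, p)
  w <- rep(1 / K, K)
  for (k in seq_len(K)) {
    idx <- which(assign0 == k)
    if (length(idx) > 1L) {
      means[k, ] <- colMeans(z[idx, , drop = FALSE])
      vars[k, ] <- pmax(apply(z[idx, , drop = FALSE], 2L, stats::var),
                        var_floor)
      w[k] <- length(idx) / n
    }
  }
  w <- w / sum(w)
  prev <- -Inf; trace <- numeric(0); converged <- FALSE
  for (it in seq_len(max_iter)) {
    lr <- log_resp(z, w, means, vars)      # n x K joint log densities
    lse <- log_sum_exp_rows(lr)
    ll <- sum(lse)
    trace <- c(trace, ll)
    resp <- exp(lr - lse)
    nk <- colSums(resp)
    w <- nk / n
    means <- (t(resp) %*% z) / nk
    ez2 <- (t(resp) %*% z^2) / nk
    vars <- pmax(ez2 - means^2, var_floor)
    if (is.finite(prev) && abs(ll - prev) <= tol * (abs(prev) + 1)) {
      converged <- TRUE
      break
    }
    prev <- ll
  }
  list(weights = w, means = means, variances = vars, loglik = ll,
       trace = trace, converged = converged)
}

kmeanspp_centers <- function(z, K) {
  n <- nrow(z)
  idx <- integer(K)
  idx[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(z, 2L, z[idx[1L], ], `-`)^2)
  for (k in seq_len(K - 1L) + 1L) {
    probs <- d2 / sum(d2)
    if (!all(is.finite(probs)) || sum(d2) <= 0) {
      idx[k] <- sample.int(n, 1L)
    } else {
      idx[k] <- sample.int(n, 1L, prob = probs)
    }
    d2 <- pmin(d2, rowSums(sweep(z, 2L, z[idx[k], ], `-`)^2))
  }
  z[idx, , drop = FALSE]
}

pairwise_sqdist <- function(x, centers) {
  cross <- x %*% t(centers)
  sx <- rowSums(x^2)
  sc <- rowSums(centers^2)
  outer(sx, sc, `+`) - 2 * cross
}

# Joint log density log(w_k) + log N(x | mu_k, diag(sigma2_k)), n x K.
log_resp <- function(z, w, means, vars) {
  inv <- 1 / vars                                    # K x p
  quad <- z^2 %*% t(inv) - 2 * z %*% t(means * inv)  # n x K
  const <- rowSums(means^2 * inv) + rowSums(log(2 * pi * vars))
  sweep(-0.5 * sweep(quad, 2L, const, `+`), 2L, log(w), `+`)
}

standardize_for_model <- function(model, features) {
  x <- feature_matrix(features)
  missing_cols <- setdiff(model$kept_features, colnames(x))
  if (length(missing_cols) > 0L) {
    rlang::abort(paste0("features lack model column(s): ",
                        paste(utils::head(missing_cols, 5), collapse = ", ")))
  }
  x <- x[, model$kept_features, drop = FALSE]
  sweep(sweep(x, 2L, model$center[model$kept_features], `-`), 2L,
        model$scale[model$kept_features], `/`)
}

#' Posterior responsibilities and cluster assignment
#'
#' \code{predict} returns either hard labels (argmax posterior
#' responsibility, ties broken toward the lowest cluster index) or the
#' full posterior matrix. Standardization reuses the training statistics.
#'
#' @param object a \code{phenotype_model}.
#' @param newdata feature table.
#' @param type \code{"class"} or \code{"posterior"}.
#' @param ... unused.
#' @return integer labels in \code{1..K}, or an n x K posterior matrix.
#' @export
predict.phenotype_model <- function(object, newdata,
                                    type = c("class", "posterior"), ...) {
  type <- match.arg(type)
  if (nrow(tibble::as_tibble(newdata)) == 0L) {
    return(if (type == "class") integer(0) else
      matrix(numeric(0), 0L, object$K))
  }
  z <- standardize_for_model(object, newdata)
  lr <- log_resp(z, object$weights, object$means, object$variances)
  if (type == "class") {
    max.col(lr, ties.method = "first")
  } else {
    exp(lr - log_sum_exp_rows(lr))
  }
}

#' @rdname predict.phenotype_model
#' @param model a \code{phenotype_model}.
#' @param features feature table.
#' @export
assign_clusters <- function(model, features) {
  predict(model, features, type = "class")
}

#' Per-patient cluster-count matrix
#'
#' Tallies hard cluster assignments into the patients x K count matrix
#' (the \code{N} of the risk score). Row sums equal per-patient TIL
#' counts; patients listed in \code{patients} but absent from
#' \code{patient_ids} get zero rows with a warning.
#'
#' @param labels integer cluster labels in \code{1..K}.
#' @param patient_ids patient identifier per TIL.
#' @param K number of clusters.
#' @param patients optional full patient roster (row order of the result).
#' @return integer matrix (patients x K) with dimnames.
#' @export
patient_cluster_matrix <- function(labels, patient_ids, K = 8L,
                                   patients = NULL) {
  stopifnot(length(labels) == length(patient_ids))
  if (is.null(patients)) patients <- unique(patient_ids)
  tab <- table(factor(patient_ids, levels = patients),
               factor(labels, levels = seq_len(K)))
  m <- matrix(as.integer(tab), nrow(tab), K,
              dimnames = list(rownames(tab), paste0("C", seq_len(K))))
  zero <- rowSums(m) == 0L
  if (any(zero)) {
    rlang::warn(paste0("patients with zero assigned TILs: ",
                       paste(rownames(m)[zero], collapse = ", ")))
  }
  m
}

#' BIC sweep over the number of mixture components
#'
#' Model-selection helper (non-normative; the paper-mode configuration
#' fixes K = 8): fits [fit_phenotype_model()] for each K and reports the
#' Bayesian information criterion.
#'
#' @param features feature table.
#' @param K_range candidate component counts.
#' @param seed RNG seed.
#' @param ... passed to [fit_phenotype_model()].
#' @return tibble with columns \code{K}, \code{loglik}, \code{n_params},
#'   \code{bic}.
#' @export
select_k <- function(features, K_range = 2:12, seed = 1L, ...) {
  x <- feature_matrix(features)
  purrr::map_dfr(K_range, function(k) {
    fit <- fit_phenotype_model(features, K = k, seed = seed, ...)
    p <- length(fit$kept_features)
    n_params <- (k - 1) + 2 * k * p
    tibble::tibble(K = k, loglik = fit$loglik, n_params = n_params,
                   bic = -2 * fit$loglik + n_params * log(nrow(x)))
  })
}

#' Serialize / restore a phenotype model as JSON
#'
#' @param model a \code{phenotype_model}.
#' @param path file path.
#' @return \code{path} invisibly / the restored model.
#' @export
write_phenotype_model <- function(model, path) {
  obj <- unclass(model)
  obj$means <- as.data.frame(obj$means)
  obj$variances <- as.data.frame(obj$variances)
  # named vectors must go through lists to keep names in JSON
  obj$center <- as.list(obj$center)
  obj$scale <- as.list(obj$scale)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_phenotype_model
#' @export
read_phenotype_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$means <- as.matrix(obj$means)
  obj$variances <- as.matrix(obj$variances)
  obj$center <- unlist(obj$center)
  obj$scale <- unlist(obj$scale)
  obj$K <- as.integer(obj$K)
  structure(obj, class = "phenotype_model")
}

#' @export
print.phenotype_model <- function(x, ...) {
  cat(sprintf("<phenotype_model> K = %d over %d features (n = %d TILs); loglik %.2f%s\n",
              x$K, length(x$kept_features), x$n_obs, x$loglik,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}
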