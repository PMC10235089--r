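# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a phenotype mixture model
#'
#' One row per mixture component: weight and the number of TILs a hard
#' assignment of the training data would be expected to allocate.
#'
#' @param x a \code{phenotype_model}.
#' @param ... unused.
#' @return tibble with \code{cluster}, \code{weight}, \code{expected_n}.
#' @method tidy phenotype_model
#' @export
tidy.phenotype_model <- function(x, ...) {
  tibble::tibble(cluster = paste0("C", seq_len(x$K)),
                 weight = as.numeric(x$weights),
                 expected_n = as.numeric(x$weights) * x$n_obs)
}

#' @rdname tidy.phenotype_model
#' @return \code{glance}: one-row tibble with \code{K}, \code{n_obs},
#'   \code{n_features}, \code{loglik}, \code{bic}, \code{converged}.
#' @method glance phenotype_model
#' @export
glance.phenotype_model <- function(x, ...) {
  p <- length(x$kept_features)
  n_params <- (x$K - 1) + 2 * x$K * p
  tibble::tibble(K = x$K, n_obs = x$n_obs, n_features = p,
                 loglik = x$loglik,
                 bic = -2 * x$loglik + n_params * log(x$n_obs),
                 converged = x$converged)
}

#' Tidy a fitted risk model
#'
#' One row per cluster coefficient, with its constructive/obstructive role.
#'
#' @param x a \code{risk_model}.
#' @param ... unused.
#' @return tibble with \code{cluster} (term), \code{beta} (estimate),
#'   \code{role}.
#' @method tidy risk_model
#' @export
tidy.risk_model <- function(x, ...) cluster_roles(x$beta)

#' @rdname tidy.risk_model
#' @method glance risk_model
#' @export
glance.risk_model <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, lambda = x$lambda, cutoff = x$cutoff,
                 n = x$n, n_events = x$n_events,
                 n_nonzero = sum(x$beta != 0))
}

#' Tidy a survival evaluation report
#'
#' \code{tidy} returns the Kaplan-Meier curve points; \code{glance} the
#' scalar metrics.
#'
#' @param x an \code{eval_report}.
#' @param ... unused.
#' @return tibbles.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$km

#' @rdname tidy.eval_report
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(logrank_p = x$logrank_p, hr = x$hr,
                 hr_lower = x$hr_ci[["lower"]],
                 hr_upper = x$hr_ci[["upper"]],
                 cindex = x$cindex, cindex_se = x$cindex_se)
}

#' Tidy a gene-cluster correlation matrix
#'
#' @param x a \code{gene_cluster_correlation}.
#' @param ... unused.
#' @return long tibble with \code{gene}, \code{target}, \code{r}, \code{n}.
#' @method tidy gene_cluster_correlation
#' @export
tidy.gene_cluster_correlation <- function(x, ...) {
  m <- unclass(x)
  attr(m, "n") <- NULL; attr(m, "flagged") <- NULL
  tibble::tibble(gene = rep(rownames(m), ncol(m)),
                 target = rep(colnames(m), each = nrow(m)),
                 r = as.numeric(m),
                 n = attr(x, "n"))
}
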