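# ggplot2 visualizations for the fitted objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Kaplan-Meier plot of a survival evaluation
#'
#' Step curves per risk group annotated with the log-rank p and hazard
#' ratio.
#'
#' @param object an \code{eval_report}.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  lab <- sprintf("log-rank p = %.2g\nHR = %.2f (%.2f-%.2f)",
                 object$logrank_p, object$hr, object$hr_ci[1],
                 object$hr_ci[2])
  ggplot2::ggplot(object$km,
                  ggplot2::aes(x = .data$time, y = .data$surv,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::annotate("text", x = Inf, y = Inf, label = lab,
                      hjust = 1.05, vjust = 1.2, size = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (months)", y = "overall survival",
                  colour = "risk group") +
    ggplot2::theme_minimal()
}

#' Coefficient plot of a risk model
#'
#' Lollipop plot of the elastic-net Cox coefficients colored by their
#' constructive/obstructive role.
#'
#' @param object a \code{risk_model}.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot risk_model
#' @export
autoplot.risk_model <- function(object, ...) {
  df <- cluster_roles(object$beta)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster, y = .data$beta,
                                   colour = .data$role)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$cluster, yend = 0)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(y = expression(beta[j]), x = NULL) +
    ggplot2::theme_minimal()
}

#' Mixture-weight plot of a phenotype model
#'
#' @param object a \code{phenotype_model}.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot phenotype_model
#' @export
autoplot.phenotype_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$cluster, y = .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::labs(y = "mixture weight", x = NULL) +
    ggplot2::theme_minimal()
}
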