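#' Radial MR fit with per-variant Q contributions
#'
#' Reformulates IVW as a no-intercept regression of `ratio * sqrt(w)` on
#' `sqrt(w)` (the Galbraith radial frame), which attributes the global
#' heterogeneity `Q_R` to per-variant contributions
#' `Q_j = w_j (ratio_j - b)^2`, each referred to chi-square(1).
#'
#' Weighting schemes:
#' \describe{
#'   \item{`"first_order"`}{`w_j = gamma_j^2 / se_out_j^2`; the radial slope
#'     is then algebraically identical to the IVW estimate.}
#'   \item{`"modified_second_order"`}{(default) `w_j = 1 / (se_out_j^2 /
#'     gamma_j^2 + b^2 se_exp_j^2 / gamma_j^2)`, iterated by re-estimating
#'     the slope until `|delta b| < tol` or `max_iter` is hit (a warning is
#'     raised and the last iterate returned with `converged = FALSE`).}
#' }
#'
#' @inheritParams mr_ivw
#' @param weights `"modified_second_order"` (default) or `"first_order"`.
#' @param tol convergence tolerance on the slope (default 1e-8).
#' @param max_iter iteration cap for the modified weights (default 100).
#' @return an object of class `radial_fit`: per-variant table via [tidy()]
#'   (`rsid`, `ratio`, `weight`, `q_contribution`, `q_pval`), global fields
#'   `b`, `Q`, `df`, `Q_pval`, `scheme`, `converged`, `iterations`.
#' @seealso [detect_outliers()], [autoplot.radial_fit()]
#' @export
radial_fit <- function(hset,
                       weights = c("modified_second_order", "first_order"),
                       tol = 1e-8, max_iter = 100) {
  weights <- match.arg(weights)
  # exact (zero-SE) exposure effects are a legitimate degenerate case in
  # which the modified weights collapse to first-order ones
  check_hset(hset, 2L, "radial_fit", zero_se_exp_ok = TRUE)
  g <- hset$beta_exp
  G <- hset$beta_out
  sg <- hset$se_exp
  sG <- hset$se_out
  ratio <- G / g
  slope <- function(w) sum(w * ratio) / sum(w)

  w1 <- g^2 / sG^2
  b <- slope(w1) # first-order start, identical to IVW
  w <- w1
  converged <- TRUE
  iters <- 0L
  if (weights == "modified_second_order") {
    converged <- FALSE
    for (i in seq_len(max_iter)) {
      iters <- i
      w <- 1 / (sG^2 / g^2 + b^2 * sg^2 / g^2)
      b_new <- slope(w)
      if (abs(b_new - b) < tol) {
        b <- b_new
        converged <- TRUE
        break
      }
      b <- b_new
    }
    if (!converged) {
      warn(paste0(
        "radial_fit: modified second-order weights did not converge in ",
        max_iter, " iterations; returning last iterate"
      ))
    }
  }
  q_j <- w * (ratio - b)^2
  per_snp <- tibble::tibble(
    rsid = if ("rsid" %in% names(hset)) hset$rsid else as.character(seq_along(g)),
    ratio = ratio,
    weight = w,
    q_contribution = q_j,
    q_pval = pchisq(q_j, 1, lower.tail = FALSE)
  )
  structure(
    list(
      data = per_snp, b = b, Q = sum(q_j), df = length(g) - 1L,
      Q_pval = pchisq(sum(q_j), length(g) - 1L, lower.tail = FALSE),
      scheme = weights, converged = converged, iterations = iters, tol = tol
    ),
    class = "radial_fit"
  )
}

#' @export
print.radial_fit <- function(x, ...) {
  cat(sprintf(
    "Radial MR fit (%s weights)\n  b = %.4f, Q_R = %.2f on %d df (p = %.3g)%s\n",
    x$scheme, x$b, x$Q, x$df, x$Q_pval,
    if (x$converged) "" else "  [NOT CONVERGED]"
  ))
  invisible(x)
}

#' @export
tidy.radial_fit <- function(x, ...) x$data

#' @export
glance.radial_fit <- function(x, ...) {
  tibble::tibble(
    b = x$b, Q = x$Q, df = x$df, Q_pval = x$Q_pval, scheme = x$scheme,
    converged = x$converged, iterations = x$iterations
  )
}

#' Flag outlier instruments from a radial fit
#'
#' A variant is an outlier when its Q contribution is improbably large under
#' chi-square(1). Under `"bonferroni"` (the default, conservative
#' convention) variant `j` is flagged iff `q_pval_j < alpha / J`; under
#' `"fixed"`, iff `q_pval_j < alpha`.
#'
#' @param fit a [radial_fit()] object.
#' @param alpha_policy `"bonferroni"` (default) or `"fixed"`.
#' @param alpha nominal level (default 0.05).
#' @return character vector of flagged rsids, sorted by Q contribution,
#'   largest first.
#' @export
detect_outliers <- function(fit, alpha_policy = c("bonferroni", "fixed"),
                            alpha = 0.05) {
  alpha_policy <- match.arg(alpha_policy)
  stopifnot(inherits(fit, "radial_fit"), alpha > 0, alpha < 1)
  d <- fit$data
  thr <- if (alpha_policy == "bonferroni") alpha / nrow(d) else alpha
  flagged <- d[d$q_pval < thr, , drop = FALSE]
  flagged$rsid[order(-flagged$q_contribution)]
}

#' Percentage reduction in heterogeneity
#'
#' `100 * (q_before - q_after) / q_before`.
#'
#' @param q_before heterogeneity statistic before adjustment; must be > 0.
#' @param q_after heterogeneity statistic after adjustment.
#' @return the percentage reduction (negative if heterogeneity increased).
#' @examples
#' heterogeneity_reduction(400, 330) # 17.5
#' @export
heterogeneity_reduction <- function(q_before, q_after) {
  if (any(q_before <= 0)) {
    abort("heterogeneity_reduction: q_before must be positive",
      class = "mrdissect_validation_error"
    )
  }
  100 * (q_before - q_after) / q_before
}

#' Radial (Galbraith) plot of a radial MR fit
#'
#' Square-root weight on the x axis, ratio times square-root weight on the
#' y axis; the fitted slope is the causal estimate and flagged outliers are
#' highlighted.
#'
#' @param object a [radial_fit()] object.
#' @param alpha_policy,alpha passed to [detect_outliers()] for highlighting.
#' @param ... ignored.
#' @return a ggplot object.
#' @export
autoplot.radial_fit <- function(object, alpha_policy = "bonferroni",
                                alpha = 0.05, ...) {
  d <- object$data
  out <- detect_outliers(object, alpha_policy, alpha)
  d$outlier <- d$rsid %in% out
  d$x <- sqrt(d$weight)
  d$y <- d$ratio * sqrt(d$weight)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(
      intercept = 0, slope = object$b,
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outlier), size = 2) +
    ggplot2::geom_text(
      data = d[d$outlier, , drop = FALSE],
      ggplot2::aes(label = .data$rsid),
      vjust = -0.8, size = 3, colour = "steelblue4"
    ) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey30", `TRUE` = "steelblue3"), guide = "none"
    ) +
    ggplot2::labs(
      x = expression(sqrt(w)), y = expression(hat(beta) %.% sqrt(w)),
      title = sprintf(
        "Radial MR (%s weights): b = %.3f, Q = %.1f",
        object$scheme, object$b, object$Q
      )
    ) +
    ggplot2::theme_minimal()
}
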