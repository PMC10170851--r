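# Statistical link between mean read depth over the peptide-binding-region
# exons (exons 2-3 for MHC-I, exon 2 for MHC-II; computed upstream, e.g.
# by mosdepth) and the correctness of the corresponding allele-pair
# prediction.

#' Rank-sum comparison of depths behind correct and incorrect calls
#'
#' Wilcoxon rank-sum (Mann-Whitney) test of the mean read depths of
#' correctly predicted sample-gene keys against those of incorrect ones,
#' using the tie-corrected normal approximation.
#'
#' @param depths_correct,depths_incorrect Numeric vectors of mean depths.
#' @return A tibble `statistic` (Mann-Whitney U of the correct group),
#'   `p_value`, `n_correct`, `n_incorrect`.
#' @export
depth_group_test <- function(depths_correct, depths_incorrect) {
  if (length(depths_correct) == 0L || length(depths_incorrect) == 0L) {
    stop("both depth groups must be non-empty", call. = FALSE)
  }
  wt <- stats::wilcox.test(depths_correct, depths_incorrect,
                           alternative = "two.sided", exact = FALSE,
                           correct = FALSE)
  tibble(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    n_correct = length(depths_correct),
    n_incorrect = length(depths_incorrect)
  )
}

#' Logistic regression of call correctness on read depth
#'
#' Maximum-likelihood fit of a binomial GLM relating the mean HLA read
#' depth of a sample-gene key to whether the allele pair was fully
#' correct. Convergence uses a relative log-likelihood change below 1e-8
#' with at most 100 iterations. Complete or quasi-complete separation is
#' reported as a warning on the returned object rather than an error.
#'
#' @param depth Numeric vector of mean read depths.
#' @param correct Logical (or 0/1) vector: both alleles correct.
#' @param log_depth Fit on `log10(depth)` instead of raw depth.
#' @return An object of class `"hla_depth_fit"` wrapping the [stats::glm()]
#'   fit; supports `tidy()`, `glance()`, `predict()` and `autoplot()`.
#' @export
fit_depth_logistic <- function(depth, correct, log_depth = FALSE) {
  correct <- as.integer(correct)
  stopifnot(length(depth) == length(correct),
            all(correct %in% c(0L, 1L)))
  if (length(depth) < 10L) {
    stop("need at least 10 records to fit", call. = FALSE)
  }
  if (length(unique(correct)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  x <- if (log_depth) log10(depth) else depth
  if (stats::sd(x) == 0) {
    stop("depth has no variation; logistic fit undefined", call. = FALSE)
  }
  # glm's "fitted probabilities 0 or 1" warning is superseded by the
  # explicit separation diagnostic below
  fit <- withCallingHandlers(
    stats::glm(correct ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  mu <- stats::fitted(fit)
  separated <- !fit$converged || all(mu > 1 - 1e-8 | mu < 1e-8)
  if (separated) {
    warning("possible complete separation: estimates are unreliable",
            call. = FALSE)
  }
  structure(
    list(fit = fit, log_depth = log_depth, separated = separated,
         n = length(depth)),
    class = "hla_depth_fit"
  )
}

#' @export
#' @method tidy hla_depth_fit
tidy.hla_depth_fit <- function(x, ...) {
  s <- stats::coef(summary(x$fit))
  tibble(
    term = c("intercept", if (x$log_depth) "log10_depth" else "depth"),
    estimate = s[, "Estimate"],
    std_error = s[, "Std. Error"],
    statistic = s[, "z value"],
    p_value = s[, "Pr(>|z|)"]
  )
}

#' @export
#' @method glance hla_depth_fit
glance.hla_depth_fit <- function(x, ...) {
  tibble(
    n = x$n,
    deviance = x$fit$deviance,
    null_deviance = x$fit$null.deviance,
    aic = x$fit$aic,
    converged = x$fit$converged,
    separated = x$separated
  )
}

#' @export
#' @method predict hla_depth_fit
predict.hla_depth_fit <- function(object, depth, ...) {
  x <- if (object$log_depth) log10(depth) else depth
  unname(stats::predict(object$fit, newdata = data.frame(x = x),
                        type = "response"))
}

#' @export
print.hla_depth_fit <- function(x, ...) {
  cat("Logistic model of call correctness on",
      if (x$log_depth) "log10 read depth" else "read depth",
      sprintf("(n = %d)\n", x$n))
  print(tidy(x))
  invisible(x)
}

#' Effective depth after read subsampling
#'
#' The absolute depth of a subsampled alignment: the original mean HLA
#' read depth multiplied by the fraction of reads retained.
#'
#' @param mean_depth Mean read depth of the full file (x).
#' @param fraction Fraction of reads retained, in (0, 1].
#' @return `mean_depth * fraction`.
#' @export
#' @examples
#' effective_depth(40, 0.5)  # 20
effective_depth <- function(mean_depth, fraction) {
  if (any(fraction <= 0 | fraction > 1)) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  mean_depth * fraction
}

#' Accuracy as a function of effective depth across subsample fractions
#'
#' Builds the depth-accuracy curve of a subsampling experiment: one point
#' per retained fraction, with the mean effective depth across samples on
#' the x-axis and the mean accuracy on the y-axis.
#'
#' @param records Tibble with columns `fraction` (reads retained, in
#'   (0,1]), `mean_depth` (full-file depth of the sample-gene key) and
#'   `score` (0..2) or logical `correct`.
#' @return A tibble `fraction`, `depth` (mean effective depth),
#'   `accuracy`, sorted by depth, of class `"hla_depth_curve"`.
#' @export
depth_accuracy_curve <- function(records) {
  if (!"score" %in% names(records) && "correct" %in% names(records)) {
    records$score <- 2L * as.integer(records$correct)
  }
  out <- records |>
    dplyr::mutate(eff = effective_depth(.data$mean_depth, .data$fraction)) |>
    dplyr::group_by(.data$fraction) |>
    dplyr::summarise(depth = mean(.data$eff),
                     accuracy = mean(.data$score) / 2,
                     .groups = "drop") |>
    dplyr::arrange(.data$depth)
  if (any(diff(out$depth) <= 0)) {
    stop("effective depths must be strictly increasing across fractions",
         call. = FALSE)
  }
  class(out) <- c("hla_depth_curve", class(out))
  out
}

#' Minimum depth reaching a target accuracy by linear interpolation
#'
#' Scans the depth-accuracy curve from low to high depth and returns the
#' lowest depth at which the piecewise-linear interpolant reaches the
#' target accuracy (90% by default). If every point already exceeds the
#' target the lowest curve depth is returned with a warning; if the target
#' is never reached the result is `NA` with a warning.
#'
#' @param curve Tibble with `depth` (strictly increasing) and `accuracy`
#'   columns, as from [depth_accuracy_curve()].
#' @param target Target accuracy in (0, 1).
#' @return A single depth (x), or `NA_real_` when unattainable.
#' @export
#' @examples
#' min_depth_for_accuracy(
#'   tibble::tibble(depth = c(10, 20), accuracy = c(0.85, 0.95)))  # 15
min_depth_for_accuracy <- function(curve, target = 0.90) {
  stopifnot(nrow(curve) >= 2L, target > 0, target < 1)
  d <- curve$depth
  a <- curve$accuracy
  if (any(diff(d) <= 0)) stop("depths must be strictly increasing",
                              call. = FALSE)
  if (a[1] >= target) {
    if (all(a >= target)) {
      warning("target accuracy met at every measured depth; ",
              "returning the lowest", call. = FALSE)
    }
    return(d[1])
  }
  for (i in seq_len(length(d) - 1L)) {
    lo <- a[i]; hi <- a[i + 1L]
    if (lo < target && hi >= target) {
      return(d[i] + (target - lo) * (d[i + 1L] - d[i]) / (hi - lo))
    }
  }
  warning("target accuracy ", target, " not reached on the curve",
          call. = FALSE)
  NA_real_
}

#' @export
#' @method autoplot hla_depth_curve
autoplot.hla_depth_curve <- function(object, target = 0.9, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$depth,
                                       y = .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = target, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Effective mean HLA read depth (x)",
                  y = "Accuracy") +
    ggplot2::theme_minimal()
}
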