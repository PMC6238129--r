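#' Mean per-substrate attack rates by treatment and resource
#'
#' For each treatment and each resource type present in its design, the mean
#' egg count per substrate: total eggs laid on substrates of that type,
#' divided by (number of such substrates x number of replicates). Resources
#' absent from a treatment's design yield no row. `alt_proportion` is the
#' proportion of substrates of the *other* resource type in the design — the
#' frequency axis along which associational effects are assessed.
#'
#' @inheritParams validate_egg_counts
#' @return Tibble: `treatment`, `resource`, `alt_proportion`,
#'   `n_substrates`, `n_replicates`, `mean_eggs`.
#' @export
per_substrate_rates <- function(data, designs = standard_designs()) {
  designs <- check_design_registry(designs)
  data <- validate_egg_counts(data, designs)
  purrr::map(unique(data$treatment), function(trt) {
    d <- designs[[trt]]
    ratio <- design_ratio(d)
    sub <- data[data$treatment == trt, ]
    n_rep <- dplyr::n_distinct(sub$replicate_id)
    purrr::map(c("A", "B"), function(res) {
      n_sub <- unname(ratio[[res]])
      if (n_sub == 0) return(NULL)
      tibble::tibble(
        treatment = trt,
        resource = res,
        alt_proportion = unname(ratio[[setdiff(c("A", "B"), res)]]) / sum(ratio),
        n_substrates = n_sub,
        n_replicates = n_rep,
        mean_eggs = sum(sub$eggs[sub$resource == res]) / (n_sub * n_rep)
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Classify the associational effect on one resource type
#'
#' Quantifies frequency dependence of the per-substrate attack rate on the
#' focal resource: the least-squares slope of
#' `log(mean eggs per substrate + 0.5)` against the proportion of the
#' alternative resource, across the treatments whose designs contain the
#' focal resource. A positive slope means the resource is attacked more
#' when surrounded by more of the alternative (associational
#' susceptibility); a negative slope means the alternative's presence
#' shields it (associational resistance). Uncertainty comes from a
#' bootstrap stratified by treatment (replicates resampled with replacement
#' within each treatment); the classification is `"susceptibility"` when
#' the percentile interval lies entirely above 0, `"resistance"` when
#' entirely below, `"none"` otherwise. The 0.5 offset inside the log guards
#' zero means.
#'
#' @inheritParams validate_egg_counts
#' @param resource Focal resource type, `"A"` or `"B"`.
#' @param n_boot Bootstrap resamples (>= 100; default 999).
#' @param level Level of the percentile interval (default 0.95).
#' @param seed Optional integer seed for the bootstrap.
#' @return An object of class `assoc_effect`: `resource`, `slope`, `ci`,
#'   `level`, `classification`, `n_boot`, `seed`, and the per-treatment
#'   `points` used for the regression. Supports [tidy()], [glance()],
#'   [autoplot()].
#' @examples
#' sim <- simulate_experiment(s_wa = 0.95, s_pa = 0.95, n_replicates = 5, seed = 7)
#' associational_effect(sim, resource = "A", n_boot = 199, seed = 1)
#' @export
associational_effect <- function(data, designs = standard_designs(),
                                 resource = c("A", "B"), n_boot = 999,
                                 level = 0.95, seed = NULL) {
  resource <- match.arg(resource)
  if (n_boot < 100) abort("`n_boot` must be at least 100.")
  designs <- check_design_registry(designs)
  data <- validate_egg_counts(data, designs)
  rates <- per_substrate_rates(data, designs)
  pts <- rates[rates$resource == resource, ]
  if (dplyr::n_distinct(pts$alt_proportion) < 2) {
    abort(paste0(
      "Insufficient design: associational effects need at least 2 distinct ",
      "frequency levels containing resource ", resource, "."
    ))
  }

  x <- pts$alt_proportion
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope_of <- function(means) sum(xc * log(means + 0.5)) / sxx
  slope <- slope_of(pts$mean_eggs)

  # stratified bootstrap: resample per-replicate focal totals within treatment
  if (!is.null(seed)) set.seed(seed)
  boot_means <- purrr::map(seq_len(nrow(pts)), function(i) {
    sub <- data[data$treatment == pts$treatment[i] & data$resource == resource, ]
    v <- tapply(sub$eggs, sub$replicate_id, sum)
    R <- length(v)
    draws <- matrix(v[sample.int(R, R * n_boot, replace = TRUE)], nrow = R)
    colMeans(draws) / pts$n_substrates[i]
  })
  ym <- do.call(rbind, boot_means)                 # treatments x n_boot
  boot_slopes <- as.vector(crossprod(xc, log(ym + 0.5))) / sxx
  alpha <- (1 - level) / 2
  ci <- unname(quantile(boot_slopes, c(alpha, 1 - alpha), type = 7))

  classification <- if (ci[1] > 0) "susceptibility"
  else if (ci[2] < 0) "resistance"
  else "none"

  structure(
    list(
      resource = resource, slope = slope,
      ci = c(lower = ci[1], upper = ci[2]), level = level,
      classification = classification, n_boot = as.integer(n_boot),
      seed = seed, points = pts, boot_slopes = boot_slopes
    ),
    class = "assoc_effect"
  )
}

#' @export
print.assoc_effect <- function(x, ...) {
  cat(sprintf(
    "<assoc_effect> resource %s: %s\n  slope %.3f (log eggs per unit alternative proportion), %.0f%% CI [%.3f, %.3f], %d bootstrap resamples\n",
    x$resource, x$classification, x$slope, 100 * x$level,
    x$ci[["lower"]], x$ci[["upper"]], x$n_boot
  ))
  invisible(x)
}

#' @rdname associational_effect
#' @param x,object An `assoc_effect` object.
#' @param ... Unused.
#' @export
tidy.assoc_effect <- function(x, ...) {
  tibble::tibble(
    resource = x$resource,
    slope = x$slope,
    conf.low = x$ci[["lower"]],
    conf.high = x$ci[["upper"]],
    classification = x$classification
  )
}

#' @rdname associational_effect
#' @export
glance.assoc_effect <- function(x, ...) {
  tibble::tibble(
    resource = x$resource,
    n_treatments = nrow(x$points),
    n_boot = x$n_boot,
    level = x$level,
    classification = x$classification
  )
}

#' @rdname associational_effect
#' @export
autoplot.assoc_effect <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$alt_proportion,
                                    y = log(.data$mean_eggs + 0.5))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "proportion of the alternative resource",
      y = "log(mean eggs per substrate + 0.5)",
      title = sprintf("Resource %s: associational %s", object$resource,
                      object$classification),
      subtitle = sprintf("slope %.3f, %.0f%% bootstrap CI [%.3f, %.3f]",
                         object$slope, 100 * object$level,
                         object$ci[["lower"]], object$ci[["upper"]])
    ) +
    ggplot2::theme_minimal()
}

#' Per-treatment attack-rate curves by resource type
#'
#' A quick look at frequency dependence: mean eggs per substrate against the
#' proportion of the alternative resource, one line per resource type.
#'
#' @inheritParams per_substrate_rates
#' @return A ggplot object.
#' @export
plot_rate_curves <- function(data, designs = standard_designs()) {
  rates <- per_substrate_rates(data, designs)
  ggplot2::ggplot(rates, ggplot2::aes(x = .data$alt_proportion,
                                      y = .data$mean_eggs,
                                      colour = .data$resource)) +
    ggplot2::geom_point() +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::scale_y_continuous(trans = "log1p") +
    ggplot2::labs(
      x = "proportion of the alternative resource",
      y = "mean eggs per substrate",
      colour = "resource"
    ) +
    ggplot2::theme_minimal()
}
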