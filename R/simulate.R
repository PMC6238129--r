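# Deterministic per-stream seed derivation: subsets of a simulation are
# reproducible on their own (same design & replicate index => same draws).
stream_seed <- function(seed, design_index, replicate_index) {
  s0 <- as.double(seed %% 2147483647L)
  as.integer((s0 * 31 + design_index * 524287 + replicate_index * 101) %%
               2147483646) + 1L
}

rdirichlet_one <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) return(alpha / sum(alpha))
  g / sum(g)
}

#' Simulate egg-count experiments from the two-scale selection model
#'
#' The generative twin of the fitted model. For every design and replicate
#' (one replicate = one fly), a total egg count is drawn — negative binomial
#' by default, matching the overdispersed nature of per-fly counts, or a
#' fixed total for exact tests — and allocated across the design's
#' substrates by a multinomial with the probabilities of
#' [substrate_probabilities()]. With `overdispersion` set, the allocation is
#' Dirichlet-multinomial: the multinomial probability vector is itself drawn
#' from a Dirichlet with mean equal to the model probabilities and
#' concentration `overdispersion`, inflating between-fly variance while
#' preserving the mean allocation.
#'
#' Defaults mirror the emulated assay: 20 replicates per treatment and the
#' seven canonical designs of [standard_designs()].
#'
#' @param designs Named design registry (default [standard_designs()]).
#' @param s_wa,s_pa True selection coefficients, or a [selection_params()]
#'   object as `s_wa`.
#' @param n_replicates Replicates (flies) per design (default 20).
#' @param egg_mean Mean total eggs per fly (default 30).
#' @param egg_dispersion Negative-binomial size parameter of the per-fly
#'   total (default 5); smaller = more overdispersed totals.
#' @param egg_total `"nbinom"` (default) or `"fixed"` (every fly lays
#'   exactly `round(egg_mean)` eggs).
#' @param overdispersion Optional Dirichlet concentration (> 0) for
#'   overdispersed substrate allocation; `NULL` (default) gives the exact
#'   multinomial twin of the fitted model.
#' @param strain Strain label stamped on every row (default `"synthetic"`).
#' @param seed Optional integer master seed; given the seed the dataset is
#'   fully reproducible.
#' @return A validated egg-count tibble (columns `replicate_id`, `strain`,
#'   `treatment`, `patch_id`, `substrate_id`, `resource`, `eggs`), one row
#'   per replicate x substrate.
#' @examples
#' sim <- simulate_experiment(s_wa = 0.9, s_pa = 0.8, n_replicates = 2, seed = 42)
#' dplyr::count(sim, treatment)
#' @export
simulate_experiment <- function(designs = standard_designs(), s_wa = 0.5,
                                s_pa = 0.5, n_replicates = 20, egg_mean = 30,
                                egg_dispersion = 5,
                                egg_total = c("nbinom", "fixed"),
                                overdispersion = NULL, strain = "synthetic",
                                seed = NULL) {
  if (inherits(s_wa, "selection_params")) {
    s_pa <- s_wa$s_pa
    s_wa <- s_wa$s_wa
  }
  check_prob(s_wa, "s_wa")
  check_prob(s_pa, "s_pa")
  egg_total <- match.arg(egg_total)
  designs <- check_design_registry(designs)
  stopifnot(n_replicates >= 1, egg_mean > 0, egg_dispersion > 0)
  if (!is.null(overdispersion) && overdispersion <= 0) {
    abort("`overdispersion` must be a positive concentration parameter.")
  }

  out <- purrr::imap(designs, function(d, trt) {
    i <- match(trt, names(designs))
    probs <- substrate_probabilities(d, s_wa, s_pa)
    purrr::map(seq_len(n_replicates), function(r) {
      if (!is.null(seed)) set.seed(stream_seed(seed, i, r))
      total <- switch(egg_total,
        nbinom = rnbinom(1, mu = egg_mean, size = egg_dispersion),
        fixed = as.integer(round(egg_mean))
      )
      p <- probs$prob
      if (!is.null(overdispersion)) {
        p <- rdirichlet_one(overdispersion * p)
      }
      eggs <- if (total > 0) {
        as.integer(rmultinom(1, size = total, prob = p))
      } else {
        integer(nrow(probs))
      }
      tibble::tibble(
        replicate_id = sprintf("%s_r%02d", trt, r),
        strain = strain,
        treatment = trt,
        patch_id = probs$patch_id,
        substrate_id = probs$substrate_id,
        resource = probs$resource,
        eggs = eggs
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  validate_egg_counts(out, designs)
}

#' Parameter-recovery simulation study
#'
#' Repeatedly simulates experiments at known true coefficients, refits each
#' one, and summarizes how well the estimator recovers the truth: median
#' estimate, bias, RMSE and (when intervals are computed) empirical coverage
#' of the profile confidence intervals. Individual fit failures are recorded
#' and never abort the study.
#'
#' @param true_s_wa,true_s_pa Equal-length vectors of true parameter points;
#'   one recovery run is performed per point.
#' @param n_experiments Simulated experiments per true point (>= 2).
#' @inheritParams simulate_experiment
#' @param level Confidence level for coverage (default 0.95).
#' @param compute_ci Compute profile intervals per fit (needed for
#'   coverage; default `TRUE`).
#' @param seed Master seed; experiment `k` at point `j` uses a seed derived
#'   deterministically from it.
#' @return A tibble with one row per true point x parameter:
#'   `true_s_wa`, `true_s_pa`, `parameter`, `true`, `median_estimate`,
#'   `bias`, `rmse`, `coverage`, `n_experiments`, `n_failed`. Per-experiment
#'   estimates are attached as the `"details"` attribute.
#' @export
recovery_study <- function(true_s_wa, true_s_pa, n_experiments = 200,
                           designs = standard_designs(), n_replicates = 20,
                           egg_mean = 30, egg_dispersion = 5,
                           egg_total = "nbinom", overdispersion = NULL,
                           level = 0.95, compute_ci = TRUE, seed = 1L) {
  stopifnot(length(true_s_wa) == length(true_s_pa), n_experiments >= 2)
  details <- purrr::map(seq_along(true_s_wa), function(j) {
    purrr::map(seq_len(n_experiments), function(k) {
      exp_seed <- stream_seed(seed, j * 1009L, k)
      sim <- simulate_experiment(
        designs = designs, s_wa = true_s_wa[j], s_pa = true_s_pa[j],
        n_replicates = n_replicates, egg_mean = egg_mean,
        egg_dispersion = egg_dispersion, egg_total = egg_total,
        overdispersion = overdispersion, seed = exp_seed
      )
      fit <- tryCatch(
        suppressWarnings(fit_mle(sim, designs, level = level,
                                 compute_ci = compute_ci, seed = exp_seed)),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        return(tibble::tibble(point = j, experiment = k, failed = TRUE,
                              est_s_wa = NA_real_, est_s_pa = NA_real_,
                              cover_s_wa = NA, cover_s_pa = NA))
      }
      cover <- c(s_wa = NA, s_pa = NA)
      if (compute_ci && nrow(fit$ci) > 0) {
        for (p in c("s_wa", "s_pa")) {
          ci <- fit$ci[fit$ci$parameter == p, ]
          truth <- if (p == "s_wa") true_s_wa[j] else true_s_pa[j]
          cover[p] <- ci$lower <= truth && truth <= ci$upper
        }
      }
      tibble::tibble(point = j, experiment = k, failed = FALSE,
                     est_s_wa = fit$estimate[["s_wa"]],
                     est_s_pa = fit$estimate[["s_pa"]],
                     cover_s_wa = cover[["s_wa"]],
                     cover_s_pa = cover[["s_pa"]])
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  summary <- purrr::map(seq_along(true_s_wa), function(j) {
    dj <- details[details$point == j & !details$failed, ]
    purrr::map(c("s_wa", "s_pa"), function(p) {
      truth <- if (p == "s_wa") true_s_wa[j] else true_s_pa[j]
      est <- dj[[paste0("est_", p)]]
      cov <- dj[[paste0("cover_", p)]]
      tibble::tibble(
        true_s_wa = true_s_wa[j], true_s_pa = true_s_pa[j],
        parameter = p, true = truth,
        median_estimate = median(est),
        bias = mean(est) - truth,
        rmse = sqrt(mean((est - truth)^2)),
        coverage = if (compute_ci) mean(cov) else NA_real_,
        n_experiments = n_experiments,
        n_failed = sum(details$point == j & details$failed)
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  attr(summary, "details") <- details
  summary
}
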