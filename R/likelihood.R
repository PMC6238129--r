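# Internal fitting context: per treatment, the cached design structure and
# the egg counts pooled over replicates. Under the iid multinomial model the
# log-likelihood of the pooled counts equals the sum of per-replicate
# log-likelihoods (up to the omitted data-only multinomial coefficient), so
# pooling is exact, not an approximation.
fit_context <- function(data, designs) {
  designs <- check_design_registry(designs)
  data <- validate_egg_counts(data, designs)
  ctxs <- purrr::map(unique(data$treatment), function(trt) {
    d <- designs[[trt]]
    comp <- design_composition(d)
    sub <- data[data$treatment == trt, ]
    by_pr <- sub |>
      dplyr::group_by(.data$patch_id, .data$resource) |>
      dplyr::summarise(eggs = sum(.data$eggs), .groups = "drop")
    pick <- function(res) {
      v <- integer(nrow(comp))
      hit <- by_pr[by_pr$resource == res, ]
      v[match(hit$patch_id, comp$patch_id)] <- hit$eggs
      v
    }
    Ya <- pick("A")
    Yb <- pick("B")
    ia <- which(Ya > 0)
    ib <- which(Yb > 0)
    list(
      n_a = comp$n_a, n_b = comp$n_b,
      tot_a = sum(comp$n_a), tot_b = sum(comp$n_b),
      Ya = Ya, Yb = Yb, ia = ia, ib = ib,
      # constant from the equal split of a type's mass among its substrates:
      # log(T / n_same) = log(T) - log(n_same)
      cst = -(sum(Ya[ia] * log(comp$n_a[ia])) + sum(Yb[ib] * log(comp$n_b[ib])))
    )
  })
  totals <- data |>
    dplyr::group_by(.data$treatment, .data$replicate_id) |>
    dplyr::summarise(total = sum(.data$eggs), .groups = "drop")
  list(
    ctxs = ctxs,
    n_replicates = sum(totals$total > 0),
    n_zero_replicates = sum(totals$total == 0),
    n_eggs = sum(data$eggs)
  )
}

# Vectorized log-likelihood over parameter pairs, with a fast scalar path
# for the optimizer. Counts are pooled by (patch, resource); the equal-split
# constant lives in ctx$cst. With clamp = TRUE, probabilities are floored at
# 1e-12 inside the log (optimizer stability); with clamp = FALSE a
# zero-probability substrate holding eggs yields -Inf.
ll_vec <- function(ctxs, s_wa, s_pa, clamp = FALSE) {
  G <- length(s_wa)
  out <- numeric(G)
  for (ctx in ctxs) {
    if (G == 1L) {
      den <- s_pa * ctx$tot_a + (1 - s_pa) * ctx$tot_b
      if (den <= 0) abort("Degenerate design: zero selection-weighted substrate total.")
      P <- (s_pa * ctx$n_a + (1 - s_pa) * ctx$n_b) / den
      wnum <- s_wa * ctx$n_a
      wden <- wnum + (1 - s_wa) * ctx$n_b
      W <- ifelse(wden > 0, wnum / wden, 0)
      W[ctx$n_b == 0] <- 1
      W[ctx$n_a == 0] <- 0
      v <- ctx$cst
      if (length(ctx$ia)) {
        ta <- W[ctx$ia] * P[ctx$ia]
        if (clamp) ta <- pmax(ta, 1e-12)
        v <- v + sum(ctx$Ya[ctx$ia] * log(ta))
      }
      if (length(ctx$ib)) {
        tb <- (1 - W[ctx$ib]) * P[ctx$ib]
        if (clamp) tb <- pmax(tb, 1e-12)
        v <- v + sum(ctx$Yb[ctx$ib] * log(tb))
      }
      out <- out + v
    } else {
      den <- s_pa * ctx$tot_a + (1 - s_pa) * ctx$tot_b
      if (any(den <= 0)) abort("Degenerate design: zero selection-weighted substrate total.")
      P <- sweep(outer(ctx$n_a, s_pa) + outer(ctx$n_b, 1 - s_pa), 2, den, "/")
      wnum <- outer(ctx$n_a, s_wa)
      wden <- wnum + outer(ctx$n_b, 1 - s_wa)
      W <- ifelse(wden > 0, wnum / wden, 0)
      W[ctx$n_b == 0, ] <- 1
      W[ctx$n_a == 0, ] <- 0
      v <- rep(ctx$cst, G)
      if (length(ctx$ia)) {
        ta <- W[ctx$ia, , drop = FALSE] * P[ctx$ia, , drop = FALSE]
        if (clamp) ta <- pmax(ta, 1e-12)
        v <- v + colSums(ctx$Ya[ctx$ia] * log(ta))
      }
      if (length(ctx$ib)) {
        tb <- (1 - W[ctx$ib, , drop = FALSE]) * P[ctx$ib, , drop = FALSE]
        if (clamp) tb <- pmax(tb, 1e-12)
        v <- v + colSums(ctx$Yb[ctx$ib] * log(tb))
      }
      out <- out + v
    }
  }
  out
}

#' Multinomial log-likelihood of egg counts under the two-scale model
#'
#' For each replicate the eight substrate counts are modelled as a
#' multinomial draw with the per-substrate probabilities of
#' [substrate_probabilities()]; with two resource types this is the binomial
#' model aggregated by type, generalized to the per-substrate level. The
#' value returned is \eqn{\sum \mathrm{eggs} \times \log(\mathrm{prob})}
#' summed over all rows — the multinomial log-likelihood up to an additive
#' data-only constant (the multinomial coefficient is omitted, so values are
#' comparable only within a dataset). If any substrate with a positive count
#' has probability zero the result is `-Inf`.
#'
#' @param data Long-format egg-count data (see [validate_egg_counts()]).
#' @param designs Named design registry resolving the treatments in `data`.
#' @param s_wa,s_pa Selection coefficients in \[0, 1\], or a
#'   [selection_params()] object as `s_wa`.
#' @return A single numeric log-likelihood (possibly `-Inf`).
#' @export
log_likelihood <- function(data, designs, s_wa, s_pa = NULL) {
  if (inherits(s_wa, "selection_params")) {
    s_pa <- s_wa$s_pa
    s_wa <- s_wa$s_wa
  }
  check_prob(s_wa, "s_wa")
  check_prob(s_pa, "s_pa")
  fc <- fit_context(data, designs)
  ll_vec(fc$ctxs, s_wa, s_pa, clamp = FALSE)
}

#' Maximum-likelihood estimation of the two selection coefficients
#'
#' Maximizes the multinomial log-likelihood over \eqn{(s_{wa}, s_{pa}) \in
#' [0,1]^2} by Nelder-Mead on the logit scale, started from a `starts` x
#' `starts` uniform grid of parameter values; the best of all starts wins
#' (ties broken by grid order). Estimates indistinguishable from a boundary
#' are snapped to 0 or 1 and flagged. A parameter whose likelihood slice is
#' flat (range below 1e-6 across its grid) is flagged unidentifiable and
#' given the full interval \[0, 1\] as its confidence interval; otherwise
#' profile-likelihood intervals are computed via [profile_ci()].
#'
#' Replicates with zero total eggs carry no information about the selection
#' coefficients and are excluded with a warning. Fits are per strain: if
#' `data` holds several strains, pass `strain` to select one.
#'
#' @inheritParams log_likelihood
#' @param level Confidence level for the profile intervals (default 0.95).
#' @param starts Number of starting values per parameter axis (default 5,
#'   i.e. a 5 x 5 grid).
#' @param strain Optional strain label to filter on; required when `data`
#'   contains more than one strain.
#' @param seed Optional integer recorded in the result for provenance (the
#'   optimization itself is deterministic).
#' @param compute_ci Compute profile confidence intervals (default `TRUE`).
#'   Skipping them speeds up large simulation studies; [profile_ci()] can
#'   add them later.
#' @return An object of class `selection_fit`: a list with elements
#'   `estimate` (named vector `s_wa`, `s_pa`), `log_likelihood`, `ci`
#'   (tibble of intervals), `boundary` and `identifiable` flags per
#'   parameter, `n_replicates_used`, `n_zero_replicates`, `n_eggs`,
#'   `starts_tried`, `level`, `seed`, `convergence`. Supports [tidy()],
#'   [glance()], [autoplot()].
#' @examples
#' sim <- simulate_experiment(s_wa = 0.9, s_pa = 0.8, n_replicates = 5, seed = 1)
#' fit <- fit_mle(sim, standard_designs(), compute_ci = FALSE)
#' tidy(fit)
#' @export
fit_mle <- function(data, designs = standard_designs(), level = 0.95,
                    starts = 5, strain = NULL, seed = NULL,
                    compute_ci = TRUE) {
  stopifnot(is.numeric(level), length(level) == 1, level > 0, level < 1,
            is.numeric(starts), starts >= 1)
  if (!is.null(strain)) data <- data[data$strain %in% strain, ]
  if (nrow(data) > 0 && dplyr::n_distinct(data$strain) > 1) {
    abort(paste0(
      "Data contain several strains (", toString(unique(data$strain)),
      "); fits are per strain — pass `strain` to select one."
    ))
  }
  if (nrow(data) == 0) abort("No data: nothing to fit.")
  fc <- fit_context(data, designs)
  if (fc$n_zero_replicates > 0) {
    warn(sprintf(
      "%d replicate(s) with zero total eggs excluded from the likelihood.",
      fc$n_zero_replicates
    ))
  }
  if (fc$n_eggs == 0) abort("All replicates are empty: no eggs to fit.")

  neg_ll <- function(t) -ll_vec(fc$ctxs, stats::plogis(t[1]), stats::plogis(t[2]),
                                clamp = TRUE)
  axis <- stats::qlogis(seq(0.1, 0.9, length.out = starts))
  start_grid <- expand.grid(t_wa = axis, t_pa = axis, KEEP.OUT.ATTRS = FALSE)

  # coarse pass from every start, then a tight polish of the winner
  best <- NULL
  for (k in seq_len(nrow(start_grid))) {
    res <- tryCatch(
      optim(as.numeric(start_grid[k, ]), neg_ll, method = "Nelder-Mead",
            control = list(reltol = 1e-7, maxit = 400)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value - 1e-10) best <- res
  }
  if (is.null(best)) {
    abort(sprintf("Optimization failed from all %d starting values.",
                  nrow(start_grid)))
  }
  polish <- tryCatch(
    optim(best$par, neg_ll, method = "Nelder-Mead",
          control = list(reltol = 1e-13, maxit = 2000)),
    error = function(e) NULL
  )
  if (!is.null(polish) && polish$value <= best$value) best <- polish

  est <- stats::plogis(best$par)
  names(est) <- c("s_wa", "s_pa")

  # flat likelihood slice across a parameter's grid => not identifiable
  identifiable <- c(s_wa = TRUE, s_pa = TRUE)
  grid_theta <- seq(0, 1, length.out = 21)
  for (p in c("s_wa", "s_pa")) {
    slice <- if (p == "s_wa") {
      ll_vec(fc$ctxs, grid_theta, rep(est["s_pa"], 21), clamp = TRUE)
    } else {
      ll_vec(fc$ctxs, rep(est["s_wa"], 21), grid_theta, clamp = TRUE)
    }
    if (diff(range(slice)) < 1e-6) identifiable[p] <- FALSE
  }

  boundary <- c(s_wa = FALSE, s_pa = FALSE)
  # snap to a boundary when the exact likelihood there is at least as good
  # (skipped for flat parameters, whose value is arbitrary anyway)
  for (p in c("s_wa", "s_pa")) {
    if (!identifiable[p]) next
    for (b in c(0, 1)) {
      cand <- est
      cand[p] <- b
      if (ll_vec(fc$ctxs, cand[1], cand[2], clamp = FALSE) >=
          ll_vec(fc$ctxs, est[1], est[2], clamp = FALSE) - 1e-8) {
        est <- cand
        boundary[p] <- TRUE
        break
      }
    }
  }
  ll_hat <- ll_vec(fc$ctxs, est[1], est[2], clamp = TRUE)

  fit <- structure(
    list(
      estimate = est,
      log_likelihood = ll_hat,
      ci = NULL,
      boundary = boundary,
      identifiable = identifiable,
      n_replicates_used = fc$n_replicates,
      n_zero_replicates = fc$n_zero_replicates,
      n_eggs = fc$n_eggs,
      starts_tried = nrow(start_grid),
      level = level,
      seed = seed,
      convergence = best$convergence,
      .ctxs = fc$ctxs
    ),
    class = "selection_fit"
  )
  fit$ci <- if (compute_ci) {
    dplyr::bind_rows(
      profile_ci(data = NULL, designs = NULL, fit = fit, parameter = "s_wa", level = level),
      profile_ci(data = NULL, designs = NULL, fit = fit, parameter = "s_pa", level = level)
    )
  } else {
    tibble::tibble(parameter = character(), lower = numeric(),
                   upper = numeric(), level = numeric())
  }
  fit
}

#' Profile-likelihood confidence interval for one selection coefficient
#'
#' The interval is the set \eqn{\{\theta : 2(\ell_{max} -
#' \ell_{prof}(\theta)) \le \chi^2_{1,level}\}} where
#' \eqn{\ell_{prof}(\theta)} maximizes the log-likelihood over the other
#' coefficient with the focal one fixed. Interior endpoints are located by
#' bisection to 1e-6; an endpoint is reported as exactly 0 or 1 when the
#' boundary lies inside the set. A flat profile yields \[0, 1\] and the
#' unidentifiability flag.
#'
#' @inheritParams fit_mle
#' @param fit A `selection_fit` from [fit_mle()]. When supplied, `data` and
#'   `designs` may be `NULL` (the fit carries its own likelihood context);
#'   otherwise they must be the data and registry the fit was computed from.
#' @param parameter `"s_wa"` or `"s_pa"`.
#' @return One-row tibble: `parameter`, `lower`, `upper`, `level`,
#'   `identifiable`.
#' @export
profile_ci <- function(data, designs, fit, parameter = c("s_wa", "s_pa"),
                       level = fit$level) {
  parameter <- match.arg(parameter)
  ctxs <- fit$.ctxs
  if (is.null(ctxs)) ctxs <- fit_context(data, designs)$ctxs
  if (!isTRUE(fit$identifiable[[parameter]])) {
    return(tibble::tibble(parameter = parameter, lower = 0, upper = 1,
                          level = level, identifiable = FALSE))
  }
  prof <- if (parameter == "s_wa") {
    function(theta) {
      f <- function(o) ll_vec(ctxs, theta, o, clamp = TRUE)
      max(optimize(f, c(0, 1), maximum = TRUE, tol = 1e-9)$objective, f(0), f(1))
    }
  } else {
    function(theta) {
      f <- function(o) ll_vec(ctxs, o, theta, clamp = TRUE)
      max(optimize(f, c(0, 1), maximum = TRUE, tol = 1e-9)$objective, f(0), f(1))
    }
  }
  cutoff <- qchisq(level, df = 1)
  mle <- unname(fit$estimate[[parameter]])
  ll_max <- fit$log_likelihood
  dev <- function(theta) 2 * (ll_max - prof(theta))

  find_end <- function(at_boundary, inner) {
    if (dev(at_boundary) <= cutoff) return(at_boundary)
    lo <- min(at_boundary, inner)
    hi <- max(at_boundary, inner)
    # root of dev - cutoff between the boundary and the MLE
    while (hi - lo > 1e-6) {
      mid <- (lo + hi) / 2
      inside <- dev(mid) <= cutoff
      if (at_boundary < inner) {  # searching below the MLE
        if (inside) hi <- mid else lo <- mid
      } else {
        if (inside) lo <- mid else hi <- mid
      }
    }
    (lo + hi) / 2
  }

  tibble::tibble(
    parameter = parameter,
    lower = find_end(0, mle),
    upper = find_end(1, mle),
    level = level,
    identifiable = TRUE
  )
}

#' Exhaustive grid search over the selection-coefficient square
#'
#' Evaluates the exact log-likelihood on a `resolution` x `resolution`
#' lattice over \eqn{[0,1]^2} (including the corners) and returns the
#' argmax. This is the package's brute-force testing oracle for
#' [fit_mle()]; ties go to the first lattice point in row-major order.
#'
#' @inheritParams log_likelihood
#' @param resolution Number of lattice points per axis (at least 2;
#'   101 gives a 0.01 grid).
#' @return A list: `estimate` ([selection_params()]), `log_likelihood`,
#'   `resolution`.
#' @export
brute_force_grid <- function(data, designs = standard_designs(), resolution = 101) {
  stopifnot(is.numeric(resolution), length(resolution) == 1, resolution >= 2)
  resolution <- as.integer(resolution)
  fc <- fit_context(data, designs)
  axis <- seq(0, 1, length.out = resolution)
  grid <- expand.grid(s_wa = axis, s_pa = axis, KEEP.OUT.ATTRS = FALSE)
  ll <- ll_vec(fc$ctxs, grid$s_wa, grid$s_pa, clamp = FALSE)
  k <- which.max(ll)  # first maximum in grid order
  list(
    estimate = selection_params(grid$s_wa[k], grid$s_pa[k]),
    log_likelihood = ll[k],
    resolution = resolution
  )
}

#' @export
print.selection_fit <- function(x, ...) {
  cat("<selection_fit> two-scale resource selection model\n")
  cat(sprintf("  s_wa (within-patch) : %.4f%s\n", x$estimate[["s_wa"]],
              if (x$boundary[["s_wa"]]) " [boundary]" else ""))
  cat(sprintf("  s_pa (between-patch): %.4f%s\n", x$estimate[["s_pa"]],
              if (x$boundary[["s_pa"]]) " [boundary]" else ""))
  if (!is.null(x$ci) && nrow(x$ci) > 0) {
    for (i in seq_len(nrow(x$ci))) {
      cat(sprintf("  %s %.0f%% profile CI: [%.4f, %.4f]%s\n",
                  x$ci$parameter[i], 100 * x$ci$level[i],
                  x$ci$lower[i], x$ci$upper[i],
                  if (!x$ci$identifiable[i]) " (not identifiable)" else ""))
    }
  }
  cat(sprintf("  logLik %.3f | %d replicates, %d eggs | %d starts\n",
              x$log_likelihood, x$n_replicates_used, x$n_eggs, x$starts_tried))
  if (any(!x$identifiable)) {
    cat(sprintf("  not identifiable: %s\n",
                toString(names(x$identifiable)[!x$identifiable])))
  }
  invisible(x)
}

#' @rdname fit_mle
#' @param x A `selection_fit` object.
#' @param ... Unused.
#' @export
tidy.selection_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = names(x$estimate),
    estimate = unname(x$estimate),
    boundary = unname(x$boundary),
    identifiable = unname(x$identifiable)
  )
  if (!is.null(x$ci) && nrow(x$ci) > 0) {
    ci <- tibble::tibble(term = x$ci$parameter, conf.low = x$ci$lower,
                         conf.high = x$ci$upper)
    out <- dplyr::left_join(out, ci, by = "term") |>
      dplyr::select("term", "estimate", "conf.low", "conf.high",
                    "boundary", "identifiable")
  }
  out
}

#' @rdname fit_mle
#' @export
glance.selection_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$log_likelihood,
    n_replicates = x$n_replicates_used,
    n_zero_replicates = x$n_zero_replicates,
    n_eggs = x$n_eggs,
    starts_tried = x$starts_tried,
    level = x$level,
    converged = x$convergence == 0
  )
}

#' @rdname fit_mle
#' @param object A `selection_fit` object.
#' @export
autoplot.selection_fit <- function(object, ...) {
  td <- tidy(object)
  scale_lab <- c(s_wa = "within patch", s_pa = "between patches")
  td$scale <- factor(scale_lab[td$term], levels = scale_lab)
  p <- ggplot2::ggplot(td, ggplot2::aes(x = .data$scale, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(size = 3)
  if (all(c("conf.low", "conf.high") %in% names(td))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high), width = 0.1
    )
  }
  p +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "selection coefficient for resource A",
      title = "Resource selection at two spatial scales",
      subtitle = "0.5 = no preference; above = preference for A"
    ) +
    ggplot2::theme_minimal()
}
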