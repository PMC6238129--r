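designs <- standard_designs()

test_that("log-likelihood matches hand computation and the zero-probability sentinel", {
  d44 <- designs["4:4-even"]
  data <- one_replicate(d44[[1]], c(p1_s1 = 10), treatment = "4:4-even")
  # neutral parameters: every substrate has probability 1/8
  expect_equal(log_likelihood(data, d44, 0.5, 0.5), 10 * log(1 / 8),
               tolerance = 1e-10)
  # an egg on a B substrate under total preference for A is impossible
  data_b <- one_replicate(d44[[1]], c(p1_s3 = 1, p1_s1 = 5), treatment = "4:4-even")
  expect_identical(log_likelihood(data_b, d44, 1, 0.5), -Inf)
  expect_identical(log_likelihood(data_b, d44, 1, 0.2), -Inf)
})

test_that("the likelihood is additive over replicates and invariant to pooling", {
  set.seed(11)
  sim <- simulate_experiment(designs = designs, s_wa = 0.8, s_pa = 0.6,
                             n_replicates = 4, seed = 91)
  r1 <- sim[sim$replicate_id %in% unique(sim$replicate_id)[1:14], ]
  r2 <- sim[!sim$replicate_id %in% unique(sim$replicate_id)[1:14], ]
  expect_equal(
    log_likelihood(sim, designs, 0.7, 0.55),
    log_likelihood(r1, designs, 0.7, 0.55) + log_likelihood(r2, designs, 0.7, 0.55)
  )
  # pool all replicates of each treatment into one pseudo-replicate
  pooled <- sim |>
    dplyr::group_by(treatment, patch_id, substrate_id, resource) |>
    dplyr::summarise(eggs = sum(eggs), .groups = "drop") |>
    dplyr::mutate(replicate_id = "pooled", strain = "wt")
  expect_equal(log_likelihood(pooled, designs, 0.7, 0.55),
               log_likelihood(sim, designs, 0.7, 0.55))
  fit_a <- suppressWarnings(fit_mle(sim, designs, compute_ci = FALSE))
  fit_b <- suppressWarnings(fit_mle(pooled, designs, compute_ci = FALSE))
  expect_equal(fit_a$estimate, fit_b$estimate, tolerance = 1e-5)
})

test_that("all eggs on apple drives the within-patch MLE to the boundary", {
  data <- constant_dataset(function(res) if (res == "A") 5 else 0,
                           designs, n_rep = 2)
  fit <- fit_mle(data, designs, compute_ci = FALSE)
  expect_equal(fit$estimate[["s_wa"]], 1)
  expect_true(fit$boundary[["s_wa"]])
})

test_that("a symmetric single-treatment design leaves s_pa unidentifiable", {
  sim <- simulate_experiment(designs = designs["4:4-even"], s_wa = 0.8,
                             s_pa = 0.5, n_replicates = 10, seed = 5)
  fit <- fit_mle(sim, designs["4:4-even"])
  expect_false(fit$identifiable[["s_pa"]])
  expect_true(fit$identifiable[["s_wa"]])
  ci <- fit$ci[fit$ci$parameter == "s_pa", ]
  expect_equal(c(ci$lower, ci$upper), c(0, 1))
})

test_that("the optimizer agrees with the brute-force grid oracle", {
  set.seed(77)
  for (i in 1:5) {
    sim <- simulate_experiment(
      designs = designs, s_wa = runif(1, 0.1, 0.9), s_pa = runif(1, 0.1, 0.9),
      n_replicates = 3, seed = 1000 + i
    )
    fit <- suppressWarnings(fit_mle(sim, designs, compute_ci = FALSE))
    bf <- brute_force_grid(sim, designs, resolution = 51)
    cell <- 1 / 50
    expect_lte(abs(fit$estimate[["s_wa"]] - bf$estimate$s_wa), cell + 1e-9)
    expect_lte(abs(fit$estimate[["s_pa"]] - bf$estimate$s_pa), cell + 1e-9)
    expect_gte(fit$log_likelihood, bf$log_likelihood - 1e-6)
  }
})

test_that("the grid oracle covers the unit square corners at resolution 2", {
  data <- constant_dataset(function(res) if (res == "A") 3 else 0,
                           designs["6:2-uneven"], n_rep = 1)
  bf <- brute_force_grid(data, designs["6:2-uneven"], resolution = 2)
  # three corners put zero probability on occupied substrates; (1, 1) wins
  expect_equal(bf$estimate$s_wa, 1)
  expect_equal(bf$estimate$s_pa, 1)
  expect_true(is.finite(bf$log_likelihood))
  expect_error(brute_force_grid(data, designs["6:2-uneven"], resolution = 1))
})

test_that("relabeling the resources maps the estimates to their complements", {
  sim <- simulate_experiment(designs = designs, s_wa = 0.85, s_pa = 0.7,
                             n_replicates = 8, seed = 314)
  fit <- suppressWarnings(fit_mle(sim, designs, compute_ci = FALSE))
  flipped <- mirror_dataset(sim, designs)
  fit_m <- suppressWarnings(fit_mle(flipped$data, flipped$designs,
                                    compute_ci = FALSE))
  expect_equal(fit_m$estimate[["s_wa"]], 1 - fit$estimate[["s_wa"]],
               tolerance = 1e-4)
  expect_equal(fit_m$estimate[["s_pa"]], 1 - fit$estimate[["s_pa"]],
               tolerance = 1e-4)
})

test_that("profile intervals contain the MLE and cut the deviance at the chi-square quantile", {
  sim <- simulate_experiment(designs = designs, s_wa = 0.9, s_pa = 0.8,
                             n_replicates = 20, seed = 2024)
  fit <- suppressWarnings(fit_mle(sim, designs))
  cutoff <- qchisq(0.95, 1)
  # independent profile evaluation through the public likelihood
  prof <- function(param, theta) {
    obj <- function(o) {
      if (param == "s_wa") log_likelihood(sim, designs, theta, o)
      else log_likelihood(sim, designs, o, theta)
    }
    optimize(obj, c(0, 1), maximum = TRUE, tol = 1e-9)$objective
  }
  for (p in c("s_wa", "s_pa")) {
    ci <- fit$ci[fit$ci$parameter == p, ]
    est <- fit$estimate[[p]]
    expect_true(ci$lower <= est && est <= ci$upper)
    expect_true(ci$lower > 0 && ci$upper < 1)  # interior at this sample size
    for (end in c(ci$lower, ci$upper)) {
      dev <- 2 * (fit$log_likelihood - prof(p, end))
      expect_equal(dev, cutoff, tolerance = 1e-3)
    }
  }
  # a simulated interval at n = 140 replicates is tight around the truth
  ci_wa <- fit$ci[fit$ci$parameter == "s_wa", ]
  expect_true(ci_wa$lower <= 0.9 && 0.9 <= ci_wa$upper)
  expect_lt(ci_wa$upper - ci_wa$lower, 0.1)
})

test_that("estimation error shrinks as the number of replicates doubles", {
  rs <- recovery_study(
    true_s_wa = 0.9, true_s_pa = 0.8, n_experiments = 30,
    n_replicates = 5, compute_ci = FALSE, seed = 11
  )
  rs2 <- recovery_study(
    true_s_wa = 0.9, true_s_pa = 0.8, n_experiments = 30,
    n_replicates = 10, compute_ci = FALSE, seed = 11
  )
  rs4 <- recovery_study(
    true_s_wa = 0.9, true_s_pa = 0.8, n_experiments = 30,
    n_replicates = 20, compute_ci = FALSE, seed = 11
  )
  for (p in c("s_wa", "s_pa")) {
    r1 <- rs$rmse[rs$parameter == p]
    r2 <- rs2$rmse[rs2$parameter == p]
    r4 <- rs4$rmse[rs4$parameter == p]
    expect_lt(r2, r1)
    expect_lt(r4, r2)
  }
})

test_that("degenerate inputs fail loudly", {
  expect_error(fit_mle(constant_dataset(0, designs["4:4-even"], n_rep = 0)),
               "No data")
  empty <- constant_dataset(0, designs["4:4-even"], n_rep = 2)
  expect_error(suppressWarnings(fit_mle(empty, designs["4:4-even"])), "empty")
  two <- dplyr::bind_rows(
    constant_dataset(1, designs["4:4-even"], n_rep = 1, strain = "wt"),
    constant_dataset(1, designs["4:4-even"], n_rep = 1, strain = "orco")
  )
  expect_error(fit_mle(two, designs["4:4-even"]), "per strain")
  # strain filter resolves it
  fit <- fit_mle(two, designs["4:4-even"], strain = "wt", compute_ci = FALSE)
  expect_s3_class(fit, "selection_fit")
})

test_that("zero-total replicates are excluded with a warning, not an error", {
  d44 <- designs["4:4-even"]
  data <- dplyr::bind_rows(
    one_replicate(d44[[1]], c(p1_s1 = 6, p2_s3 = 2), treatment = "4:4-even",
                  replicate_id = "r1"),
    one_replicate(d44[[1]], c(), treatment = "4:4-even", replicate_id = "r2")
  )
  expect_warning(fit <- fit_mle(data, d44, compute_ci = FALSE), "zero total")
  expect_equal(fit$n_replicates_used, 1)
  expect_equal(fit$n_zero_replicates, 1)
  expect_equal(fit$n_eggs, 8)
})

test_that("tidy, glance and autoplot expose the fit", {
  sim <- simulate_experiment(designs = designs, s_wa = 0.8, s_pa = 0.6,
                             n_replicates = 5, seed = 8)
  fit <- suppressWarnings(fit_mle(sim, designs))
  td <- tidy(fit)
  expect_equal(td$term, c("s_wa", "s_pa"))
  expect_true(all(c("estimate", "conf.low", "conf.high") %in% names(td)))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$starts_tried, 25L)
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})
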