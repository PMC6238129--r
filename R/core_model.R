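#' Selection parameters for the two-scale choice model
#'
#' Bundles the two selection coefficients. Each lies in the closed unit
#' interval; 0.5 means no preference between the resource types at that
#' scale (a Manly-type selectivity). The coefficients for resource B are
#' always the complements `1 - s_wa` and `1 - s_pa` and are never stored.
#'
#' @param s_wa Within-patch selection coefficient for resource A.
#' @param s_pa Between-patch selection coefficient for resource A.
#' @return A named list of class `selection_params`.
#' @examples
#' selection_params(0.9, 0.8)
#' @export
selection_params <- function(s_wa, s_pa) {
  check_prob(s_wa, "s_wa")
  check_prob(s_pa, "s_pa")
  structure(list(s_wa = as.numeric(s_wa), s_pa = as.numeric(s_pa)),
            class = "selection_params")
}

#' @export
print.selection_params <- function(x, ...) {
  cat(sprintf("<selection_params> s_wa = %.4g, s_pa = %.4g\n", x$s_wa, x$s_pa))
  invisible(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1], got %s.",
                  name, toString(x)))
  }
  invisible(x)
}

#' Relative within-patch use of resource A
#'
#' For a patch holding `n_a` substrates of resource A and `n_b` of resource
#' B, the relative use of A is
#' \deqn{W_A = \frac{s_{wa} n_A}{s_{wa} n_A + (1 - s_{wa}) n_B},}
#' the Manly selectivity weighting of availability. The use of B is
#' `1 - W_A`. A patch holding only one resource type yields 1 (only A) or
#' 0 (only B) regardless of the coefficient.
#'
#' @param s_wa Within-patch selection coefficient in \[0, 1\] (vectorized).
#' @param n_a,n_b Non-negative substrate counts of each resource type;
#'   `n_a + n_b` must be at least 1.
#' @return `W_A`, the probability that an egg laid in this patch lands on an
#'   A-type substrate.
#' @examples
#' within_patch_use(0.5, 3, 1)  # neutral selection: availability share 3/4
#' within_patch_use(0.9, 2, 6)
#' @export
within_patch_use <- function(s_wa, n_a, n_b) {
  if (!is.numeric(s_wa) || any(is.na(s_wa)) || any(s_wa < 0) || any(s_wa > 1)) {
    abort("`s_wa` must be numeric in [0, 1].")
  }
  if (any(n_a < 0) || any(n_b < 0)) abort("Substrate counts must be non-negative.")
  if (any(n_a + n_b < 1)) abort("Empty patch: `n_a + n_b` must be at least 1.")
  n <- max(length(s_wa), length(n_a), length(n_b))
  s <- rep_len(s_wa, n)
  na <- rep_len(n_a, n)
  nb <- rep_len(n_b, n)
  out <- s * na / (s * na + (1 - s) * nb)
  out[nb == 0] <- 1
  out[na == 0] <- 0
  out
}

#' Relative use of each patch in a design
#'
#' The relative use of patch `j` with composition `(N_Aj, N_Bj)` is
#' \deqn{P_j = \frac{s_{pa} N_{Aj} + (1 - s_{pa}) N_{Bj}}
#'                  {s_{pa} \sum_j N_{Aj} + (1 - s_{pa}) \sum_j N_{Bj}},}
#' so patch use is driven by the selection-weighted resource content of the
#' patch relative to the whole arena. The `P_j` sum to 1. A boundary
#' coefficient that zeroes the denominator (e.g. `s_pa = 1` in a design with
#' no A substrates) is a degenerate-design error.
#'
#' @param design An [experiment_design()].
#' @param s_pa Between-patch selection coefficient in \[0, 1\].
#' @return Tibble with columns `patch_id`, `patch_use`, in design patch order.
#' @examples
#' d <- standard_designs()[["6:2-uneven"]]
#' patch_use(d, 0.75)
#' @export
patch_use <- function(design, s_pa) {
  check_prob(s_pa, "s_pa")
  comp <- design_composition(design)
  num <- s_pa * comp$n_a + (1 - s_pa) * comp$n_b
  den <- sum(num)
  if (den <= 0) {
    abort(paste0(
      "Degenerate design: the selection-weighted substrate total is zero ",
      "(s_pa at a boundary with no substrates of the favoured resource)."
    ))
  }
  tibble::tibble(patch_id = comp$patch_id, patch_use = num / den)
}

#' Per-substrate use probabilities under the two-scale model
#'
#' Combines the two scales: assuming within- and between-patch selection are
#' independent, the probability mass on resource A in patch `j` is
#' \eqn{T_{Aj} = W_{Aj} \times P_j} (and `(1 - W_{Aj}) P_j` for B). The mass
#' for a resource type within a patch is divided equally among that patch's
#' substrates of the type, giving one use probability per substrate; these
#' sum to 1 over the design.
#'
#' @param design An [experiment_design()].
#' @param s_wa,s_pa Selection coefficients in \[0, 1\], or pass a
#'   [selection_params()] object as `s_wa`.
#' @return Tibble with one row per substrate: `patch_id`, `substrate_id`,
#'   `resource`, `patch_use` (`P_j`), `within_use` (`W` for the substrate's
#'   own resource type), `prob` (the per-substrate use probability).
#' @examples
#' d <- standard_designs()[["4:4-even"]]
#' substrate_probabilities(d, 0.75, 0.5)
#' @export
substrate_probabilities <- function(design, s_wa, s_pa = NULL) {
  if (inherits(s_wa, "selection_params")) {
    s_pa <- s_wa$s_pa
    s_wa <- s_wa$s_wa
  }
  check_prob(s_wa, "s_wa")
  check_prob(s_pa, "s_pa")
  pu <- patch_use(design, s_pa)
  comp <- design_composition(design)
  per_patch <- dplyr::left_join(comp, pu, by = "patch_id") |>
    dplyr::mutate(w_a = within_patch_use(s_wa, .data$n_a, .data$n_b))
  design |>
    tibble::as_tibble() |>
    dplyr::left_join(per_patch, by = "patch_id") |>
    dplyr::mutate(
      within_use = ifelse(.data$resource == "A", .data$w_a, 1 - .data$w_a),
      n_same = ifelse(.data$resource == "A", .data$n_a, .data$n_b),
      prob = .data$within_use * .data$patch_use / .data$n_same
    ) |>
    dplyr::select("patch_id", "substrate_id", "resource",
                  "patch_use", "within_use", "prob")
}

# ---- internal vectorized engine -------------------------------------------
#
# The likelihood code evaluates substrate probabilities for many parameter
# pairs at once (multi-start fits, profile bisection, the grid oracle). The
# context below caches a design's patch structure so those evaluations are
# plain matrix arithmetic.

design_ctx <- function(design) {
  comp <- design_composition(design)
  sub <- tibble::as_tibble(design) |>
    dplyr::left_join(comp, by = "patch_id")
  list(
    n_a = comp$n_a,
    n_b = comp$n_b,
    tot_a = sum(comp$n_a),
    tot_b = sum(comp$n_b),
    patch_index = match(sub$patch_id, comp$patch_id),
    is_a = sub$resource == "A",
    n_same = ifelse(sub$resource == "A", sub$n_a, sub$n_b),
    substrate_id = sub$substrate_id
  )
}

# 8 x G matrix of per-substrate probabilities for G parameter pairs.
ctx_prob_matrix <- function(ctx, s_wa, s_pa) {
  G <- length(s_wa)
  num <- outer(ctx$n_a, s_pa) + outer(ctx$n_b, 1 - s_pa)  # J x G
  den <- ctx$tot_a * s_pa + ctx$tot_b * (1 - s_pa)
  if (any(den <= 0)) {
    abort("Degenerate design: zero selection-weighted substrate total.")
  }
  P <- sweep(num, 2, den, "/")
  wa_num <- outer(ctx$n_a, s_wa)
  wa_den <- wa_num + outer(ctx$n_b, 1 - s_wa)
  W <- ifelse(wa_den > 0, wa_num / wa_den, 0)
  W[ctx$n_b == 0, ] <- 1
  W[ctx$n_a == 0, ] <- 0
  Wsub <- W[ctx$patch_index, , drop = FALSE]
  Wsub[!ctx$is_a, ] <- 1 - Wsub[!ctx$is_a, , drop = FALSE]
  Wsub * P[ctx$patch_index, , drop = FALSE] / ctx$n_same
}
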