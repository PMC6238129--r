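#' Build an experiment design from per-patch substrate counts
#'
#' An experiment design describes one treatment of a two-resource choice
#' assay: a set of patches, each holding some number of discrete substrates
#' of resource type `"A"` or `"B"`. It is stored as a tibble with one row
#' per substrate and carries the treatment label, the overall A:B frequency
#' ratio and the distribution kind (`"even"`, `"uneven"` or `"split"`) as
#' attributes.
#'
#' @param treatment Character scalar naming the treatment (e.g. `"6:2-even"`).
#' @param patches Named list; one element per patch, each an integer vector
#'   with names `A` and `B` giving the substrate counts of each resource
#'   type in that patch. Element names are the patch ids.
#' @param distribution One of `"even"`, `"uneven"`, `"split"`; descriptive
#'   label of how the resources are spread over patches.
#'
#' @return A tibble of class `experiment_design` with columns
#'   `patch_id`, `substrate_id`, `resource`.
#'
#' @examples
#' experiment_design(
#'   "6:2-uneven",
#'   patches = list(p1 = c(A = 4, B = 0), p2 = c(A = 2, B = 2)),
#'   distribution = "uneven"
#' )
#' @export
experiment_design <- function(treatment, patches,
                              distribution = c("even", "uneven", "split")) {
  distribution <- match.arg(distribution)
  if (!is.character(treatment) || length(treatment) != 1L || is.na(treatment)) {
    abort("`treatment` must be a single non-missing string.")
  }
  if (!is.list(patches) || length(patches) < 1L || is.null(names(patches)) ||
      anyDuplicated(names(patches)) || any(!nzchar(names(patches)))) {
    abort("`patches` must be a non-empty list with unique non-empty names.")
  }
  rows <- purrr::imap(patches, function(comp, pid) {
    n_a <- as.integer(if ("A" %in% names(comp)) comp[["A"]] else 0L)
    n_b <- as.integer(if ("B" %in% names(comp)) comp[["B"]] else 0L)
    if (is.na(n_a) || is.na(n_b) || n_a < 0L || n_b < 0L) {
      abort(sprintf("Patch '%s': substrate counts must be non-negative integers.", pid))
    }
    if (n_a + n_b < 1L) {
      abort(sprintf("Patch '%s' is empty: every patch needs at least one substrate.", pid))
    }
    resource <- c(rep("A", n_a), rep("B", n_b))
    tibble::tibble(
      patch_id = pid,
      substrate_id = sprintf("%s_s%d", pid, seq_along(resource)),
      resource = resource
    )
  })
  out <- dplyr::bind_rows(rows)
  ratio <- c(A = sum(out$resource == "A"), B = sum(out$resource == "B"))
  structure(
    out,
    treatment = treatment,
    ratio = ratio,
    distribution = distribution,
    class = c("experiment_design", class(tibble::tibble()))
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf(
    "<experiment_design> %s (%d:%d A:B, %s; %d patches, %d substrates)\n",
    design_treatment(x), design_ratio(x)[["A"]], design_ratio(x)[["B"]],
    attr(x, "distribution"), dplyr::n_distinct(x$patch_id), nrow(x)
  ))
  NextMethod()
}

#' Design metadata accessors
#'
#' @param design An [experiment_design()].
#' @return `design_treatment()` the treatment label; `design_ratio()` a named
#'   integer vector `c(A = , B = )` of substrate totals.
#' @export
design_treatment <- function(design) attr(design, "treatment")

#' @rdname design_treatment
#' @export
design_ratio <- function(design) attr(design, "ratio")

#' Per-patch resource composition of a design
#'
#' @param design An [experiment_design()].
#' @return Tibble with one row per patch: `patch_id`, `n_a`, `n_b`, in the
#'   design's patch order.
#' @export
design_composition <- function(design) {
  design |>
    dplyr::mutate(patch_id = factor(.data$patch_id, levels = unique(.data$patch_id))) |>
    dplyr::group_by(.data$patch_id) |>
    dplyr::summarise(
      n_a = sum(.data$resource == "A"),
      n_b = sum(.data$resource == "B"),
      .groups = "drop"
    ) |>
    dplyr::mutate(patch_id = as.character(.data$patch_id))
}

#' The seven canonical two-patch treatments
#'
#' Returns the built-in designs of the assay the package emulates: overall
#' apple:banana ratios 6:2, 4:4 and 2:6, each as an "even" arrangement (both
#' patches identical) and an "uneven" one (the majority resource concentrated
#' in one patch, the other patch holding the remainder), plus a seventh
#' 4:4 "split" treatment whose patches hold 3:1 and 1:3 within-patch ratios.
#' Every design has 2 patches of 4 substrates each.
#'
#' @return Named list of seven [experiment_design()] objects; names are the
#'   treatment labels.
#' @examples
#' names(standard_designs())
#' design_composition(standard_designs()[["6:2-uneven"]])
#' @export
standard_designs <- function() {
  specs <- list(
    "6:2-even"   = list(list(p1 = c(A = 3, B = 1), p2 = c(A = 3, B = 1)), "even"),
    "6:2-uneven" = list(list(p1 = c(A = 4, B = 0), p2 = c(A = 2, B = 2)), "uneven"),
    "4:4-even"   = list(list(p1 = c(A = 2, B = 2), p2 = c(A = 2, B = 2)), "even"),
    "4:4-uneven" = list(list(p1 = c(A = 4, B = 0), p2 = c(A = 0, B = 4)), "uneven"),
    "4:4-split"  = list(list(p1 = c(A = 3, B = 1), p2 = c(A = 1, B = 3)), "split"),
    "2:6-even"   = list(list(p1 = c(A = 1, B = 3), p2 = c(A = 1, B = 3)), "even"),
    "2:6-uneven" = list(list(p1 = c(A = 0, B = 4), p2 = c(A = 2, B = 2)), "uneven")
  )
  purrr::imap(specs, function(s, nm) {
    experiment_design(nm, patches = s[[1]], distribution = s[[2]])
  })
}

#' Read and write design registries as plain-text YAML
#'
#' One YAML document holds a named registry of treatments; each treatment
#' lists its distribution kind and, per patch, the substrate counts of each
#' resource type.
#'
#' @param path File path.
#' @param designs Named list of [experiment_design()] objects.
#' @return `read_designs()` a named list of designs; `write_designs()` the
#'   path, invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_designs(standard_designs(), f)
#' identical(names(read_designs(f)), names(standard_designs()))
#' @export
read_designs <- function(path) {
  if (!file.exists(path)) abort(sprintf("Design file not found: '%s'", path))
  raw <- yaml::read_yaml(path)
  if (!is.list(raw) || is.null(names(raw))) {
    abort("Design file must map treatment names to patch descriptions.")
  }
  purrr::imap(raw, function(entry, nm) {
    if (!all(c("distribution", "patches") %in% names(entry))) {
      abort(sprintf("Treatment '%s': needs 'distribution' and 'patches' keys.", nm))
    }
    patches <- purrr::map(entry$patches, function(p) {
      c(A = as.integer(p[["A"]] %||% 0L), B = as.integer(p[["B"]] %||% 0L))
    })
    experiment_design(nm, patches = patches, distribution = entry$distribution)
  })
}

#' @rdname read_designs
#' @export
write_designs <- function(designs, path) {
  designs <- check_design_registry(designs)
  doc <- purrr::map(designs, function(d) {
    comp <- design_composition(d)
    list(
      distribution = attr(d, "distribution"),
      patches = setNames(
        purrr::map2(comp$n_a, comp$n_b, ~ list(A = .x, B = .y)),
        comp$patch_id
      )
    )
  })
  yaml::write_yaml(doc, path)
  invisible(path)
}

# Validate a design registry: a named list of experiment_design objects.
check_design_registry <- function(designs) {
  if (inherits(designs, "experiment_design")) {
    designs <- setNames(list(designs), design_treatment(designs))
  }
  if (!is.list(designs) || length(designs) == 0L ||
      !all(purrr::map_lgl(designs, inherits, "experiment_design"))) {
    abort("`designs` must be a named list of experiment_design objects.")
  }
  if (is.null(names(designs)) || anyDuplicated(names(designs))) {
    abort("`designs` must have unique names (the treatment labels).")
  }
  designs
}
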