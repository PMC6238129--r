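# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# A dataset with the given egg count on every substrate of each treatment,
# replicated `n_rep` times (all replicates identical).
constant_dataset <- function(per_substrate, designs, n_rep = 1,
                             strain = "wt") {
  purrr::imap_dfr(designs, function(d, trt) {
    purrr::map_dfr(seq_len(n_rep), function(r) {
      eggs <- if (is.function(per_substrate)) {
        vapply(seq_len(nrow(d)), function(i) per_substrate(d$resource[i]), numeric(1))
      } else {
        rep(per_substrate, nrow(d))
      }
      tibble::tibble(
        replicate_id = sprintf("%s_r%d", trt, r),
        strain = strain,
        treatment = trt,
        patch_id = d$patch_id,
        substrate_id = d$substrate_id,
        resource = d$resource,
        eggs = as.integer(eggs)
      )
    })
  })
}

# One replicate of a single design with named per-substrate counts
# (unnamed substrates get zero eggs).
one_replicate <- function(design, counts, treatment = design_treatment(design),
                          replicate_id = "r1", strain = "wt") {
  eggs <- integer(nrow(design))
  eggs[match(names(counts), design$substrate_id)] <- as.integer(counts)
  tibble::tibble(
    replicate_id = replicate_id,
    strain = strain,
    treatment = treatment,
    patch_id = design$patch_id,
    substrate_id = design$substrate_id,
    resource = design$resource,
    eggs = eggs
  )
}

# Random valid design: 1-3 patches, 1-4 substrates each, both resource
# types present somewhere (so no boundary parameter is degenerate).
random_design <- function(label = "rand") {
  repeat {
    n_patch <- sample(1:3, 1)
    patches <- lapply(seq_len(n_patch), function(j) {
      repeat {
        comp <- c(A = sample(0:4, 1), B = sample(0:4, 1))
        if (sum(comp) >= 1) return(comp)
      }
    })
    names(patches) <- paste0("p", seq_len(n_patch))
    tot <- Reduce(`+`, patches)
    if (tot[["A"]] >= 1 && tot[["B"]] >= 1) {
      return(experiment_design(label, patches, distribution = "even"))
    }
  }
}

# Swap the resource labels of a design, preserving patch structure.
mirror_design <- function(design) {
  comp <- design_composition(design)
  patches <- setNames(
    purrr::map2(comp$n_b, comp$n_a, ~ c(A = .x, B = .y)),
    comp$patch_id
  )
  experiment_design(design_treatment(design), patches,
                    distribution = attr(design, "distribution"))
}

# Swap resource labels in a dataset generated from `designs`, remapping each
# substrate onto the mirrored design's substrate ids (A substrates map onto
# the mirror's B substrates in patch order, and vice versa).
mirror_dataset <- function(data, designs) {
  mirrored <- lapply(designs, mirror_design)
  out <- purrr::map_dfr(unique(data$treatment), function(trt) {
    d <- designs[[trt]]
    m <- mirrored[[trt]]
    map_ids <- character(nrow(d))
    for (p in unique(d$patch_id)) {
      for (res in c("A", "B")) {
        from <- which(d$patch_id == p & d$resource == res)
        to <- which(m$patch_id == p & m$resource == setdiff(c("A", "B"), res))
        map_ids[from] <- m$substrate_id[to]
      }
    }
    sub <- data[data$treatment == trt, ]
    i <- match(sub$substrate_id, d$substrate_id)
    sub$substrate_id <- map_ids[i]
    sub$resource <- ifelse(d$resource[i] == "A", "B", "A")
    sub$patch_id <- d$patch_id[i]
    sub
  })
  list(data = out, designs = mirrored)
}
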