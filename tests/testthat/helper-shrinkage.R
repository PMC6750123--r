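# library of 4 coarse phantoms: entries 1 and 2 share an anatomy (near
# duplicates under slightly different poses), entries 3 and 4 are distinct
make_four_phantom_library <- function() {
  spec <- coarse_spec(noise_sigma = 0, bias_field_amplitude = 0)
  seeds <- c(101, 101, 202, 303)
  poses <- list(c(2, -1, 3, 4, -3, 2, 1.02, 0.98, 1.0, 0.01, 0, 0),
                c(-1, 2, -2, -3, 2, 4, 0.99, 1.03, 0.98, 0, 0.01, 0),
                c(4, 3, -5, 6, 5, -3, 1.05, 0.95, 1.02, -0.02, 0, 0.01),
                c(-3, -4, 6, -5, -2, 5, 0.96, 1.04, 1.03, 0.01, -0.01, 0))
  template <- make_canonical_brain(1, spec)
  entries <- lapply(1:4, function(i) {
    p <- perturb(make_canonical_brain(seeds[i], spec), poses[[i]],
                 fov = "sagittal")
    id <- paste0("m", i)
    mediator_entry(id, p$volume,
                   affine_transform(matrix = p$true_to_canonical$matrix,
                                    from_space = id, to_space = "template"),
                   mask = p$brain_mask)
  })
  mediator_library(template$volume, template$brain_mask, entries, "template")
}

# exhaustive complete-linkage oracle: enumerate every partition of the ids
# into exactly k non-empty clusters and pick the one minimizing the largest
# within-cluster dissimilarity
oracle_best_partition <- function(values, k) {
  n <- nrow(values)
  parts <- list()
  assign_next <- function(labels, i, used) {
    if (i > n) {
      if (used == k) parts[[length(parts) + 1L]] <<- labels
      return(invisible())
    }
    for (g in seq_len(min(used + 1L, k)))
      assign_next(c(labels, g), i + 1L, max(used, g))
  }
  assign_next(integer(), 1L, 0L)
  score <- vapply(parts, function(lab) {
    worst <- 0
    for (g in unique(lab)) {
      m <- which(lab == g)
      if (length(m) > 1) worst <- max(worst, max(values[m, m]))
    }
    worst
  }, numeric(1))
  parts[[which.min(score)]]
}
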