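# Small fixtures shared across test files; everything built in code.

# a 1-element foundation: closed-form invertible single spring
single_spring_geometry <- function(spacing = 2) {
  knee_geometry(mesh_nx_ap = 1, mesh_ny_ml = 1, element_spacing = spacing,
                meniscus_coverage = 0)
}

# cohort config with all feature SDs (and body-mass SD) set to zero
flat_cohort_config <- function(...) {
  sds <- default_condition_sds()
  sds[, ] <- 0
  cohort_config(condition_sds = sds, body_mass_sd_kg = 0, ...)
}

# config with every condition set to the neutral row (null condition effect)
null_cohort_config <- function(seed) {
  means <- default_condition_means()
  means[, ] <- means[rep("neutral", 4), ]
  sds <- default_condition_sds()
  sds[, ] <- sds[rep("neutral", 4), ]
  cohort_config(condition_means = means, condition_sds = sds, seed = seed)
}
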