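#!/usr/bin/env Rscript

# Stage 1: generate a study-like synthetic dataset (139 whales, 2016-2023,
# with the field study's sampling sparsity and missingness) and archive it
# with its generating truth under results/run1/.

library(whalehealth)

seed <- 1L
out <- "results/run1"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sim <- make_study_like_dataset(seed = seed)
write_dataset(sim$dataset, file.path(out, "data"))
truth <- sim$truth
truth$h <- NULL; truth$s <- NULL; truth$Ltrue <- NULL  # large latent arrays
jsonlite::write_json(truth, file.path(out, "truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

ds <- sim$dataset
cat("Simulated cohort:", nrow(ds$individuals), "individuals over",
    length(ds$config$years), "years\n")
cat("  BAI measurements:   ", nrow(ds$bai), "\n")
cat("  faecal samples:     ", nrow(ds$fgc), "in",
    length(unique(ds$fgc$individual_id)), "individuals\n")
cat("  calving events:     ", sum(sim$truth$c), "true;",
    sum(ds$sightings$calf_observed), "seen in the study area;",
    sum(ds$sightings$calf_reported_elsewhere), "reported elsewhere;",
    sim$truth$n_missed, "unobserved\n")
cat("  sex unknown:        ", round(100 * mean(ds$individuals$sex == "unknown")), "%\n")
cat("  age known:          ", round(100 * mean(ds$individuals$known_age)), "%\n")
cat("Dataset written to", file.path(out, "data"), "\n")
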