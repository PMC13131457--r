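#!/usr/bin/env Rscript

# Step 2 — per-soma EV punctum quantification on a simulated 500-soma cohort
# (50 fields x 10 somata) drawn from the zero-inflated count model: 67% of
# cells positive, overall mean 4.2 puncta per cell. The pipeline detects
# somata from the marker channel, segments puncta, assigns them by centroid,
# and reports counts, densities, and the count/density vs soma-area
# correlations. The recovered mean and positive fraction should sit within
# sampling error of the generator's parameters.

suppressMessages(library(evquant))

fields <- lapply(1:50, function(i) generate_soma_field(soma_field_spec(seed = 1000 + i)))
truth <- unlist(lapply(fields, function(f) f$soma_truth$true_count))

cfg <- run_config(pixel_size_nm = 200, seed = 1, output_dir = "results/soma")
res <- run_soma_pipeline(fields, cfg)

cat(sprintf("cohort: %d somata over %d images\n", res$n_somata, length(fields)))
cat(sprintf("true mean count  %.3f | recovered %.3f +/- %.3f (SEM)\n",
            mean(truth), res$mean_count, res$sem_count))
cat(sprintf("true positive %%  %.1f | recovered %.1f\n",
            100 * mean(truth > 0), 100 * res$fraction_of_somata_with_particles))
cv <- res$correlations$count_vs_area
dv <- res$correlations$density_vs_area
cat(sprintf("count    vs soma area: r = %+.3f, p = %.3g\n", cv$r, cv$p_two_sided))
cat(sprintf("density  vs soma area: r = %+.3f, p = %.3g\n", dv$r, dv$p_two_sided))
cat("Note: the generator draws counts independently of soma area, so the\n")
cat("count-area correlation sits near zero and the density-area correlation\n")
cat("is mechanically negative (density = count / area). Size-proportional\n")
cat("uptake would show the opposite signature: positive count-area, flat\n")
cat("density-area.\n")
cat("artifacts: results/soma/per_soma.csv, soma_summary.json, run_log.jsonl\n")
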