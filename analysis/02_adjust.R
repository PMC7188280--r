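#!/usr/bin/env Rscript
# Step 2 — augmented-design adjustment of plot yields.
#
# For every population: per-environment BLUEs (fixed-effect ACBD model) and
# combined-environment BLUPs with REML variance components, from which the
# broad-sense heritability H2 = sigma_g2 / (sigma_g2 + sigma_e2) is taken.
# Writes adjusted-value TSVs (plus variance components) under
# results/adjusted/.

library(breedgain)

ind <- "results/data"
out <- "results/adjusted"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (pop in c("amp", "dh_pop", "f5_pop")) {
  fb <- read_fieldbook_csv(file.path(ind, paste0(pop, "_fieldbook.csv")))
  for (e in unique(fb$environment)) {
    blue <- adjust_single_env(fb, e)
    write_adjusted_tsv(blue, file.path(out, sprintf("%s_blue_%s.tsv", pop, e)))
  }
  blup <- adjust_multi_env(fb)
  write_adjusted_tsv(blup, file.path(out, sprintf("%s_blup.tsv", pop)))
  cat(sprintf("%s: sigma_g2 = %.3f, sigma_e2 = %.3f, H2 = %.3f\n", pop,
              blup$varcomp["sigma_g2"], blup$varcomp["sigma_e2"],
              estimate_h2(blup)))
}
cat("wrote", out, "\n")
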