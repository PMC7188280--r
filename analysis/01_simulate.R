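#!/usr/bin/env Rscript
# Step 1 — simulate the study populations.
#
# Builds the synthetic analogue of the study design: a diverse 456-line
# training panel genotyped at 2000 SNPs and trialled in two environments
# with modest genetic correlation (strong G-by-E), plus two biparental
# progeny populations (a DH population calibrated to plot H2 ~ 0.56 and an
# F5 population at H2 ~ 0.13) grown in the same two environments.  Writes
# genotype and field-book CSVs under results/data/.

library(breedgain)

seed <- 1
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

amp_cfg <- sim_config(n_lines = 456, n_markers = 2000, n_qtl = 30,
                      h2_target = 0.5, environments = c("ENV1", "ENV2"),
                      gxe_corr = 0.3, seed = seed)
amp <- simulate_founders(amp_cfg)
amp_trial <- simulate_trial(amp, amp_cfg)
write_genotype_csv(amp, file.path(out, "amp_geno.csv"))
write_fieldbook_csv(amp_trial$fieldbook, file.path(out, "amp_fieldbook.csv"))
cat(sprintf("AMP: %d lines x %d markers; realized plot H2 = %.2f / %.2f\n",
            nrow(amp$dosage), ncol(amp$dosage),
            amp_trial$truth$realized_h2[1], amp_trial$truth$realized_h2[2]))

pops <- list(list(name = "DH_POP", type = "DH", n = 500, h2 = 0.56),
             list(name = "F5_POP", type = "F5", n = 500, h2 = 0.13))
set.seed(seed)
for (p in pops) {
  parents <- sample(rownames(amp$dosage), 2)
  prog <- derive_biparental(geno_subset(amp, lines = parents), p$n,
                            pop_type = p$type, seed = seed, prefix = p$name)
  cfg <- amp_cfg
  cfg$n_lines <- p$n
  cfg$h2_target <- p$h2
  trial <- simulate_trial(prog, cfg, seed = seed + match(p$name, sapply(pops, `[[`, "name")))
  write_genotype_csv(prog, file.path(out, paste0(tolower(p$name), "_geno.csv")))
  write_fieldbook_csv(trial$fieldbook,
                      file.path(out, paste0(tolower(p$name), "_fieldbook.csv")))
  cat(sprintf("%s (%s x %s): %d lines, target plot H2 = %.2f\n",
              p$name, parents[1], parents[2], p$n, p$h2))
}
cat("wrote", out, "\n")
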