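#!/usr/bin/env Rscript
# Step 4 — genomic prediction of the breeding populations.
#
# Trains RRBLUP on each adjusted panel dataset and predicts GEBVs for the DH
# and F5 progeny under the standard scenario (GS1) and with the top GWAS
# markers as fixed effects (GS2).  Also runs the five-fold cross-validation
# of the panel itself.  Writes GEBV TSVs and predictive abilities under
# results/prediction/.

library(breedgain)

ind <- "results/data"
adj <- "results/adjusted"
gws <- "results/gwas"
out <- "results/prediction"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

amp <- read_genotype_csv(file.path(ind, "amp_geno.csv"))
read_adj <- function(f) {
  d <- read.delim(f)
  setNames(d$adjusted_value, d$line_id)
}
datasets <- list(ENV1 = read_adj(file.path(adj, "amp_blue_ENV1.tsv")),
                 ENV2 = read_adj(file.path(adj, "amp_blue_ENV2.tsv")),
                 COMBINED = read_adj(file.path(adj, "amp_blup.tsv")))
top_file <- file.path(gws, "top_snps.tsv")
fixed <- if (file.exists(top_file)) read.delim(top_file)$marker else character()

cv <- cross_validate(amp, datasets$COMBINED, folds = 5, seed = 1)
cat(sprintf("panel 5-fold CV predictive ability: %.3f (per fold: %s)\n",
            cv$mean_r, paste(sprintf("%.2f", cv$fold_r), collapse = " ")))

pa_rows <- list()
for (pop in c("dh_pop", "f5_pop")) {
  prog <- read_genotype_csv(file.path(ind, paste0(pop, "_geno.csv")))
  obs <- read_adj(file.path(adj, sprintf("%s_blue_ENV1.tsv", pop)))
  obs <- obs[names(obs) %in% rownames(prog$dosage)]
  gebv_all <- list()
  for (nm in names(datasets)) {
    for (scen in c("GS1", "GS2")) {
      fm <- if (scen == "GS2" && length(fixed) > 0) fixed else NULL
      if (scen == "GS2" && is.null(fm)) next
      fit <- fit_rrblup(amp, datasets[[nm]], fixed_markers = fm)
      pr <- predict_gebv(fit, prog)
      pr$training <- nm
      gebv_all[[paste(nm, scen)]] <- pr
      pa <- predictive_ability(pr, obs)
      pa_rows[[length(pa_rows) + 1]] <- data.frame(
        population = pop, training = nm, scenario = scen, r = pa$r, n = pa$n)
    }
  }
  write.table(do.call(rbind, gebv_all),
              file.path(out, paste0("gebv_", pop, ".tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
}
pa <- do.call(rbind, pa_rows)
write.table(pa, file.path(out, "predictive_ability.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("predictive abilities (GEBV vs adjusted yield, selection environment):\n")
print(pa)
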