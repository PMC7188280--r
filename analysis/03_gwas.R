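#!/usr/bin/env Rscript
# Step 3 — relatedness and marker-trait association on the training panel.
#
# Computes the VanRaden kinship matrix, Rogers genetic distances between the
# panel and each progeny population (overall, per chromosome, and averaged
# over line pairs), runs the kinship-corrected single-marker scan on every
# adjusted yield dataset with BH-FDR control at 0.05, picks the top five
# markers across datasets, and reports their drop-one variance explained.
# Writes TSVs under results/gwas/.

library(breedgain)

ind <- "results/data"
adj <- "results/adjusted"
out <- "results/gwas"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

amp <- read_genotype_csv(file.path(ind, "amp_geno.csv"))
K <- compute_kinship(amp)
write_relatedness_tsv(K, file.path(out, "kinship.tsv"))

for (pop in c("dh_pop", "f5_pop")) {
  prog <- read_genotype_csv(file.path(ind, paste0(pop, "_geno.csv")))
  ov <- rogers_distance(amp, prog)
  pc <- rogers_distance(amp, prog, scope = "chromosome")
  lp <- rogers_distance(amp, prog, scope = "line_pair")
  write_relatedness_tsv(rbind(ov, pc, lp),
                        file.path(out, paste0("rogers_", pop, ".tsv")))
  cat(sprintf("Rogers distance AMP vs %s: %.3f overall, %.3f line-pair mean\n",
              pop, ov$distance, lp$distance))
}

read_adj <- function(f) {
  d <- read.delim(f)
  setNames(d$adjusted_value, d$line_id)
}
datasets <- list(ENV1 = read_adj(file.path(adj, "amp_blue_ENV1.tsv")),
                 ENV2 = read_adj(file.path(adj, "amp_blue_ENV2.tsv")),
                 COMBINED = read_adj(file.path(adj, "amp_blup.tsv")))
eig <- eigen(unclass(K), symmetric = TRUE)
gwas <- list()
for (nm in names(datasets)) {
  gwas[[nm]] <- run_mlm_gwas(amp, datasets[[nm]], K = K, eig = eig,
                             dataset = nm)
  write_gwas_tsv(gwas[[nm]], file.path(out, paste0("gwas_", nm, ".tsv")))
  cat(sprintf("GWAS %s: %d significant markers (q <= 0.05)\n", nm,
              sum(gwas[[nm]]$significant)))
}

top <- select_top_snps(gwas, k = 5)
if (nrow(top) > 0) {
  r2 <- snp_variance_explained(amp, datasets[[top$dataset[1]]], top$marker)
  top$r2 <- r2$r2[match(top$marker, r2$marker)]
  write.table(top, file.path(out, "top_snps.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  cat("top markers across datasets:\n")
  print(top)
} else {
  cat("no significant marker-trait associations in this realization\n")
}
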