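#!/usr/bin/env Rscript
# Step 5 — selection strategies and response to selection.
#
# Applies the four truncation-selection strategies to each progeny
# population: PS (top 20% by adjusted yield in the selection environment),
# MS (homozygous favorable alleles at the top GWAS markers), GS1/GS2 (top
# 20% by GEBV per training dataset), and PS+GS (intersection).  Scores every
# strategy by R = H2 * S, both within the selection environment and
# validated in the second environment, and runs paired t-tests between the
# GEBV-based strategies.  Writes results/response/.

library(breedgain)

ind <- "results/data"
adj <- "results/adjusted"
gws <- "results/gwas"
prd <- "results/prediction"
out <- "results/response"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

read_adj <- function(f) {
  d <- read.delim(f)
  setNames(d$adjusted_value, d$line_id)
}
top_file <- file.path(gws, "top_snps.tsv")
top <- if (file.exists(top_file)) read.delim(top_file) else
  data.frame(marker = character(), favorable_dosage = numeric())

rows <- list()
for (pop in c("dh_pop", "f5_pop")) {
  prog <- read_genotype_csv(file.path(ind, paste0(pop, "_geno.csv")))
  sel_env <- read_adj(file.path(adj, sprintf("%s_blue_ENV1.tsv", pop)))
  val_env <- read_adj(file.path(adj, sprintf("%s_blue_ENV2.tsv", pop)))
  sel_env <- sel_env[names(sel_env) %in% rownames(prog$dosage)]
  val_env <- val_env[names(val_env) %in% rownames(prog$dosage)]
  vc <- read.delim(file.path(adj, sprintf("%s_blup.tsv.varcomp.tsv", pop)))
  h2 <- estimate_h2(setNames(vc$value, vc$component))

  ps <- select_top_fraction(sel_env, 0.20)
  ms <- if (nrow(top) > 0) marker_select(prog, top) else character()
  sets <- list(PS = ps, MS = ms)
  gebv <- read.delim(file.path(prd, paste0("gebv_", pop, ".tsv")))
  for (nm in unique(gebv$training)) {
    for (scen in unique(gebv$scenario)) {
      gg <- gebv[gebv$training == nm & gebv$scenario == scen, ]
      if (nrow(gg) == 0) next
      gs <- select_top_fraction(setNames(gg$gebv, gg$line_id), 0.20)
      sets[[paste0(scen, ".", nm)]] <- gs
      sets[[paste0("PS+", scen, ".", nm)]] <- combine_ps_gs(ps, gs)
    }
  }
  for (snm in names(sets)) {
    strat <- sub("\\..*$", "", snm)
    train <- if (grepl("\\.", snm)) sub("^[^.]*\\.", "", snm) else NA
    for (ev in c("within", "cross")) {
      ep <- if (ev == "within") sel_env else val_env
      row <- response_report_row(pop, ev, sets[[snm]], ep, h2, strat)
      row$training <- train
      rows[[length(rows) + 1]] <- row
    }
  }
}
resp <- do.call(rbind, rows)
write.table(resp, file.path(out, "response.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("mean response to selection by strategy:\n")
print(aggregate(R ~ strategy + validation, resp, mean,
                na.rm = TRUE, na.action = NULL))

gsr <- resp[resp$validation == "within" & grepl("GS", resp$strategy), ]
rmat <- tapply(gsr$R, list(gsr$strategy, paste(gsr$population, gsr$training)),
               mean)
cmp <- tryCatch(compare_strategies(rmat), error = function(e) NULL)
if (!is.null(cmp)) {
  write.table(cmp, file.path(out, "strategy_ttests.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  cat("paired t-tests between GEBV-based strategies (within environment):\n")
  print(cmp)
}
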