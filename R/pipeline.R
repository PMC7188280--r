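## End-to-end study pipeline on synthetic (or ingested) data:
## simulate -> ACBD adjustment -> GWAS on the training panel -> RRBLUP
## prediction of biparental progeny (GS1/GS2) -> selection (PS/MS/GS/PS+GS)
## -> response to selection within the selection environment and in a
## validation environment.

#' Study run configuration
#'
#' @param amp \code{\link{sim_config}} for the association-mapping-panel
#'   analogue (training population).
#' @param populations list of progeny population definitions, each a list
#'   with \code{name}, \code{type} ("DH"/"F5"), \code{n} and \code{h2}.
#' @param selection_fraction truncation fraction q (default 0.20).
#' @param fdr_threshold GWAS significance threshold (default 0.05).
#' @param k_fixed number of GWAS-derived fixed-effect markers for GS2/MS
#'   (default 5).
#' @param folds cross-validation folds on the training panel (default 5).
#' @param include_cv run the training-panel cross-validation (default TRUE).
#' @param seed master seed; mandatory for simulated runs.
#' @param out_dir optional directory for TSV outputs.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(amp = sim_config(n_lines = 456, n_markers = 2000,
                                        n_qtl = 30, h2_target = 0.5,
                                        environments = c("ENV1", "ENV2"),
                                        gxe_corr = 0.3, seed = seed),
                       populations = list(
                         list(name = "DH_POP", type = "DH", n = 500, h2 = 0.56),
                         list(name = "F5_POP", type = "F5", n = 500, h2 = 0.13)),
                       selection_fraction = 0.20, fdr_threshold = 0.05,
                       k_fixed = 5, folds = 5, include_cv = TRUE,
                       seed, out_dir = NULL) {
  if (missing(seed)) stop("seed is mandatory for simulated runs")
  force(amp)
  stopifnot(selection_fraction > 0, selection_fraction <= 1,
            fdr_threshold > 0, fdr_threshold <= 1, k_fixed >= 0)
  structure(list(amp = amp, populations = populations,
                 selection_fraction = selection_fraction,
                 fdr_threshold = fdr_threshold, k_fixed = k_fixed,
                 folds = folds, include_cv = include_cv,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

config_hash <- function(config) {
  ## stable content hash of the scientific configuration (output location
  ## excluded: it must not change the hash stamped into result tables)
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  s <- paste(utils::capture.output(utils::str(cfg)), collapse = "\n")
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% 1e9
}

#' Run the full selection-strategy comparison study
#'
#' Simulates a training panel and its multi-environment ACBD trial, adjusts
#' yields (per-environment BLUEs + combined BLUPs), scans the panel for
#' marker-trait associations, derives biparental progeny populations,
#' predicts their GEBVs with RRBLUP trained on each panel dataset (GS1 and
#' GWAS-assisted GS2), applies PS / MS / GS / PS+GS truncation selection in
#' the first environment, and scores every strategy by R = H^2 * S both in
#' the selection environment and in the second (validation) environment.
#'
#' @param config a \code{\link{run_config}}.
#' @return list of class \code{study_report}: \code{response} (long
#'   response-to-selection table), \code{gwas} (per-dataset results),
#'   \code{top_snps}, \code{predictive_ability}, \code{strategy_means},
#'   \code{comparisons} (paired t-tests, within-environment),
#'   \code{cv} (training-panel cross-validation), \code{h2} (per-population
#'   heritabilities), \code{truth}, plus \code{seed} and \code{config_hash}
#'   attributes.  With \code{out_dir} set, all tables are also written as
#'   TSV.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  seeds <- split_seed(config$seed, 6 + 2 * length(config$populations))
  envs <- config$amp$environments
  if (length(envs) < 2) stop("the study design needs >= 2 environments")
  sel_env <- envs[1]; val_env <- envs[2]
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))

  ## --- training panel ----------------------------------------------------
  amp_cfg <- config$amp; amp_cfg$seed <- seeds[1]
  amp <- simulate_founders(amp_cfg)
  amp_trial <- simulate_trial(amp, amp_cfg, seed = seeds[2])
  say("AMP: %d lines x %d markers", nrow(amp$dosage), ncol(amp$dosage))

  datasets <- list()
  for (e in envs)
    datasets[[e]] <- adjust_single_env(amp_trial$fieldbook, e)
  datasets[["COMBINED"]] <- adjust_multi_env(amp_trial$fieldbook)

  ## datasets whose adjusted values carry no signal (e.g. BLUPs fully
  ## shrunken to the grand mean at a zero genotypic-variance boundary) are
  ## excluded from GWAS and prediction training
  usable <- vapply(datasets, function(d)
    stats::sd(pheno_values(d)) > 1e-8, logical(1))
  for (nm in names(datasets)[!usable])
    say("dataset %s: adjusted values are constant; excluded from GWAS/GS", nm)
  datasets <- datasets[usable]
  if (length(datasets) == 0) stop("no usable adjusted dataset")

  ## --- GWAS on the panel (every dataset) ---------------------------------
  K <- compute_kinship(amp)
  K_eig <- eigen(unclass(K), symmetric = TRUE)
  gwas <- list()
  for (nm in names(datasets)) {
    gwas[[nm]] <- run_mlm_gwas(amp, datasets[[nm]], K = K, eig = K_eig,
                               q_threshold = config$fdr_threshold,
                               dataset = nm)
    say("GWAS %s: %d/%d markers significant at q<=%.2f (engine %s)", nm,
        sum(gwas[[nm]]$significant), nrow(gwas[[nm]]),
        config$fdr_threshold, attr(gwas[[nm]], "engine"))
  }
  top <- suppressWarnings(select_top_snps(gwas, k = config$k_fixed,
                                          q_threshold = config$fdr_threshold))
  say("top SNPs selected across datasets: %d", nrow(top))

  ## --- training-panel cross-validation -----------------------------------
  cv <- NULL
  if (isTRUE(config$include_cv) && "COMBINED" %in% names(datasets)) {
    cv <- cross_validate(amp, datasets[["COMBINED"]], folds = config$folds,
                         seed = seeds[3])
    say("AMP %d-fold CV mean predictive ability: %.3f", config$folds, cv$mean_r)
  }

  ## --- progeny populations ------------------------------------------------
  response <- list(); pa_rows <- list(); h2_pop <- c()
  truths <- list()
  for (pi in seq_along(config$populations)) {
    pop <- config$populations[[pi]]
    pseed <- seeds[4 + 2 * (pi - 1)]
    tseed <- seeds[5 + 2 * (pi - 1)]
    set.seed(pseed)
    par_ids <- sample(rownames(amp$dosage), 2)
    prog <- derive_biparental(geno_subset(amp, lines = par_ids), pop$n,
                              pop_type = pop$type, seed = pseed,
                              prefix = pop$name)
    pop_cfg <- config$amp
    pop_cfg$n_lines <- pop$n; pop_cfg$h2_target <- pop$h2
    pop_cfg$seed <- tseed
    trial <- simulate_trial(prog, pop_cfg, seed = tseed)
    truths[[pop$name]] <- trial$truth
    adj_sel <- adjust_single_env(trial$fieldbook, sel_env)
    adj_val <- adjust_single_env(trial$fieldbook, val_env)
    h2 <- estimate_h2(adjust_multi_env(trial$fieldbook))
    h2_pop[pop$name] <- h2
    say("%s (%s, n=%d): H2=%.3f (target %.2f)", pop$name, pop$type, pop$n,
        h2, pop$h2)

    ps_ids <- select_top_fraction(pheno_values(adj_sel),
                                  config$selection_fraction)
    ms_ids <- marker_select(prog, top)
    if (nrow(top) == 0) ms_ids <- character()  # no MTAs -> MS not applicable
    sel_sets <- list(PS = ps_ids, MS = ms_ids)

    for (train_nm in names(datasets)) {
      for (scen in c("GS1", "GS2")) {
        fm <- if (scen == "GS2" && nrow(top) > 0) top$marker else NULL
        if (scen == "GS2" && is.null(fm)) next
        fit <- suppressWarnings(fit_rrblup(amp, datasets[[train_nm]],
                                           fixed_markers = fm,
                                           K = K, eig = K_eig))
        pred <- predict_gebv(fit, prog)
        gs_ids <- select_top_fraction(
          stats::setNames(pred$gebv, pred$line_id), config$selection_fraction)
        pa <- predictive_ability(pred, adj_sel)
        pa_rows[[length(pa_rows) + 1]] <- data.frame(
          population = pop$name, training = train_nm, scenario = scen,
          r = pa$r, n = pa$n, stringsAsFactors = FALSE)
        sel_sets[[paste0(scen, ".", train_nm)]] <- gs_ids
        sel_sets[[paste0("PS+", scen, ".", train_nm)]] <-
          combine_ps_gs(ps_ids, gs_ids)
      }
    }

    for (snm in names(sel_sets)) {
      strat <- sub("\\..*$", "", snm)
      train_nm <- if (grepl("\\.", snm)) sub("^[^.]*\\.", "", snm) else NA
      ids <- sel_sets[[snm]]
      for (ev in c("within", "cross")) {
        ep <- if (ev == "within") adj_sel else adj_val
        row <- response_report_row(pop$name,
                                   if (ev == "within") sel_env else val_env,
                                   ids, ep, h2, strat)
        row$training <- train_nm
        row$evaluation <- ev
        response[[length(response) + 1]] <- row
      }
    }
  }
  response <- do.call(rbind, response)
  pa_tab <- do.call(rbind, pa_rows)

  ## --- summaries ----------------------------------------------------------
  strategy_means <- stats::aggregate(R ~ strategy + evaluation, response,
                                     mean, na.rm = TRUE, na.action = NULL)
  within <- response[response$evaluation == "within" &
                       response$strategy != "PS" &
                       response$strategy != "MS", ]
  rmat <- tapply(within$R, list(within$strategy,
                                paste(within$population, within$training)),
                 mean)
  comparisons <- tryCatch(compare_strategies(rmat), error = function(e) NULL)

  report <- structure(list(response = response, gwas = gwas, top_snps = top,
                           predictive_ability = pa_tab,
                           strategy_means = strategy_means,
                           comparisons = comparisons, cv = cv, h2 = h2_pop,
                           truth = truths, log = log,
                           seed = config$seed,
                           config_hash = config_hash(config)),
                      class = "study_report")
  if (!is.null(config$out_dir)) write_study_report(report, config$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report (seed", x$seed, ", config", x$config_hash, ")\n")
  cat("mean R by strategy and evaluation scope:\n")
  print(x$strategy_means)
  invisible(x)
}

#' Write all study-report tables as TSV
#' @param report a \code{study_report}.
#' @param out_dir output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- function(df) {
    df$seed <- report$seed; df$config_hash <- report$config_hash; df
  }
  w <- function(df, nm) utils::write.table(
    stamp(df), file.path(out_dir, nm), sep = "\t", row.names = FALSE,
    quote = FALSE)
  w(report$response, "response.tsv")
  w(do.call(rbind, report$gwas), "gwas.tsv")
  if (nrow(report$top_snps) > 0) w(report$top_snps, "top_snps.tsv")
  w(report$predictive_ability, "predictive_ability.tsv")
  w(report$strategy_means, "strategy_means.tsv")
  if (!is.null(report$comparisons)) w(report$comparisons, "comparisons.tsv")
  writeLines(report$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Ingest user-supplied genotype and phenotype tables
#'
#' Reads a genotype CSV (lines x markers, \code{line_id} column + one column
#' per marker ID in the "S1A_497083519" convention) and an adjusted-yield
#' CSV (columns \code{line_id}, \code{value}), validating marker IDs,
#' deduplicating repeated marker columns and reporting MAF / missingness
#' and per-chromosome tallies.
#'
#' @param geno_csv path to the genotype CSV.
#' @param pheno_csv optional path to an adjusted-phenotype CSV.
#' @return list: \code{geno} (\code{genotype_matrix}), \code{pheno} (named
#'   numeric or NULL), \code{report} (list: n_lines, n_markers,
#'   n_malformed_ids, maf summary, missingness, chromosome and genome
#'   tallies).
#' @export
ingest_supplementary <- function(geno_csv, pheno_csv = NULL) {
  geno <- read_genotype_csv(geno_csv)
  d <- geno$dosage
  parsed <- parse_marker_ids(colnames(d))
  bad <- !parsed$valid
  if (any(bad)) {
    warning(sum(bad), " malformed marker ID(s) quarantined")
    d <- d[, !bad, drop = FALSE]   # positional: names may be duplicated
  }
  if (anyDuplicated(colnames(d))) {
    warning("duplicated marker column(s) deduplicated")
    d <- d[, !duplicated(colnames(d)), drop = FALSE]
  }
  geno <- genotype_matrix(d)
  parsed <- parse_marker_ids(colnames(d))
  maf <- colMeans(geno$dosage, na.rm = TRUE) / 2
  maf <- pmin(maf, 1 - maf)
  report <- list(n_lines = nrow(geno$dosage), n_markers = ncol(geno$dosage),
                 n_malformed_ids = sum(bad),
                 maf = summary(maf),
                 missingness = mean(is.na(geno$dosage)),
                 chromosome_tally = table(parsed$chrom),
                 genome_tally = table(parsed$genome, useNA = "no"))
  pheno <- NULL
  if (!is.null(pheno_csv)) {
    pdf <- utils::read.csv(pheno_csv, stringsAsFactors = FALSE)
    if (!all(c("line_id", "value") %in% names(pdf)))
      stop("phenotype CSV must have columns line_id, value")
    if (!is.numeric(pdf$value)) stop("non-numeric phenotype values")
    pheno <- stats::setNames(pdf$value, pdf$line_id)
  }
  list(geno = geno, pheno = pheno, report = report)
}
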