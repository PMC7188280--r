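## Truncation-selection strategies and response-to-selection accounting.
##
## Strategies: PS (top fraction by adjusted yield), MS (favorable alleles at
## the top GWAS markers), GS1/GS2 (top fraction by GEBV without / with
## GWAS-derived fixed-effect markers), PS+GS (intersection of the PS and GS
## sets).  Gains are scored by the response to selection R = H^2 * S with
## S = mean(selected) - mean(unselected) on a declared evaluation set.

#' Select the top fraction of lines by score
#'
#' Keeps floor(q * N) lines (minimum 1) with the highest scores; ties break
#' lexicographically by line ID for determinism.
#'
#' @param values named numeric vector of per-line scores.
#' @param q selection fraction in (0, 1] (default 0.20).
#' @return character vector of selected line IDs.
#' @export
select_top_fraction <- function(values, q = 0.20) {
  if (length(values) == 0) stop("empty population")
  if (is.null(names(values))) stop("values must be named by line ID")
  if (q <= 0 || q > 1) stop("q must be in (0, 1]")
  n_sel <- max(1L, floor(q * length(values)))
  ord <- order(-values, names(values))
  names(values)[ord[seq_len(n_sel)]]
}

#' Marker-based selection on favorable alleles
#'
#' Selects the lines carrying the required favorable dosage at ALL listed
#' markers.  An empty result is a valid outcome (reported downstream as a
#' not-applicable response); an empty allele set selects every line
#' (vacuous condition).
#'
#' @param geno \code{\link{genotype_matrix}}.
#' @param alleles a \code{favorable_allele_set} (or data.frame with columns
#'   marker, favorable_dosage).
#' @return character vector of selected line IDs (possibly empty).
#' @export
marker_select <- function(geno, alleles) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (nrow(alleles) == 0) return(rownames(geno$dosage))
  if (!all(alleles$marker %in% colnames(geno$dosage)))
    stop("favorable-allele markers absent from genotype matrix")
  d <- geno$dosage[, alleles$marker, drop = FALSE]
  ok <- rowSums(sweep(d, 2, alleles$favorable_dosage, `==`)) == nrow(alleles)
  rownames(geno$dosage)[ok]
}

#' Combine phenotypic and genomic selections
#'
#' The PS+GS set is the intersection of the phenotypic top set and the
#' GEBV top set; it may be empty.
#'
#' @param ps_ids,gs_ids character vectors of line IDs.
#' @return sorted character vector (possibly empty).
#' @export
combine_ps_gs <- function(ps_ids, gs_ids) sort(intersect(ps_ids, gs_ids))

#' Selection differential
#'
#' S = mean(evaluation value of selected lines) - mean(evaluation value of
#' the whole population).  The evaluation phenotypes may come from the same
#' environment or from a validation environment.  An empty selection yields
#' NA (a not-applicable sentinel, not zero).
#'
#' @param selected_ids character vector of selected line IDs.
#' @param evaluation_pheno \code{adjusted_phenotypes} or named numeric
#'   covering the population.
#' @return S in t/ha, or NA if no line was selected or none of the selected
#'   lines has an evaluation phenotype.
#' @export
selection_differential <- function(selected_ids, evaluation_pheno) {
  v <- if (inherits(evaluation_pheno, "adjusted_phenotypes"))
    pheno_values(evaluation_pheno) else evaluation_pheno
  if (length(selected_ids) == 0) return(NA_real_)
  sel <- v[intersect(selected_ids, names(v))]
  if (length(sel) == 0) return(NA_real_)
  mean(sel) - mean(v)
}

#' Response to selection
#'
#' R = H^2 * S (broad-sense heritability times the selection differential).
#'
#' @param h2 broad-sense heritability in [0, 1].
#' @param S selection differential (t/ha); NA propagates.
#' @return R in t/ha.
#' @export
response_to_selection <- function(h2, S) {
  if (!is.na(h2) && (h2 < 0 || h2 > 1)) stop("H^2 must be in [0, 1]")
  h2 * S
}

#' Response relative to the check mean
#'
#' Same as \code{\link{selection_differential}} +
#' \code{\link{response_to_selection}}, with the unselected mean replaced by
#' the mean of the replicated check lines in the evaluation trial.
#'
#' @param selected_ids selected line IDs.
#' @param check_pheno named numeric of check phenotypes (>= 1 required).
#' @param evaluation_pheno \code{adjusted_phenotypes} or named numeric for
#'   the population.
#' @param h2 broad-sense heritability.
#' @return list: mu_selected, mu_checks, S, R.
#' @export
response_vs_checks <- function(selected_ids, check_pheno, evaluation_pheno,
                               h2) {
  if (length(check_pheno) == 0) stop("no check phenotypes in evaluation trial")
  v <- if (inherits(evaluation_pheno, "adjusted_phenotypes"))
    pheno_values(evaluation_pheno) else evaluation_pheno
  sel <- v[intersect(selected_ids, names(v))]
  S <- if (length(sel) == 0) NA_real_ else mean(sel) - mean(check_pheno)
  list(mu_selected = if (length(sel) == 0) NA_real_ else mean(sel),
       mu_checks = mean(check_pheno), S = S,
       R = response_to_selection(h2, S))
}

#' Paired comparison of strategy responses
#'
#' Paired t-tests between every pair of strategies over the shared
#' (population x training dataset) cells; cells where either strategy is
#' not applicable (NA) are dropped pairwise.  Degenerate difference vectors
#' are handled by convention: all-zero differences give p = 1 (t = 0);
#' constant non-zero differences give |t| = Inf with p = 0, flagged.
#'
#' @param r_matrix numeric matrix of R values, strategies in rows, dataset
#'   cells in columns (NA = not applicable).
#' @return data.frame: strategy_a, strategy_b, n_pairs, mean_diff, t, p,
#'   degenerate.
#' @export
compare_strategies <- function(r_matrix) {
  r_matrix <- as.matrix(r_matrix)
  if (nrow(r_matrix) < 2) stop("need >= 2 strategies")
  strat <- rownames(r_matrix)
  if (is.null(strat)) strat <- paste0("S", seq_len(nrow(r_matrix)))
  pairs <- utils::combn(seq_len(nrow(r_matrix)), 2)
  rows <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    ok <- !is.na(r_matrix[i1, ]) & !is.na(r_matrix[i2, ])
    diff <- r_matrix[i1, ok] - r_matrix[i2, ok]
    if (length(diff) < 2) stop("fewer than 2 complete pairs for ",
                               strat[i1], " vs ", strat[i2])
    if (stats::sd(diff) <= 1e-10 * max(abs(diff), 1)) {
      if (all(abs(diff) <= 1e-12)) {
        tt <- 0; pp <- 1
      } else {
        tt <- sign(mean(diff)) * Inf; pp <- 0
      }
      degen <- TRUE
    } else {
      ht <- stats::t.test(diff)
      tt <- unname(ht$statistic); pp <- ht$p.value; degen <- FALSE
    }
    rows[[j]] <- data.frame(strategy_a = strat[i1], strategy_b = strat[i2],
                            n_pairs = length(diff), mean_diff = mean(diff),
                            t = tt, p = pp, degenerate = degen,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble a response-report row
#'
#' One Table-2-style row: population, evaluation scope, means with and
#' without selection, S, H^2, R and the selected count.  R is reported at
#' full precision; round for display.
#'
#' @param population,validation labels.
#' @param selected_ids selected line IDs.
#' @param evaluation_pheno \code{adjusted_phenotypes} or named numeric.
#' @param h2 broad-sense heritability of the test population.
#' @param strategy strategy label.
#' @return one-row data.frame.
#' @export
response_report_row <- function(population, validation, selected_ids,
                                evaluation_pheno, h2, strategy) {
  v <- if (inherits(evaluation_pheno, "adjusted_phenotypes"))
    pheno_values(evaluation_pheno) else evaluation_pheno
  sel <- v[intersect(selected_ids, names(v))]
  S <- selection_differential(selected_ids, v)
  data.frame(population = population, validation = validation,
             strategy = strategy,
             mu_unselected = mean(v),
             mu_selected = if (length(sel) == 0) NA_real_ else mean(sel),
             S = S, H2 = h2, R = response_to_selection(h2, S),
             n_selected = length(sel), stringsAsFactors = FALSE)
}
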