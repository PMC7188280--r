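# Small programmatic fixtures shared across test files.

# A tiny genotype matrix with explicit dosages (inbred coding).
toy_geno <- function(dosage, markers = NULL, lines = NULL) {
  d <- as.matrix(dosage)
  if (is.null(markers)) markers <- sprintf("S1A_%d", seq_len(ncol(d)) * 1000)
  if (is.null(lines)) lines <- sprintf("L%02d", seq_len(nrow(d)))
  dimnames(d) <- list(lines, markers)
  genotype_matrix(d)
}

# Hand-built single-environment ACBD field book: `blocks` is a list of
# named yield vectors (names = line IDs); `checks` names the replicated
# check lines.
toy_fieldbook <- function(blocks, checks, env = "E1") {
  rows <- lapply(seq_along(blocks), function(b) {
    y <- blocks[[b]]
    data.frame(line_id = names(y), environment = env,
               block = sprintf("B%02d", b),
               is_check = names(y) %in% checks,
               yield_t_ha = as.numeric(y), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Default small simulation for pipeline-level tests.
small_cfg <- function(seed = 1, ...) {
  args <- list(n_lines = 80, n_markers = 200, n_qtl = 15, h2_target = 0.5,
               environments = c("E1", "E2"), gxe_corr = 0.3,
               block_size = 20, n_checks = 2, seed = seed)
  args[names(list(...))] <- list(...)
  if (is.null(args$n_chromosomes))
    args$n_chromosomes <- min(21, args$n_markers)
  args$n_qtl <- min(args$n_qtl, args$n_markers)
  do.call(sim_config, args)
}
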