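## Breeding-population and field-trial simulator.  Generates founder panels
## of inbred lines, F5 / doubled-haploid biparental progeny, and augmented
## complete block design (ACBD) multi-environment yield trials with known
## ground truth, so every downstream analysis stage can be validated against
## simulated truth.

wheat_chromosomes <- function(n = 21) {
  all <- paste0(rep(1:7, each = 3), c("A", "B", "D"))
  if (n > length(all)) paste0("C", seq_len(n)) else all[seq_len(n)]
}

## One master seed drives every stage; sub-seeds are drawn once so that
## identical seeds give identical output regardless of how many stages run.
split_seed <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic breeding-study generator.  Defaults
#' emulate the structure of a diverse winter-wheat association panel: 456
#' inbred lines, biallelic SNPs spread round-robin over the 21 wheat
#' chromosomes, unreplicated test lines plus replicated checks in ~40-plot
#' blocks, and two environments with modest genetic correlation (strong
#' genotype-by-environment interaction).
#'
#' @param n_lines number of (test) lines to simulate.
#' @param n_markers number of biallelic SNP markers.
#' @param n_chromosomes number of chromosomes (default 21, i.e. 1A-7D).
#' @param maf_range length-2 numeric in (0, 0.5]: minor allele frequencies
#'   are drawn uniformly within this range.
#' @param n_qtl number of causal loci (must be <= n_markers).
#' @param h2_target broad-sense plot heritability sigma_g^2 /
#'   (sigma_g^2 + sigma_e^2) the trial noise is calibrated to, in (0, 1].
#' @param environments character vector of environment labels.
#' @param gxe_corr genetic correlation of line values between environments,
#'   in [-1, 1]; low values mean strong genotype-by-environment interaction.
#' @param block_size plots per block (checks + unreplicated test plots).
#' @param n_checks number of replicated check lines per block.
#' @param mu trial grand mean in t/ha.
#' @param effect_sd standard deviation of per-QTL additive effects
#'   (t/ha per minor-allele copy) before noise calibration.
#' @param seed integer RNG seed; all randomness flows from it.
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(n_lines = 456, n_markers = 2000, n_chromosomes = 21,
                       maf_range = c(0.05, 0.5), n_qtl = 30, h2_target = 0.5,
                       environments = c("ENV1", "ENV2"), gxe_corr = 0.3,
                       block_size = 40, n_checks = 3, mu = 4.5,
                       effect_sd = 0.25, seed = 1) {
  cfg <- list(n_lines = as.integer(n_lines), n_markers = as.integer(n_markers),
              n_chromosomes = as.integer(n_chromosomes),
              maf_range = as.numeric(maf_range), n_qtl = as.integer(n_qtl),
              h2_target = h2_target, environments = as.character(environments),
              gxe_corr = gxe_corr, block_size = as.integer(block_size),
              n_checks = as.integer(n_checks), mu = mu, effect_sd = effect_sd,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_lines < 1) stop("n_lines must be >= 1")
    if (n_markers < n_chromosomes)
      stop("n_markers must be >= n_chromosomes")
    if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
        maf_range[1] > maf_range[2])
      stop("degenerate maf_range: need 0 < low <= high <= 0.5")
    if (n_qtl > n_markers) stop("n_qtl must be <= n_markers")
    if (h2_target < 0 || h2_target > 1) stop("h2_target must be in [0, 1]")
    if (abs(gxe_corr) > 1) stop("gxe_corr must be in [-1, 1]")
    if (block_size < n_checks + 1)
      stop("block_size must be >= n_checks + 1 (each block needs a test plot)")
    if (length(environments) < 1) stop("at least one environment required")
  })
  invisible(cfg)
}

#' Simulate a founder panel of inbred lines
#'
#' Generates fully homozygous lines: at each marker the minor-allele
#' frequency is drawn uniformly from \code{maf_range}, each line's dosage is
#' 0 or 2 (two copies of one allele), and the column is redrawn until its
#' empirical minor-allele frequency stays within the requested range (dosage
#' coding is flipped where needed so columns always count the minor allele).
#' Markers are assigned round-robin to chromosomes 1A-7D with random
#' physical positions encoded in the marker ID ("S1A_497083519" style).
#'
#' @param config a \code{\link{sim_config}}.
#' @return a \code{\link{genotype_matrix}} with an extra \code{maf} column
#'   in its map.
#' @export
simulate_founders <- function(config) {
  validate_sim_config(config)
  set.seed(split_seed(config$seed, 3)[1])
  n <- config$n_lines
  m <- config$n_markers
  chroms <- wheat_chromosomes(config$n_chromosomes)
  chrom <- chroms[((seq_len(m) - 1L) %% length(chroms)) + 1L]
  pos <- sample.int(8e8, m, replace = TRUE)
  ids <- sprintf("S%s_%d", chrom, pos)
  while (anyDuplicated(ids)) {  # regenerate clashing positions
    dup <- duplicated(ids)
    pos[dup] <- sample.int(8e8, sum(dup), replace = TRUE)
    ids <- sprintf("S%s_%d", chrom, pos)
  }
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  d <- matrix(0, n, m)
  for (j in seq_len(m)) {
    repeat {
      col <- 2L * stats::rbinom(n, 1L, maf[j])
      f <- mean(col) / 2
      if (f > 0.5) { col <- 2L - col; f <- 1 - f }
      if (f >= config$maf_range[1]) break  # empirical MAF floor enforced
    }
    d[, j] <- col
  }
  rownames(d) <- sprintf("L%04d", seq_len(n))
  colnames(d) <- ids
  g <- genotype_matrix(d, data.frame(marker = ids, chrom = chrom, pos = pos,
                                     stringsAsFactors = FALSE))
  g$map$maf <- colMeans(d) / 2
  g
}

## Simulate one gamete from an individual with haplotype pair (h1, h2) given
## marker genetic positions (cM) per chromosome.  Crossover counts are
## Poisson(L/100) with uniform positions and no interference.
sim_gamete <- function(h1, h2, chrom_index, pos_cM, map_length) {
  out <- numeric(length(h1))
  for (ci in seq_along(chrom_index)) {
    idx <- chrom_index[[ci]]
    nx <- stats::rpois(1, map_length / 100)
    xpos <- sort(stats::runif(nx, 0, map_length))
    start <- stats::rbinom(1, 1, 0.5)
    phase <- (start + findInterval(pos_cM[[ci]], xpos)) %% 2
    out[idx] <- ifelse(phase == 0, h1[idx], h2[idx])
  }
  out
}

#' Derive a biparental population (F5 or doubled haploid)
#'
#' Crosses two fully homozygous parents and simulates progeny genotypes by
#' meiosis with Poisson crossovers (no interference) on a uniform genetic
#' map.  DH progeny double a single F1 gamete and are fully homozygous; F5
#' progeny are produced by four rounds of selfing from the F1, leaving
#' residual heterozygosity at about 1/16 of segregating loci.
#'
#' @param parents a \code{genotype_matrix} restricted to exactly 2 fully
#'   homozygous lines.
#' @param n_progeny number of progeny lines.
#' @param pop_type "F5" or "DH".
#' @param map_length_cM genetic map length per chromosome (default 150 cM).
#' @param seed integer RNG seed.
#' @param prefix line-ID prefix for the progeny.
#' @return a \code{genotype_matrix} of progeny dosages (same marker coding
#'   as the parents).
#' @export
derive_biparental <- function(parents, n_progeny, pop_type = c("DH", "F5"),
                              map_length_cM = 150, seed = 1,
                              prefix = pop_type) {
  pop_type <- match.arg(pop_type)
  stopifnot(inherits(parents, "genotype_matrix"))
  if (nrow(parents$dosage) != 2) stop("parents must be exactly 2 lines")
  if (n_progeny < 1) stop("n_progeny must be >= 1")
  if (!all(parents$dosage %in% c(0, 2)))
    stop("parents must be fully homozygous (dosages 0/2)")
  set.seed(seed)
  hp1 <- parents$dosage[1, ] / 2
  hp2 <- parents$dosage[2, ] / 2
  chroms <- unique(parents$map$chrom)
  chrom_index <- lapply(chroms, function(cc) which(parents$map$chrom == cc))
  ## evenly spaced genetic positions within each chromosome
  pos_cM <- lapply(chrom_index, function(idx)
    map_length_cM * (seq_along(idx) - 0.5) / length(idx))
  m <- ncol(parents$dosage)
  d <- matrix(0, n_progeny, m)
  for (i in seq_len(n_progeny)) {
    if (pop_type == "DH") {
      g <- sim_gamete(hp1, hp2, chrom_index, pos_cM, map_length_cM)
      d[i, ] <- 2 * g
    } else {
      h1 <- hp1; h2 <- hp2                      # the F1
      for (gen in 1:4) {                        # selfing F1 -> F5
        n1 <- sim_gamete(h1, h2, chrom_index, pos_cM, map_length_cM)
        n2 <- sim_gamete(h1, h2, chrom_index, pos_cM, map_length_cM)
        h1 <- n1; h2 <- n2
      }
      d[i, ] <- h1 + h2
    }
  }
  rownames(d) <- sprintf("%s%04d", prefix, seq_len(n_progeny))
  colnames(d) <- colnames(parents$dosage)
  genotype_matrix(d, parents$map)
}

#' Simulate a multi-environment ACBD yield trial
#'
#' Draws additive QTL effects per environment from a multivariate normal
#' with between-environment correlation \code{gxe_corr}, forms true genetic
#' values, and lays the lines out in an augmented complete block design:
#' each block holds all \code{n_checks} replicated checks plus a set of
#' unreplicated test lines, and every test line appears exactly once per
#' environment.  Residual variance per environment is calibrated from the
#' realized genetic variance so that plot-level broad-sense heritability
#' sigma_g^2/(sigma_g^2+sigma_e^2) equals \code{h2_target}.  Block effects
#' are normal with SD equal to 20\% of the residual SD.  Check lines are
#' average performers (true genetic value 0 on the centered scale).
#'
#' @param geno \code{genotype_matrix} of the test lines.
#' @param config a \code{\link{sim_config}} (environments, h2_target,
#'   gxe_corr, block layout, n_qtl, effect scale).
#' @param seed optional integer seed overriding \code{config$seed}.
#' @return list with elements \code{fieldbook} (data.frame: line_id,
#'   environment, block, is_check, yield_t_ha) and \code{truth} (list:
#'   qtl_ids, qtl_effects, true_genetic_values, realized_h2, residual_sd,
#'   mu) of class \code{simulation_truth}.
#' @export
simulate_trial <- function(geno, config, seed = config$seed) {
  stopifnot(inherits(geno, "genotype_matrix"))
  validate_sim_config(config)
  if (nrow(geno$dosage) == 0) stop("empty genotype matrix")
  envs <- config$environments
  n_env <- length(envs)
  seeds <- split_seed(seed, 2 + n_env)
  set.seed(seeds[1])

  ## --- QTL effects with G-by-E correlation ------------------------------
  n_qtl <- min(config$n_qtl, ncol(geno$dosage))
  qtl_idx <- sort(sample.int(ncol(geno$dosage), n_qtl))
  qtl_ids <- colnames(geno$dosage)[qtl_idx]
  Sigma <- matrix(config$gxe_corr, n_env, n_env)
  diag(Sigma) <- 1
  Sigma <- Sigma * config$effect_sd^2
  es <- eigen(Sigma, symmetric = TRUE)   # sqrt via eigen: tolerates corr +/-1
  rt <- es$vectors %*% (sqrt(pmax(es$values, 0)) * t(es$vectors))
  effects <- matrix(stats::rnorm(n_qtl * n_env), n_qtl, n_env) %*% rt
  colnames(effects) <- envs
  rownames(effects) <- qtl_ids

  ## true genetic values, centered per environment
  W <- geno$dosage[, qtl_idx, drop = FALSE]
  G <- W %*% effects
  if (n_qtl > 0) G <- sweep(G, 2, colMeans(G))
  rownames(G) <- rownames(geno$dosage)
  colnames(G) <- envs

  ## --- residual calibration to the target heritability -----------------
  h2 <- config$h2_target
  vg <- apply(G, 2, stats::var)
  if (nrow(G) < 2) vg <- rep(0, n_env)
  sigma_e <- numeric(n_env)
  for (e in seq_len(n_env)) {
    if (h2 == 0 && vg[e] > 0)
      stop("h2_target = 0 contradicts non-zero genetic variance")
    sigma_e[e] <- if (h2 >= 1 || vg[e] == 0) {
      if (vg[e] == 0 && h2 < 1) 1 else 0
    } else sqrt(vg[e] * (1 - h2) / h2)
  }
  realized_h2 <- ifelse(vg + sigma_e^2 > 0, vg / (vg + sigma_e^2), 0)
  names(realized_h2) <- names(sigma_e) <- envs

  ## --- field layout ------------------------------------------------------
  n_checks <- config$n_checks
  checks <- if (n_checks > 0) sprintf("CHK%02d", seq_len(n_checks)) else character()
  tests_per_block <- config$block_size - n_checks
  lines <- rownames(geno$dosage)
  fb <- vector("list", n_env)
  for (e in seq_len(n_env)) {
    set.seed(seeds[2 + e])
    ord <- sample(lines)
    n_blocks <- ceiling(length(ord) / tests_per_block)
    block_of <- rep(seq_len(n_blocks), each = tests_per_block)[seq_along(ord)]
    block_eff <- stats::rnorm(n_blocks, 0, 0.2 * sigma_e[e])
    test_y <- config$mu + block_eff[block_of] + G[ord, e] +
      stats::rnorm(length(ord), 0, sigma_e[e])
    rows <- data.frame(line_id = ord, environment = envs[e],
                       block = sprintf("B%02d", block_of), is_check = FALSE,
                       yield_t_ha = as.numeric(test_y),
                       stringsAsFactors = FALSE)
    if (n_checks > 0) {
      cb <- expand.grid(line_id = checks, blk = seq_len(n_blocks),
                        stringsAsFactors = FALSE)
      check_y <- config$mu + block_eff[cb$blk] +
        stats::rnorm(nrow(cb), 0, sigma_e[e])
      rows <- rbind(rows, data.frame(line_id = cb$line_id,
                                     environment = envs[e],
                                     block = sprintf("B%02d", cb$blk),
                                     is_check = TRUE,
                                     yield_t_ha = as.numeric(check_y),
                                     stringsAsFactors = FALSE))
    }
    fb[[e]] <- rows
  }
  fieldbook <- do.call(rbind, fb)
  rownames(fieldbook) <- NULL
  truth <- structure(list(qtl_ids = qtl_ids, qtl_effects = effects,
                          true_genetic_values = G, realized_h2 = realized_h2,
                          residual_sd = sigma_e, mu = config$mu),
                     class = "simulation_truth")
  list(fieldbook = fieldbook, truth = truth)
}

#' Write / read a field book as CSV
#'
#' Columns: line_id, environment, block, is_check, yield_t_ha.
#'
#' @param fieldbook a field-book data.frame.
#' @param path file path.
#' @return the field book (read) or \code{path} invisibly (write).
#' @export
write_fieldbook_csv <- function(fieldbook, path) {
  utils::write.csv(fieldbook, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fieldbook_csv
#' @export
read_fieldbook_csv <- function(path) {
  fb <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("line_id", "environment", "block", "is_check", "yield_t_ha")
  if (!all(need %in% names(fb)))
    stop("field book CSV must have columns: ", paste(need, collapse = ", "))
  fb$is_check <- as.logical(fb$is_check)
  if (any(!is.finite(fb$yield_t_ha))) stop("non-finite yields in field book")
  fb
}
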