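## Kinship-corrected single-marker association scan (P3D/EMMAX style).
##
## The null model y = mu + u + e, u ~ N(0, K sigma_u^2) is fit once by
## spectral REML; the estimated variance ratio is then held fixed and each
## marker is tested as a fixed effect by weighted least squares in the
## rotated (eigen) coordinates.  The residual scale is re-estimated per
## marker, so with K = I and sigma_u^2 = 0 the scan reduces exactly to
## per-marker simple linear regression t-tests.

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: q(i) = min over j >= i of m * p(j) / j,
#' clipped at 1 and mapped back to input order.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Kinship-corrected mixed-linear-model GWAS scan
#'
#' For each marker passing the MAF / missingness filters, tests the marker
#' fixed effect in y = mu + m*g + u + e with u ~ N(0, K sigma_u^2).
#' Variance components are estimated once on the marker-free null model and
#' reused for every marker (P3D).  Effects are per copy of the minor allele
#' (t/ha); p-values are Wald t-tests; q-values are Benjamini-Hochberg.
#'
#' @param geno \code{\link{genotype_matrix}}.
#' @param pheno \code{adjusted_phenotypes} or named numeric phenotype.
#' @param K optional \code{\link{compute_kinship}} matrix for the
#'   phenotyped lines (computed from \code{geno} when omitted).
#' @param maf_min minimum minor allele frequency (markers at or below are
#'   dropped; default 0.05).
#' @param max_missing maximum fraction of missing dosages per marker
#'   (default 0.10).
#' @param q_threshold significance threshold on the q-value (default 0.05).
#' @param varcomp optional list(sigma_u2, sigma_e2) overriding the null-model
#'   REML estimates (P3D plumbing, used for calibration checks).
#' @param eig optional precomputed eigen decomposition of K (reuse across
#'   repeated scans on the same panel).
#' @param dataset label recorded with every row (e.g. the environment).
#' @return data.frame of class \code{gwas_result}: marker, chrom, pos,
#'   maf, effect, se, p, q, significant; attributes \code{engine}
#'   ("MLM-P3D", recording the single-marker substitution for multi-locus
#'   scans), \code{n}, \code{varcomp}, \code{threshold}, \code{dataset}.
#' @export
run_mlm_gwas <- function(geno, pheno, K = NULL, maf_min = 0.05,
                         max_missing = 0.10, q_threshold = 0.05,
                         varcomp = NULL, eig = NULL, dataset = "trait") {
  stopifnot(inherits(geno, "genotype_matrix"))
  o <- if (inherits(pheno, "adjusted_phenotypes")) pheno_values(pheno) else pheno
  ids <- intersect(rownames(geno$dosage), names(o))
  if (length(ids) < 30)
    stop("fewer than 30 lines with genotype and phenotype (", length(ids), ")")
  y <- as.numeric(o[ids])
  ## center and standardize for numerical stability (t-tests are invariant;
  ## effects are rescaled back); guards against catastrophic cancellation
  ## when adjusted values are nearly constant (e.g. fully shrunken BLUPs)
  sdy <- stats::sd(y)
  if (sdy == 0) stop("constant phenotype: association scan undefined")
  y <- (y - mean(y)) / sdy
  M <- geno$dosage[ids, , drop = FALSE]
  n <- length(ids)

  miss <- colMeans(is.na(M))
  maf <- colMeans(M, na.rm = TRUE) / 2
  maf <- pmin(maf, 1 - maf)
  keep <- maf > maf_min & miss <= max_missing
  if (!any(keep)) stop("no markers pass the MAF/missingness filters")
  M <- M[, keep, drop = FALSE]
  maf <- maf[keep]
  if (anyNA(M)) {
    mu <- colMeans(M, na.rm = TRUE)
    idx <- which(is.na(M), arr.ind = TRUE)
    M[idx] <- mu[idx[, 2]]
  }

  if (is.null(K)) K <- compute_kinship(geno_subset(geno, lines = ids))
  K <- unclass(K)[ids, ids]
  if (!is.null(eig) && length(eig$values) != length(ids)) eig <- NULL
  if (is.null(eig)) eig <- eigen(K, symmetric = TRUE)
  if (min(eig$values) < -1e-6) stop("kinship matrix is not positive semidefinite")

  X0 <- matrix(1, n, 1)
  if (is.null(varcomp)) {
    null_fit <- reml_spectral(y, X0, K, eig = eig)
    su2 <- null_fit$sigma_u2; se2 <- null_fit$sigma_e2
  } else {
    ## supplied components are on the original scale
    su2 <- varcomp$sigma_u2 / sdy^2; se2 <- varcomp$sigma_e2 / sdy^2
  }

  ## rotate once, then per-marker 2x2 weighted least squares (vectorized)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  w <- 1 / (su2 * d + se2)
  yt <- as.numeric(crossprod(U, y))
  ones_t <- as.numeric(crossprod(U, rep(1, n)))
  Wc <- sweep(M, 2, colMeans(M))
  Mt <- crossprod(U, Wc)

  a11 <- sum(w * ones_t^2)
  b1 <- sum(w * ones_t * yt)
  a12 <- as.numeric(crossprod(Mt, w * ones_t))
  a22 <- as.numeric(colSums(Mt^2 * w))
  b2 <- as.numeric(crossprod(Mt, w * yt))
  det <- a11 * a22 - a12^2
  det[det <= 0] <- NA  # monomorphic-after-filter safeguard
  beta_m <- (a11 * b2 - a12 * b1) / det
  beta_0 <- (a22 * b1 - a12 * b2) / det
  ## weighted RSS per marker, residual scale re-estimated per marker
  yty <- sum(w * yt^2)
  rss <- yty - 2 * (beta_0 * b1 + beta_m * b2) +
    beta_0^2 * a11 + 2 * beta_0 * beta_m * a12 + beta_m^2 * a22
  rss[rss < 0] <- 0
  s2 <- rss / (n - 2)
  se <- sqrt(s2 * a11 / det)
  tstat <- beta_m / se
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[is.na(p)] <- 1
  q <- bh_fdr(p)

  out <- data.frame(marker = colnames(M),
                    chrom = geno$map$chrom[match(colnames(M), geno$map$marker)],
                    pos = geno$map$pos[match(colnames(M), geno$map$marker)],
                    maf = as.numeric(maf), effect = as.numeric(beta_m) * sdy,
                    se = as.numeric(se) * sdy, p = as.numeric(p),
                    q = as.numeric(q),
                    significant = as.numeric(q) <= q_threshold,
                    dataset = dataset, stringsAsFactors = FALSE)
  attr(out, "engine") <- "MLM-P3D"
  attr(out, "n") <- n
  attr(out, "varcomp") <- c(sigma_u2 = su2 * sdy^2, sigma_e2 = se2 * sdy^2)
  attr(out, "threshold") <- q_threshold
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' Select the top-k significant SNPs across datasets
#'
#' Markers are ranked by their best (minimum) q-value across the supplied
#' GWAS results and must be significant (q <= threshold) in at least one
#' dataset; ties break by |effect| (larger first) then marker ID.  The
#' favorable allele is the dosage direction with positive yield effect in
#' the dataset achieving the minimum q: required dosage 2 (homozygous minor)
#' for positive effects, 0 (homozygous major) for negative effects —
#' heterozygotes never satisfy the requirement in inbred material.
#'
#' @param gwas a \code{gwas_result} or a list of them (one per dataset).
#' @param k number of markers to keep (default 5).
#' @param q_threshold significance threshold (default 0.05).
#' @return data.frame of class \code{favorable_allele_set}: marker, dataset,
#'   effect, q, favorable_dosage.  Empty (with a warning) when nothing is
#'   significant.
#' @export
select_top_snps <- function(gwas, k = 5, q_threshold = 0.05) {
  if (inherits(gwas, "gwas_result")) gwas <- list(gwas)
  all <- do.call(rbind, lapply(gwas, function(g)
    g[, c("marker", "dataset", "effect", "q")]))
  sig <- all[all$q <= q_threshold, , drop = FALSE]
  if (nrow(sig) == 0) {
    warning("no significant markers at q <= ", q_threshold)
    out <- data.frame(marker = character(), dataset = character(),
                      effect = numeric(), q = numeric(),
                      favorable_dosage = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("favorable_allele_set", "data.frame")
    return(out)
  }
  ## best dataset per marker
  sig <- sig[order(sig$marker, sig$q, -abs(sig$effect)), , drop = FALSE]
  best <- sig[!duplicated(sig$marker), , drop = FALSE]
  best <- best[order(best$q, -abs(best$effect), best$marker), , drop = FALSE]
  best <- utils::head(best, k)
  best$favorable_dosage <- ifelse(best$effect > 0, 2, 0)
  rownames(best) <- NULL
  class(best) <- c("favorable_allele_set", "data.frame")
  best
}

#' Per-SNP variance explained by drop-one regression
#'
#' Joint OLS fit of the phenotype on all significant markers; each marker's
#' R^2 is the total R^2 minus the R^2 of the model refit without that marker
#' (values can be near zero for correlated markers).  Collinear markers are
#' pruned (later-ordered marker dropped) with a warning.
#'
#' @param geno \code{\link{genotype_matrix}}.
#' @param pheno \code{adjusted_phenotypes} or named numeric.
#' @param markers character vector of (significant) marker IDs.
#' @return data.frame: marker, r2; attribute \code{r2_full}.
#' @export
snp_variance_explained <- function(geno, pheno, markers) {
  o <- if (inherits(pheno, "adjusted_phenotypes")) pheno_values(pheno) else pheno
  ids <- intersect(rownames(geno$dosage), names(o))
  y <- as.numeric(o[ids])
  if (!all(markers %in% colnames(geno$dosage)))
    stop("markers absent from genotype matrix")
  M <- geno$dosage[ids, markers, drop = FALSE]
  X <- cbind(1, M)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_idx <- qx$pivot[seq(qx$rank + 1, ncol(X))] - 1L
    warning("pruning collinear marker(s): ",
            paste(markers[drop_idx], collapse = ", "))
    markers <- markers[-drop_idx]
    M <- M[, markers, drop = FALSE]
  }
  r2_of <- function(mat) {
    if (ncol(mat) == 0) return(0)
    f <- stats::lm.fit(cbind(1, mat), y)
    1 - sum(f$residuals^2) / sum((y - mean(y))^2)
  }
  r2_full <- r2_of(M)
  r2 <- vapply(seq_along(markers), function(j)
    r2_full - r2_of(M[, -j, drop = FALSE]), numeric(1))
  out <- data.frame(marker = markers, r2 = r2, stringsAsFactors = FALSE)
  attr(out, "r2_full") <- r2_full
  out
}

#' Write a GWAS result as TSV (Table-1-style columns)
#' @param gwas a \code{gwas_result}.
#' @param path output path.
#' @param significant_only keep only q-significant rows (default FALSE).
#' @return \code{path}, invisibly.
#' @export
write_gwas_tsv <- function(gwas, path, significant_only = FALSE) {
  g <- gwas
  if (significant_only) g <- g[g$significant, , drop = FALSE]
  out <- data.frame(SNP = g$marker, dataset = g$dataset, P_value = g$p,
                    q = g$q, MAF = g$maf, effect = g$effect,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
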