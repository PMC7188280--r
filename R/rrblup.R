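## Ridge-regression BLUP genomic prediction.
##
## Model: y = X beta + Z u + e,  u ~ N(0, K sigma_u^2),  e ~ N(0, I sigma_e^2)
## with Z = I for the training lines and K the marker-derived additive
## relationship matrix.  Variance components are estimated by REML profiled
## over the ratio lambda = sigma_e^2 / sigma_u^2 after a single spectral
## decomposition of K (the standard one-eigendecomposition mixed-model
## device), with a Brent search on log(lambda) in [-10, 10].
##
## The marker-effect and breeding-value parameterizations are equivalent:
## with K = WW'/c, marker effects a = W'(WW' + lambda_m I)^{-1} r solve the
## ridge problem (W'W + lambda_m I)^{-1} W' r, and W a equals the K-model
## BLUP u at lambda_K = lambda_m / c.

## Spectral-REML for y = X beta + u + e, u ~ N(0, K su2).  Returns variance
## components, GLS beta, and the eigen pieces for reuse.
reml_spectral <- function(y, X, K, interval = c(-10, 10), tol = 1e-8,
                          eig = NULL) {
  n <- length(y)
  p <- ncol(X)
  if (is.null(eig)) eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)

  prof <- function(loglam) {
    lam <- exp(loglam)
    w <- 1 / (d + lam)
    XtWX <- crossprod(Xt * w, Xt)
    XtWy <- crossprod(Xt * w, yt)
    beta <- solve(XtWX, XtWy)
    r <- yt - Xt %*% beta
    rss <- sum(w * r^2)
    su2 <- rss / (n - p)
    ## restricted log-likelihood up to an additive constant
    -0.5 * ((n - p) * log(su2) + sum(log(d + lam)) +
              determinant(XtWX, logarithm = TRUE)$modulus)
  }
  opt <- stats::optimize(prof, interval = interval, maximum = TRUE, tol = tol)
  lam <- exp(opt$maximum)
  w <- 1 / (d + lam)
  XtWX <- crossprod(Xt * w, Xt)
  beta <- solve(XtWX, crossprod(Xt * w, yt))
  r <- yt - Xt %*% beta
  su2 <- sum(w * r^2) / (n - p)
  se2 <- lam * su2
  list(sigma_u2 = su2, sigma_e2 = se2, lambda = lam,
       beta = as.numeric(beta), eig = eig, U = U, d = d,
       loglik = opt$objective)
}

## GLS beta and BLUP u at a fixed variance ratio lambda_K (K scale).
gls_blup <- function(y, X, K, lambda_K) {
  n <- length(y)
  V <- K + diag(lambda_K, n)          # proportional to Var(y)
  Vi <- solve(V)
  XtVi <- crossprod(X, Vi)
  beta <- solve(XtVi %*% X, XtVi %*% y)
  r <- y - X %*% beta
  u <- K %*% Vi %*% r
  list(beta = as.numeric(beta), u = as.numeric(u), resid = as.numeric(r))
}

#' Fit an RRBLUP genomic prediction model
#'
#' Fits y = X beta + u + e with u ~ N(0, K sigma_u^2), K the VanRaden
#' relationship matrix from the training markers.  The fixed part X is an
#' intercept plus, optionally, the dosage columns of GWAS-derived markers
#' (the GWAS-assisted scenario); those markers stay in the polygenic
#' background as well.  Variance components come from spectral REML unless a
#' fixed marker-scale ridge parameter \code{lambda} (= sigma_e^2 /
#' sigma_a^2) is supplied, in which case REML is skipped.
#'
#' @param train_geno \code{\link{genotype_matrix}} of training lines.
#' @param train_pheno an \code{\link{adjusted_phenotypes}} object or a named
#'   numeric vector of phenotypes.
#' @param fixed_markers optional character vector of marker IDs fitted as
#'   fixed effects (GS2 scenario).
#' @param lambda optional fixed marker-scale ridge parameter.
#' @param K,eig optional precomputed kinship (for exactly the training
#'   lines, VanRaden scaling from the same markers) and its eigen
#'   decomposition; recomputed when omitted.  Reuse across repeated fits on
#'   the same panel.
#' @return object of class \code{rrblup_model}: beta, marker_effects,
#'   variance components, centering means and training metadata.
#' @export
fit_rrblup <- function(train_geno, train_pheno, fixed_markers = NULL,
                       lambda = NULL, K = NULL, eig = NULL) {
  stopifnot(inherits(train_geno, "genotype_matrix"))
  y_all <- if (inherits(train_pheno, "adjusted_phenotypes"))
    pheno_values(train_pheno) else train_pheno
  ids <- intersect(rownames(train_geno$dosage), names(y_all))
  if (length(ids) < 2) stop("need overlapping genotyped + phenotyped lines")
  if (length(ids) < 30)
    warning("fewer than 30 training lines (", length(ids), ")")
  y <- as.numeric(y_all[ids])
  if (stats::var(y) == 0) stop("all-constant training phenotype")
  M <- train_geno$dosage[ids, , drop = FALSE]

  X <- matrix(1, length(ids), 1, dimnames = list(NULL, "(Intercept)"))
  if (length(fixed_markers) > 0) {
    missing_fm <- setdiff(fixed_markers, colnames(M))
    if (length(missing_fm) > 0)
      stop("fixed markers absent from genotype matrix: ",
           paste(missing_fm, collapse = ", "))
    X <- cbind(X, M[, fixed_markers, drop = FALSE])
  }
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("rank-deficient fixed-effect design; offending column(s): ",
         paste(colnames(X)[qx$pivot[seq(qx$rank + 1, ncol(X))]],
               collapse = ", "))

  col_means <- colMeans(M)
  p <- col_means / 2
  cc <- 2 * sum(p * (1 - p))
  if (cc == 0) stop("all training markers monomorphic")
  W <- sweep(M, 2, col_means)
  if (is.null(K)) {
    K <- tcrossprod(W) / cc
  } else {
    K <- unclass(K)[ids, ids]
  }

  if (!is.null(eig) && length(eig$values) != length(ids)) eig <- NULL

  if (is.null(lambda)) {
    fit <- reml_spectral(y, X, K, eig = eig)
    lambda_K <- fit$lambda
    sigma_u2 <- fit$sigma_u2
    sigma_e2 <- fit$sigma_e2
    lambda_m <- lambda_K * cc
  } else {
    lambda_m <- lambda
    lambda_K <- lambda / cc
    sigma_u2 <- NA_real_
    sigma_e2 <- NA_real_
  }
  sol <- gls_blup(y, X, K, lambda_K)
  ## marker effects: a = W'(WW' + lambda_m I)^{-1} r  (ridge solution)
  a <- crossprod(W, solve(tcrossprod(W) + diag(lambda_m, length(ids)),
                          sol$resid))
  structure(list(beta = stats::setNames(sol$beta, colnames(X)),
                 fixed_markers = fixed_markers,
                 marker_effects = stats::setNames(as.numeric(a), colnames(M)),
                 col_means = col_means, scaling_c = cc,
                 lambda_K = lambda_K, lambda_m = lambda_m,
                 sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
                 train_ids = ids, train_gebv = stats::setNames(sol$u, ids),
                 scenario = if (length(fixed_markers) > 0) "GS2" else "GS1"),
            class = "rrblup_model")
}

#' @export
print.rrblup_model <- function(x, ...) {
  cat(sprintf("rrblup_model (%s): %d training lines, %d markers, %d fixed\n",
              x$scenario, length(x$train_ids), length(x$marker_effects),
              length(x$fixed_markers)))
  if (is.finite(x$sigma_u2))
    cat(sprintf("  sigma_u2=%.4g sigma_e2=%.4g lambda_K=%.4g\n",
                x$sigma_u2, x$sigma_e2, x$lambda_K))
  invisible(x)
}

#' Predict genomic estimated breeding values
#'
#' GEBV of target lines from the marker-effect parameterization: target
#' dosages are centered by the training column means and multiplied by the
#' fitted marker effects.  The predicted yield adds the fixed-effect
#' contribution X beta (intercept + any fixed markers), putting predictions
#' back on the t/ha scale; the GEBV itself is on the deviation scale.
#'
#' @param model an \code{rrblup_model}.
#' @param target_geno \code{\link{genotype_matrix}} of lines to predict.
#' @return data.frame of class \code{gebv_result}: line_id, gebv,
#'   predicted_yield, scenario.
#' @export
predict_gebv <- function(model, target_geno) {
  stopifnot(inherits(model, "rrblup_model"),
            inherits(target_geno, "genotype_matrix"))
  shared <- intersect(colnames(target_geno$dosage),
                      names(model$marker_effects))
  if (length(shared) == 0) stop("no markers shared with the training panel")
  if (length(shared) < length(model$marker_effects))
    message(sprintf("predicting with %d of %d training markers",
                    length(shared), length(model$marker_effects)))
  Mt <- target_geno$dosage[, shared, drop = FALSE]
  Wt <- sweep(Mt, 2, model$col_means[shared])
  gebv <- as.numeric(Wt %*% model$marker_effects[shared])
  Xt <- matrix(1, nrow(Mt), 1)
  if (length(model$fixed_markers) > 0) {
    if (!all(model$fixed_markers %in% colnames(target_geno$dosage)))
      stop("target lines lack the model's fixed-effect markers")
    Xt <- cbind(Xt, target_geno$dosage[, model$fixed_markers, drop = FALSE])
  }
  pred <- as.numeric(Xt %*% model$beta) + gebv
  out <- data.frame(line_id = rownames(Mt), gebv = gebv,
                    predicted_yield = pred, scenario = model$scenario,
                    stringsAsFactors = FALSE)
  class(out) <- c("gebv_result", "data.frame")
  out
}

#' Predictive ability
#'
#' Pearson correlation between GEBVs and observed (adjusted) phenotypes over
#' the overlapping lines.
#'
#' @param gebv a \code{gebv_result} (or named numeric of GEBVs).
#' @param observed an \code{adjusted_phenotypes} object or named numeric.
#' @return list with \code{r} (Pearson correlation) and \code{n} (lines used).
#' @export
predictive_ability <- function(gebv, observed) {
  g <- if (inherits(gebv, "data.frame"))
    stats::setNames(gebv$gebv, gebv$line_id) else gebv
  o <- if (inherits(observed, "adjusted_phenotypes"))
    pheno_values(observed) else observed
  ids <- intersect(names(g), names(o))
  if (length(ids) < 3) stop("need >= 3 overlapping lines")
  if (stats::sd(g[ids]) == 0 || stats::sd(o[ids]) == 0)
    stop("zero variance: correlation undefined")
  list(r = stats::cor(g[ids], o[ids]), n = length(ids))
}

#' K-fold cross-validated genomic prediction
#'
#' Random disjoint folds (uniform permutation split from \code{seed}); each
#' fold is predicted by a model trained on the remaining lines, so every
#' line receives exactly one out-of-fold GEBV.
#'
#' @param geno \code{\link{genotype_matrix}}.
#' @param pheno \code{adjusted_phenotypes} or named numeric.
#' @param folds number of folds (>= 2; \code{folds = n} gives leave-one-out,
#'   for which per-fold correlations are undefined and reported as NA).
#' @param seed integer seed for the fold assignment.
#' @param fixed_markers optional fixed-effect markers passed through to
#'   \code{\link{fit_rrblup}}.
#' @return list: \code{oof} (data.frame line_id, fold, gebv),
#'   \code{fold_r} (per-fold predictive ability), \code{mean_r}.
#' @export
cross_validate <- function(geno, pheno, folds = 5, seed = 1,
                           fixed_markers = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  o <- if (inherits(pheno, "adjusted_phenotypes")) pheno_values(pheno) else pheno
  ids <- intersect(rownames(geno$dosage), names(o))
  n <- length(ids)
  if (folds < 2) stop("folds must be >= 2")
  if (n < folds) stop("more folds than lines")
  set.seed(seed)
  fold_of <- stats::setNames(sample(rep(seq_len(folds), length.out = n)), ids)
  oof <- vector("list", folds)
  fold_r <- rep(NA_real_, folds)
  for (k in seq_len(folds)) {
    test_ids <- names(fold_of)[fold_of == k]
    train_ids <- setdiff(ids, test_ids)
    if (length(train_ids) < 2) stop("fold with < 2 training lines")
    fit <- suppressWarnings(
      fit_rrblup(geno_subset(geno, lines = train_ids), o[train_ids],
                 fixed_markers = fixed_markers))
    pr <- predict_gebv(fit, geno_subset(geno, lines = test_ids))
    oof[[k]] <- data.frame(line_id = pr$line_id, fold = k, gebv = pr$gebv,
                           stringsAsFactors = FALSE)
    if (length(test_ids) >= 3 && stats::sd(pr$gebv) > 0 &&
        stats::sd(o[pr$line_id]) > 0)
      fold_r[k] <- stats::cor(pr$gebv, o[pr$line_id])
  }
  oof <- do.call(rbind, oof)
  all_r <- predictive_ability(stats::setNames(oof$gebv, oof$line_id), o)$r
  list(oof = oof, fold_r = fold_r,
       mean_r = if (all(is.na(fold_r))) all_r else mean(fold_r, na.rm = TRUE),
       overall_r = all_r)
}
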