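## Augmented complete block design (ACBD) adjustment of plot yields.
##
## Single-environment adjustment fits the fixed-effect model
##   Y = mu + Block + G + C + I + e
## where G indexes the unreplicated test genotypes, C separates checks from
## tests and I differentiates the named checks.  The pooled-level coding
## (tests share one I level, checks share one G level) makes G, C and I a
## partition of a single "entry" factor, so the model is fit as
## Y ~ block + entry, which spans the identical column space and is always
## estimable when every block carries at least one check.  Multi-environment
## BLUPs treat genotype, check, interaction and nested-block terms as random
## (REML via lme4).

#' Adjusted phenotypes container
#' @param data data.frame with columns line_id, value, is_check.
#' @param mode "BLUE" or "BLUP".
#' @param scope character vector of environments covered.
#' @param varcomp named numeric: sigma_g2, sigma_e2 ((t/ha)^2; sigma_g2 is
#'   NA for single-environment BLUEs, where genotypic and residual variance
#'   are confounded for unreplicated entries).
#' @return object of class \code{adjusted_phenotypes}.
#' @export
adjusted_phenotypes <- function(data, mode = c("BLUE", "BLUP"), scope,
                                varcomp = c(sigma_g2 = NA_real_,
                                            sigma_e2 = NA_real_)) {
  mode <- match.arg(mode)
  stopifnot(all(c("line_id", "value", "is_check") %in% names(data)))
  structure(list(data = data, mode = mode, scope = scope,
                 varcomp = varcomp),
            class = "adjusted_phenotypes")
}

#' @export
print.adjusted_phenotypes <- function(x, ...) {
  cat(sprintf("adjusted_phenotypes: %d lines, mode=%s, scope=%s\n",
              nrow(x$data), x$mode, paste(x$scope, collapse = "+")))
  if (is.finite(x$varcomp["sigma_g2"]))
    cat(sprintf("  sigma_g2=%.4f sigma_e2=%.4f (H2=%.3f)\n",
                x$varcomp["sigma_g2"], x$varcomp["sigma_e2"],
                estimate_h2(x$varcomp)))
  invisible(x)
}

#' Extract adjusted values as a named vector
#' @param x an \code{adjusted_phenotypes} object.
#' @param tests_only drop check lines (default TRUE).
#' @return named numeric vector of adjusted yields (t/ha).
#' @export
pheno_values <- function(x, tests_only = TRUE) {
  stopifnot(inherits(x, "adjusted_phenotypes"))
  d <- x$data
  if (tests_only) d <- d[!d$is_check, , drop = FALSE]
  stats::setNames(d$value, d$line_id)
}

check_fieldbook <- function(fb) {
  need <- c("line_id", "environment", "block", "is_check", "yield_t_ha")
  if (!all(need %in% names(fb)))
    stop("field book must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(fb$yield_t_ha))) {
    fb <- fb[is.finite(fb$yield_t_ha), , drop = FALSE]  # listwise drop
  }
  dup <- fb[!fb$is_check, c("line_id", "environment")]
  if (anyDuplicated(dup))
    stop("test lines must be unreplicated within an environment")
  fb
}

#' Single-environment ACBD adjustment (BLUEs)
#'
#' Fits the fixed-effect augmented-design model by least squares and returns
#' check- and block-corrected line estimates, re-centered so that the mean
#' of the check BLUEs equals the raw check mean.
#'
#' @param fieldbook field-book data.frame (one environment, or use
#'   \code{environment} to restrict).
#' @param environment optional environment label to subset on.
#' @return an \code{\link{adjusted_phenotypes}} object (mode "BLUE");
#'   \code{varcomp["sigma_e2"]} is the residual variance of the fit.
#' @export
adjust_single_env <- function(fieldbook, environment = NULL) {
  fb <- check_fieldbook(fieldbook)
  if (!is.null(environment)) fb <- fb[fb$environment == environment, , drop = FALSE]
  envs <- unique(fb$environment)
  if (length(envs) != 1)
    stop("adjust_single_env needs exactly one environment (got ",
         length(envs), "); pass `environment`")
  blocks <- unique(fb$block)
  if (length(blocks) == 1) {
    ## degenerate single-block layout: nothing to adjust, BLUEs = raw values
    return(adjusted_phenotypes(
      data.frame(line_id = fb$line_id, value = fb$yield_t_ha,
                 is_check = fb$is_check, stringsAsFactors = FALSE),
      mode = "BLUE", scope = envs,
      varcomp = c(sigma_g2 = NA_real_, sigma_e2 = NA_real_)))
  }
  has_check <- tapply(fb$is_check, fb$block, any)
  if (any(!has_check))
    stop("block(s) without any check plot: ",
         paste(names(has_check)[!has_check], collapse = ", "))
  fb$entry <- factor(fb$line_id)
  fb$block <- factor(fb$block)
  fit <- stats::lm(yield_t_ha ~ block + entry, data = fb)
  if (any(is.na(stats::coef(fit))))
    stop("singular ACBD design: collinear model terms")
  cf <- stats::coef(fit)
  bnames <- paste0("block", levels(fb$block))
  beff <- c(0, cf[bnames[-1]])
  mean_block <- mean(beff)
  enames <- paste0("entry", levels(fb$entry))
  eeff <- c(0, cf[enames[-1]])
  blue <- cf[["(Intercept)"]] + eeff + mean_block
  names(blue) <- levels(fb$entry)
  is_chk <- stats::setNames(tapply(fb$is_check, fb$entry, any), levels(fb$entry))
  ## re-center: mean of check BLUEs equals the raw check mean
  if (any(is_chk)) {
    shift <- mean(fb$yield_t_ha[fb$is_check]) - mean(blue[names(which(is_chk))])
    blue <- blue + shift
  }
  adjusted_phenotypes(
    data.frame(line_id = names(blue), value = as.numeric(blue),
               is_check = as.logical(is_chk[names(blue)]),
               stringsAsFactors = FALSE),
    mode = "BLUE", scope = envs,
    varcomp = c(sigma_g2 = NA_real_,
                sigma_e2 = summary(fit)$sigma^2))
}

#' Multi-environment ACBD adjustment (BLUPs) and variance components
#'
#' Fits the combined augmented-design model with genotype, check-identifier,
#' environment, their interactions, and block-nested-in-environment terms
#' all random (REML via \pkg{lme4}), and returns genotype BLUPs shrunken
#' toward the grand mean plus the genotypic and residual variance
#' components used for broad-sense heritability.
#'
#' @param fieldbook field-book data.frame spanning >= 2 environments.
#' @return an \code{\link{adjusted_phenotypes}} object (mode "BLUP") with
#'   \code{varcomp} carrying sigma_g2 and sigma_e2.
#' @export
adjust_multi_env <- function(fieldbook) {
  fb <- check_fieldbook(fieldbook)
  envs <- unique(fb$environment)
  if (length(envs) < 2) stop("adjust_multi_env needs >= 2 environments")
  fb$geno <- ifelse(fb$is_check, ".CHECK.", fb$line_id)      # G (+ pooled checks)
  fb$check_id <- ifelse(fb$is_check, fb$line_id, ".TEST.")   # I (+ pooled tests)
  fb$env <- fb$environment
  fb$blk <- interaction(fb$env, fb$block, drop = TRUE)       # B_k(E_i)
  n_checks <- length(unique(fb$check_id)) - 1L
  form <- yield_t_ha ~ 1 + (1 | geno) + (1 | env) + (1 | geno:env) + (1 | blk)
  if (n_checks > 0)
    form <- stats::update(form, . ~ . + (1 | check_id) + (1 | check_id:env))
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(form, data = fb, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.nobs.vs.nlev = "ignore",
                                             check.nobs.vs.nRE = "ignore")))),
    error = function(e) stop("REML fit failed: ", conditionMessage(e)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_g2 <- vc$vcov[vc$grp == "geno"]
  sigma_e2 <- vc$vcov[vc$grp == "Residual"]
  if (length(sigma_g2) == 0) sigma_g2 <- 0
  if (sigma_g2 < 1e-10) {
    if (sigma_g2 < 0) warning("negative genotypic variance clamped")
    sigma_g2 <- max(sigma_g2, 1e-10)
  }
  mu <- lme4::fixef(fit)[["(Intercept)"]]
  re <- lme4::ranef(fit)$geno
  blup <- stats::setNames(mu + re[, 1], rownames(re))
  blup <- blup[names(blup) != ".CHECK."]
  ## lines absent from the random-effect table (none in practice) get mu
  tests <- setdiff(unique(fb$line_id[!fb$is_check]), names(blup))
  if (length(tests) > 0)
    blup <- c(blup, stats::setNames(rep(mu, length(tests)), tests))
  adjusted_phenotypes(
    data.frame(line_id = names(blup), value = as.numeric(blup),
               is_check = FALSE, stringsAsFactors = FALSE),
    mode = "BLUP", scope = envs,
    varcomp = c(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2))
}

#' Broad-sense heritability from variance components
#'
#' H^2 = sigma_g^2 / (sigma_g^2 + sigma_e^2), clamped to [0, 1].
#'
#' @param variance_components named numeric with sigma_g2 and sigma_e2, or
#'   an \code{adjusted_phenotypes} object carrying them.
#' @return heritability in [0, 1].
#' @export
estimate_h2 <- function(variance_components) {
  if (inherits(variance_components, "adjusted_phenotypes"))
    variance_components <- variance_components$varcomp
  g <- variance_components[["sigma_g2"]]
  e <- variance_components[["sigma_e2"]]
  if (is.na(g) || is.na(e)) stop("variance components unavailable")
  if (g < 0 || e < 0) stop("variance components must be non-negative")
  if (g + e == 0) stop("both variance components are zero")
  min(max(g / (g + e), 0), 1)
}

#' Write adjusted phenotypes (and variance components) as TSV
#' @param x an \code{adjusted_phenotypes} object.
#' @param path output TSV path; variance components go to
#'   \code{<path>.varcomp.tsv}.
#' @return \code{path}, invisibly.
#' @export
write_adjusted_tsv <- function(x, path) {
  stopifnot(inherits(x, "adjusted_phenotypes"))
  out <- data.frame(line_id = x$data$line_id,
                    adjusted_value = x$data$value, mode = x$mode,
                    environment_scope = paste(x$scope, collapse = "+"),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  vc <- data.frame(component = names(x$varcomp), value = as.numeric(x$varcomp))
  utils::write.table(vc, paste0(path, ".varcomp.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
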