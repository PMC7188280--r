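## Marker-based relationship structures: the VanRaden additive genomic
## relationship matrix used by RRBLUP/GWAS, and Rogers genetic distances
## between populations.

#' Additive genomic relationship (kinship) matrix
#'
#' VanRaden scaling: dosages are centered by twice the allele frequency per
#' marker and K = WW' / c with c = 2 * sum(p * (1 - p)).  Missing dosages
#' are imputed with the per-marker mean before centering.
#'
#' @param geno a \code{\link{genotype_matrix}} (>= 2 lines).
#' @return symmetric positive-semidefinite matrix of class
#'   \code{kinship_matrix} with attribute \code{c} (the scaling constant)
#'   and \code{p} (allele frequencies used for centering).
#' @export
compute_kinship <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosage
  if (nrow(d) < 2) stop("need >= 2 lines for a kinship matrix")
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  p <- colMeans(d) / 2
  cc <- 2 * sum(p * (1 - p))
  if (cc == 0) stop("all markers monomorphic: kinship scaling constant is 0")
  W <- sweep(d, 2, 2 * p)
  K <- tcrossprod(W) / cc
  structure(K, c = cc, p = p, class = c("kinship_matrix", "matrix"))
}

#' Rogers genetic distance between two populations
#'
#' Per biallelic marker the Rogers distance is the Euclidean distance
#' between the two populations' allele-frequency vectors divided by sqrt(2)
#' (which reduces to |p_A - p_B|); the reported value averages over the
#' markers in scope.  Markers monomorphic in both populations contribute 0.
#'
#' @param popA,popB \code{genotype_matrix} objects sharing markers.
#' @param scope "overall" (one value over all shared markers),
#'   "chromosome" (one value per chromosome), or "line_pair" (mean over all
#'   cross-population line pairs of the per-pair distance, each line
#'   treated as a two-allele population).
#' @return data.frame with columns \code{scope} and \code{distance}
#'   (class \code{distance_report}), values in [0, 1].
#' @export
rogers_distance <- function(popA, popB, scope = c("overall", "chromosome",
                                                  "line_pair")) {
  scope <- match.arg(scope)
  stopifnot(inherits(popA, "genotype_matrix"), inherits(popB, "genotype_matrix"))
  shared <- intersect(colnames(popA$dosage), colnames(popB$dosage))
  if (length(shared) == 0) stop("no shared markers between populations")
  dA <- popA$dosage[, shared, drop = FALSE]
  dB <- popB$dosage[, shared, drop = FALSE]
  pA <- colMeans(dA, na.rm = TRUE) / 2
  pB <- colMeans(dB, na.rm = TRUE) / 2
  per_marker <- sqrt((pA - pB)^2 + ((1 - pA) - (1 - pB))^2) / sqrt(2)
  out <- switch(scope,
    overall = data.frame(scope = "overall", distance = mean(per_marker),
                         stringsAsFactors = FALSE),
    chromosome = {
      chrom <- popA$map$chrom[match(shared, popA$map$marker)]
      agg <- tapply(per_marker, chrom, mean)
      data.frame(scope = names(agg), distance = as.numeric(agg),
                 stringsAsFactors = FALSE)
    },
    line_pair = {
      ## per line pair: mean over markers of |f_a - f_b|, f in {0, .5, 1}
      total <- 0
      for (i in seq_len(nrow(dA))) {
        fa <- dA[i, ] / 2
        total <- total + sum(abs(sweep(dB / 2, 2, fa)))
      }
      data.frame(scope = "line_pair",
                 distance = total / (nrow(dA) * nrow(dB) * length(shared)),
                 stringsAsFactors = FALSE)
    })
  class(out) <- c("distance_report", "data.frame")
  out
}

#' Write a kinship matrix or distance report as TSV
#' @param x a \code{kinship_matrix} or \code{distance_report}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_relatedness_tsv <- function(x, path) {
  if (inherits(x, "kinship_matrix")) {
    utils::write.table(data.frame(line_id = rownames(x), unclass(x),
                                  check.names = FALSE),
                       path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
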