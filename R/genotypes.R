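#' Genotype matrix container
#'
#' A light container pairing a lines x markers dosage matrix with a marker
#' map.  Dosages count copies of the minor allele on a \{0, 1, 2\} scale;
#' fully inbred material carries only 0 and 2.
#'
#' @param dosage numeric matrix, lines in rows (rownames = line IDs),
#'   markers in columns (colnames = marker IDs such as "S1A_497083519").
#' @param map optional data.frame with columns \code{marker}, \code{chrom},
#'   \code{pos}; derived from marker IDs when omitted.
#' @return an object of class \code{genotype_matrix} with elements
#'   \code{dosage} and \code{map}.
#' @export
genotype_matrix <- function(dosage, map = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("L%04d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    stop("dosage matrix must carry marker IDs as column names")
  if (is.null(map)) {
    parsed <- parse_marker_ids(colnames(dosage))
    map <- data.frame(marker = colnames(dosage),
                      chrom = parsed$chrom, pos = parsed$pos,
                      stringsAsFactors = FALSE)
  }
  if (!identical(map$marker, colnames(dosage)))
    map <- map[match(colnames(dosage), map$marker), , drop = FALSE]
  structure(list(dosage = dosage, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d lines x %d markers (%d chromosomes)\n",
              nrow(x$dosage), ncol(x$dosage),
              length(unique(x$map$chrom))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by lines and/or markers
#'
#' @param geno a \code{genotype_matrix}.
#' @param lines,markers character vectors of line / marker IDs (or index
#'   vectors); \code{NULL} keeps everything.
#' @return a \code{genotype_matrix}.
#' @export
geno_subset <- function(geno, lines = NULL, markers = NULL) {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosage
  if (!is.null(lines)) d <- d[lines, , drop = FALSE]
  if (!is.null(markers)) d <- d[, markers, drop = FALSE]
  genotype_matrix(d, geno$map[match(colnames(d), geno$map$marker), ,
                              drop = FALSE])
}

#' Parse marker identifiers of the form S<chrom>_<position>
#'
#' Marker IDs encode chromosome and physical position, e.g.
#' \code{"S1A_497083519"} is chromosome 1A at 497,083,519 bp.  Unplaced
#' markers use chromosome "UN".
#'
#' @param ids character vector of marker IDs.
#' @return data.frame with columns \code{marker}, \code{chrom},
#'   \code{genome} (the subgenome letter, NA when not A/B/D), \code{pos},
#'   and logical \code{valid} flagging IDs that match the convention.
#' @export
parse_marker_ids <- function(ids) {
  m <- regmatches(ids, regexec("^S([0-9]+[A-Za-z]+|UN)_([0-9]+)$", ids))
  ok <- lengths(m) == 3L
  chrom <- rep(NA_character_, length(ids))
  pos <- rep(NA_real_, length(ids))
  chrom[ok] <- vapply(m[ok], `[`, "", 2L)
  pos[ok] <- as.numeric(vapply(m[ok], `[`, "", 3L))
  genome <- ifelse(grepl("^[0-9]+[ABD]$", chrom),
                   substring(chrom, nchar(chrom)), NA_character_)
  data.frame(marker = ids, chrom = chrom, genome = genome, pos = pos,
             valid = ok, stringsAsFactors = FALSE)
}

#' Write / read a genotype matrix as CSV
#'
#' Plain CSV, lines in rows, first column \code{line_id}, remaining columns
#' one per marker (header = marker IDs).
#'
#' @param geno a \code{genotype_matrix}.
#' @param path file path.
#' @return \code{read_genotype_csv} returns a \code{genotype_matrix};
#'   \code{write_genotype_csv} returns \code{path} invisibly.
#' @export
write_genotype_csv <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  df <- data.frame(line_id = rownames(geno$dosage), geno$dosage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_genotype_csv
#' @export
read_genotype_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"line_id" %in% names(df)) stop("genotype CSV must have a line_id column")
  ids <- as.character(df$line_id)
  keep <- names(df) != "line_id"
  d <- as.matrix(df[, keep, drop = FALSE])
  if (!is.numeric(d)) stop("non-numeric dosages in genotype CSV")
  colnames(d) <- names(df)[keep]  # as.matrix mangles duplicated names
  rownames(d) <- ids
  genotype_matrix(d)
}

#' Write a minimal VCF for an inbred-line genotype matrix
#'
#' Dosage 0 is written as 0/0, dosage 2 as 1/1, dosage 1 as 0/1 (REF is the
#' major allele, ALT the minor allele; actual nucleotides are not tracked,
#' so placeholder A/T alleles are emitted).  Intended for interoperability
#' checks, not as the primary interchange format.
#'
#' @param geno a \code{genotype_matrix}.
#' @param path output path (plain text, uncompressed).
#' @return \code{path}, invisibly.
#' @export
write_genotype_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  d <- geno$dosage
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=breedgain",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(d)), collapse = "\t")), con)
  gt <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(d))) {
    calls <- gt[d[, j] + 1L]
    writeLines(paste(c(geno$map$chrom[j], format(geno$map$pos[j],
                                                 scientific = FALSE),
                       geno$map$marker[j], "A", "T", ".", "PASS", ".", "GT",
                       calls), collapse = "\t"), con)
  }
  invisible(path)
}
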