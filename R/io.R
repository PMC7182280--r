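# Plain-text readers and writers for the three input formats: LD matrices,
# genotype dosage matrices, haplotype tables, and summary statistics.

#' Read / write an LD matrix file
#'
#' Whitespace- or tab-delimited square numeric matrix, with an optional
#' single header row of SNP identifiers. \code{writeLDMatrix} emits
#' tab-separated values with 10 significant digits, so a write/read cycle
#' round-trips the printed representation exactly.
#'
#' @param file path.
#' @param x an \code{\linkS4class{LDMatrix}} (writer).
#' @return \code{readLDMatrix}: an \code{LDMatrix}. \code{writeLDMatrix}:
#'   invisibly, the file path.
#' @examples
#' f <- tempfile()
#' writeLDMatrix(equicorrLD(3, 0.5, labels = paste0("rs", 1:3)), f)
#' readLDMatrix(f)
#' @export
readLDMatrix <- function(file) {
  first <- scan(file, what = "character", nlines = 1, quiet = TRUE)
  header <- all(is.na(suppressWarnings(as.numeric(first))))
  m <- as.matrix(utils::read.table(file, header = header,
                                   check.names = FALSE))
  labels <- if (header) colnames(m) else NULL
  rownames(m) <- colnames(m) <- labels
  LDMatrix(m, labels = labels)
}

#' @rdname readLDMatrix
#' @export
writeLDMatrix <- function(x, file) {
  m <- unclass(as.matrix(x))
  txt <- apply(m, 1, function(r) paste(signif(r, 10), collapse = "\t"))
  if (!is.null(colnames(m)))
    txt <- c(paste(colnames(m), collapse = "\t"), txt)
  writeLines(txt, file)
  invisible(file)
}

#' Read a genotype dosage matrix
#'
#' TSV with a header row of SNP identifiers; rows are individuals and
#' entries are allele dosages 0/1/2.
#'
#' @param file path.
#' @return numeric matrix (individuals x SNPs).
#' @export
readGenotypeMatrix <- function(file) {
  d <- utils::read.delim(file, check.names = FALSE)
  m <- as.matrix(d)
  if (!is.numeric(m)) stop("genotype matrix must be numeric")
  bad <- !(m %in% c(0, 1, 2) | is.na(m))
  if (any(bad)) stop("genotype entries must be 0, 1 or 2")
  m
}

#' Read a haplotype frequency table
#'
#' TSV with columns \code{haplotype} (string over 0/1; 1 = minor allele) and
#' \code{frequency}.
#'
#' @param file path.
#' @return A \code{\linkS4class{HaplotypeTable}}.
#' @export
readHaplotypeTable <- function(file) {
  d <- utils::read.delim(file, colClasses = c(haplotype = "character"))
  if (!all(c("haplotype", "frequency") %in% names(d)))
    stop("haplotype table needs columns 'haplotype' and 'frequency'")
  HaplotypeTable(d$haplotype, d$frequency)
}

#' Read GWAS summary statistics
#'
#' TSV with a header; required columns \code{SNP} and at least one of
#' \code{Z} or \code{P}; optional \code{CHR}, \code{POS}, \code{SIGN}.
#' Unknown columns are preserved. When both Z and P are present, Z takes
#' precedence and consistency of the two-sided P with |Z| is checked (a
#' mismatch beyond 1e-6 warns). When only P is given, Z-scores are derived
#' by \code{\link{pvaluesToZ}} using SIGN if available.
#'
#' @param file path.
#' @return data.frame with at least columns \code{SNP} and \code{Z}.
#' @export
readSumStats <- function(file) {
  d <- utils::read.delim(file, check.names = FALSE)
  if (!"SNP" %in% names(d)) stop("summary statistics need an 'SNP' column")
  if (anyDuplicated(d$SNP)) stop("duplicate SNP identifiers")
  hasZ <- "Z" %in% names(d)
  hasP <- "P" %in% names(d)
  if (!hasZ && !hasP) stop("need a 'Z' or 'P' column")
  if (hasP && (any(d$P <= 0) || any(d$P > 1)))
    stop("P-values must lie in (0, 1]")
  if (hasZ && any(!is.finite(d$Z))) stop("Z-scores must be finite")
  if (hasZ && hasP) {
    p2 <- 2 * stats::pnorm(-abs(d$Z))
    if (any(abs(p2 - d$P) > 1e-6))
      warning("Z and P columns disagree beyond 1e-6 for ",
              sum(abs(p2 - d$P) > 1e-6), " SNPs; using Z")
  }
  if (!hasZ) {
    signs <- if ("SIGN" %in% names(d)) d$SIGN else NULL
    d$Z <- zScores(pvaluesToZ(d$P, signs = signs))
  }
  d
}
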