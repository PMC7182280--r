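#' Select an anchor-SNP LD block
#'
#' Collects the SNPs whose LD correlation with a previously reported risk
#' ("anchor") variant is at least \code{threshold} in absolute value
#' (|r| is used because the sign of r flips with allele coding), preserving
#' their order in the LD matrix, and extracts the restricted submatrix.
#'
#' @param R \code{\linkS4class{LDMatrix}} with SNP labels.
#' @param anchor anchor SNP identifier.
#' @param threshold minimum |r| with the anchor, in (0, 1]; threshold 0
#'   returns the whole region.
#' @return A \code{\linkS4class{GeneBlock}}.
#' @examples
#' R <- equicorrLD(4, 0.3, labels = paste0("rs", 1:4))
#' anchorBlock(R, "rs2", threshold = 0.25)
#' @export
anchorBlock <- function(R, anchor, threshold = 0.25) {
  labels <- rownames(R)
  if (is.null(labels)) stop("LD matrix must carry SNP labels")
  if (!anchor %in% labels)
    stop("anchor '", anchor, "' not found; available: ",
         paste(utils::head(labels, 20), collapse = ", "),
         if (length(labels) > 20) ", ..." else "")
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  r <- unclass(as.matrix(R))[, anchor]
  keep <- labels[abs(r) >= threshold | labels == anchor]
  sub <- unclass(as.matrix(R))[keep, keep, drop = FALSE]
  new("GeneBlock", anchor = anchor, members = keep, threshold = threshold,
      ld = .as_corr(sub, keep))
}

# Align a summary-statistic table to a block; returns the Z vector in block
# member order.
.block_z <- function(stats, block) {
  if (is.character(stats) && length(stats) == 1L) stats <- readSumStats(stats)
  miss <- setdiff(block@members, stats$SNP)
  if (length(miss))
    stop("block SNPs absent from the summary statistics: ",
         paste(miss, collapse = ", "))
  z <- stats$Z[match(block@members, stats$SNP)]
  names(z) <- block@members
  z
}

#' Gene-level association tests on an anchor block
#'
#' Applies the requested combination methods to the block's Z-scores and LD.
#' P-value-only inputs are converted by \code{\link{pvaluesToZ}} inside
#' \code{\link{readSumStats}}. ACAT and min-P work from the two-sided
#' per-SNP P-values; DOT, TQ and RTP use the Z-scores and block LD.
#'
#' @param stats summary-statistic data.frame (from \code{readSumStats}) or a
#'   file path.
#' @param block a \code{\linkS4class{GeneBlock}}.
#' @param methods subset of "dot", "tq", "acat", "minp", "rtp".
#' @param rtpK truncation rank for RTP (default: half the block, at least 1).
#' @param nNull null replicates for the RTP reference distribution.
#' @param seed RNG seed for RTP.
#' @return Named list of \code{\linkS4class{AssocTest}} objects.
#' @examples
#' R <- equicorrLD(3, 0.4, labels = paste0("rs", 1:3))
#' st <- data.frame(SNP = paste0("rs", 1:3), Z = c(2.5, 1.2, -0.3))
#' geneTest(st, anchorBlock(R, "rs1", 0.25))
#' @export
geneTest <- function(stats, block,
                     methods = c("dot", "tq", "acat", "minp"),
                     rtpK = NULL, nNull = 1e4, seed = NULL) {
  methods <- match.arg(methods, c("dot", "tq", "acat", "minp", "rtp"),
                       several.ok = TRUE)
  z <- .block_z(stats, block)
  R <- block@ld
  chk <- .validate_corr(R)
  if (!isTRUE(chk))
    stop("block LD is not usable (", chk, "); if it came from a reference ",
         "panel, the panel may be too small for this block")
  p <- 2 * stats::pnorm(-abs(z))
  out <- list()
  for (m in methods) {
    out[[m]] <- switch(m,
      dot = dotTest(z, R),
      tq = tqTest(z, R),
      acat = acatTest(p),
      minp = minpTest(p),
      rtp = rtpTest(z, R, k = if (is.null(rtpK))
        max(1L, length(z) %/% 2L) else rtpK, nNull = nNull, seed = seed))
  }
  out
}

#' Top-contributor SNP decomposition of the DOT statistic
#'
#' DOT = sum_i X_i^2 with X = H Z; each decorrelated component is itself a
#' linear combination X_i = sum_j h_ij Z_j of the original SNP statistics.
#' Ranking components by X_i^2 (ties broken by lower index) and decomposing
#' the top ones into their per-SNP terms h_ij Z_j identifies which SNPs
#' carry a gene's signal. Terms sharing the component's sign and, by
#' default, at least 25% of the largest |term| are flagged as selected
#' contributors.
#'
#' @param stats summary statistics (data.frame or file path).
#' @param block a \code{\linkS4class{GeneBlock}}.
#' @param nComponents how many top components to decompose.
#' @param termFraction selection cutoff as a fraction of the largest
#'   same-sign |term| within a component.
#' @return data.frame with columns component (rank), x (component value),
#'   snp, term (h_ij Z_j), sameSign, selected; rows ordered by rank and
#'   descending |term|.
#' @examples
#' R <- equicorrLD(3, 0.4, labels = paste0("rs", 1:3))
#' st <- data.frame(SNP = paste0("rs", 1:3), Z = c(3.5, 0.4, -0.2))
#' topContributors(st, anchorBlock(R, "rs1", 0.25), nComponents = 2)
#' @export
topContributors <- function(stats, block, nComponents = 3,
                            termFraction = 0.25) {
  z <- .block_z(stats, block)
  L <- length(z)
  nComponents <- min(nComponents, L)
  H <- transformMatrix(decorrelationTransform(block@ld))
  terms <- H * rep(z, each = L)          # terms[i, j] = h_ij * z_j
  x <- rowSums(terms)
  ord <- order(x^2, decreasing = TRUE)   # stable: ties keep lower index
  out <- do.call(rbind, lapply(seq_len(nComponents), function(rank) {
    i <- ord[rank]
    tr <- terms[i, ]
    same <- sign(tr) == sign(x[i])
    sel <- same & abs(tr) >= termFraction * max(abs(tr[same]))
    o <- order(abs(tr), decreasing = TRUE)
    data.frame(component = rank, x = x[i], snp = block@members[o],
               term = tr[o], sameSign = same[o], selected = sel[o],
               row.names = NULL)
  }))
  out
}

#' Scan configured genes: blocks, tests, contributors
#'
#' End-to-end workflow over a set of genes: for each configured gene an
#' anchor block is selected from the LD matrix, all requested combination
#' methods are applied, and the top-contributor SNPs are extracted.
#' Failures in one gene are caught, reported, and do not stop the scan.
#'
#' @param sumstats summary statistics: data.frame or TSV path.
#' @param ld LD matrix: \code{LDMatrix} or file path.
#' @param genes list of per-gene configurations, each a list with
#'   \code{label}, \code{anchor} and optionally \code{threshold},
#'   \code{methods}, \code{nComponents}; or a YAML file path with a
#'   top-level \code{genes} list.
#' @param outPrefix if non-NULL, writes \code{<prefix>.genes.tsv} (one row
#'   per gene: gene, L, and one P-value column per method) and
#'   \code{<prefix>.contributors.tsv}.
#' @return Named list of \code{\linkS4class{GeneReport}} objects.
#' @examples
#' R <- equicorrLD(3, 0.4, labels = paste0("rs", 1:3))
#' st <- data.frame(SNP = paste0("rs", 1:3), Z = c(2.5, 1.2, -0.3))
#' scanGenes(st, R, list(list(label = "G1", anchor = "rs1")))
#' @export
scanGenes <- function(sumstats, ld, genes, outPrefix = NULL) {
  if (is.character(sumstats)) sumstats <- readSumStats(sumstats)
  if (is.character(ld)) ld <- readLDMatrix(ld)
  if (is.character(genes)) genes <- yaml::read_yaml(genes)$genes
  reports <- list()
  for (g in genes) {
    label <- g$label
    rep_g <- tryCatch({
      block <- anchorBlock(ld, g$anchor,
                           threshold = if (is.null(g$threshold)) 0.25
                           else g$threshold)
      methods <- if (is.null(g$methods)) c("dot", "tq", "acat", "minp")
        else g$methods
      res <- geneTest(sumstats, block, methods = methods)
      contrib <- topContributors(sumstats, block,
                                 nComponents = if (is.null(g$nComponents)) 3
                                 else g$nComponents)
      new("GeneReport", gene = label, block = block, results = res,
          contributors = contrib)
    }, error = function(e) {
      warning("gene ", label, " skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(rep_g)) reports[[label]] <- rep_g
  }
  if (!is.null(outPrefix)) .write_scan(reports, outPrefix)
  reports
}

.write_scan <- function(reports, prefix) {
  gene_rows <- lapply(reports, function(r) {
    ps <- vapply(r@results, pValue, numeric(1))
    cbind(data.frame(gene = r@gene, L = length(r@block@members)),
          as.data.frame(as.list(stats::setNames(ps, paste0("p_", names(ps))))))
  })
  genes_df <- if (length(gene_rows)) do.call(rbind, gene_rows) else
    data.frame(gene = character(), L = integer())
  utils::write.table(genes_df, paste0(prefix, ".genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  contrib_rows <- lapply(reports, function(r)
    cbind(gene = r@gene, r@contributors))
  contrib_df <- if (length(contrib_rows)) do.call(rbind, contrib_rows) else
    data.frame(gene = character())
  utils::write.table(contrib_df, paste0(prefix, ".contributors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
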