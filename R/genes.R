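#' Assign markers or windows to a flanked gene span
#'
#' A gene's territory is its annotated span plus `flank` bp on each side
#' (default 50 kb). A point item (marker) is assigned when its position lies
#' inside the flanked span, boundaries inclusive; an interval item (window)
#' when it overlaps the flanked span by at least 1 bp.
#'
#' @param gene one-row data.frame (or list) with `chrom`, `start`, `end`.
#' @param item_chrom chromosome per item.
#' @param item_start item position (markers) or span start (windows).
#' @param item_end span end; defaults to `item_start` for point items.
#' @param flank bp added on each side of the gene.
#' @return integer vector of assigned item indices.
#' @export
assign_items_to_gene <- function(gene, item_chrom, item_start,
                                 item_end = item_start, flank = 50000L) {
  lo <- gene$start - flank
  hi <- gene$end + flank
  which(item_chrom == gene$chrom & item_end >= lo & item_start <= hi)
}

#' Most extreme statistic within a gene
#'
#' @param values statistic values of the items assigned to one gene.
#' @param tail `"upper"` (max is most significant, e.g. branch length) or
#'   `"lower"` (min, e.g. lnRH).
#' @return the extreme value, or `NA` when no defined item is assigned.
#' @export
gene_extreme_statistic <- function(values, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  values <- values[!is.na(values)]
  if (!length(values)) return(NA_real_)
  if (tail == "upper") max(values) else min(values)
}

#' Per-gene extreme statistics for all genes
#'
#' Vectorized scoring: every gene receives the most extreme value among the
#' items falling in its 50-kb-flanked span, plus item and significant-item
#' counts (mirroring per-gene supplementary scan tables).
#'
#' @param genes a [gene_table()].
#' @param item_chrom,item_start,item_end item coordinates as in
#'   [assign_items_to_gene()].
#' @param values statistic per item.
#' @param flags optional logical significance per item (empirical 5% tail).
#' @param tail extreme direction, see [gene_extreme_statistic()].
#' @param flank bp flank per side.
#' @return data.frame: `gene_id`, `pathway_tag`, `n_items`, `n_significant`,
#'   `extreme_value` (`NA` when a gene has no defined item).
#' @export
gene_scores <- function(genes, item_chrom, item_start, item_end = item_start,
                        values, flags = NULL, tail = c("upper", "lower"),
                        flank = 50000L) {
  tail <- match.arg(tail)
  g <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1L, genes$start - flank), genes$end + flank))
  it <- GenomicRanges::GRanges(item_chrom,
                               IRanges::IRanges(item_start, item_end))
  hits <- GenomicRanges::findOverlaps(g, it)
  gi <- S4Vectors::queryHits(hits)
  ii <- S4Vectors::subjectHits(hits)
  n_genes <- nrow(genes)
  ext <- rep(NA_real_, n_genes)
  n_items <- integer(n_genes)
  n_sig <- integer(n_genes)
  if (length(gi)) {
    spl <- split(ii, gi)
    idx <- as.integer(names(spl))
    n_items[idx] <- lengths(spl)
    ext[idx] <- vapply(spl, function(j) gene_extreme_statistic(values[j], tail),
                       numeric(1))
    if (!is.null(flags))
      n_sig[idx] <- vapply(spl, function(j) sum(flags[j], na.rm = TRUE),
                           integer(1))
  }
  data.frame(gene_id = genes$gene_id, pathway_tag = genes$pathway_tag,
             n_items = n_items, n_significant = n_sig, extreme_value = ext,
             stringsAsFactors = FALSE)
}

#' Empirical cutoffs of the per-gene null distribution
#'
#' The per-gene null is the distribution of each gene's most extreme
#' statistic across every scored gene in the dataset; a candidate gene is
#' called against this null rather than against the per-marker distribution,
#' which corrects for gene length and marker density. Cutoffs use the same
#' `round_half_up(alpha * N)` prefix rule as the marker-level scan.
#'
#' @param scores per-gene extreme values (`NA` = unscored, excluded).
#' @param tail extreme direction.
#' @param min_genes minimum defined scores required (default 20).
#' @return list with `cutoff_05`, `cutoff_01` (the least extreme score still
#'   inside each tail; `NA` when the prefix is empty) and `n`.
#' @export
gene_null_cutoffs <- function(scores, tail = c("upper", "lower"),
                              min_genes = 20L) {
  tail <- match.arg(tail)
  ok <- scores[!is.na(scores)]
  if (length(ok) < min_genes)
    stop("need >= ", min_genes, " scored genes for a per-gene null (got ",
         length(ok), ")")
  n <- length(ok)
  srt <- sort(ok, decreasing = (tail == "upper"))
  cutoff_at <- function(alpha) {
    m <- significant_count(n, alpha)
    if (m < 1) NA_real_ else srt[m]
  }
  list(cutoff_05 = cutoff_at(0.05), cutoff_01 = cutoff_at(0.01), n = n)
}

#' Flag candidate genes against the genome-wide per-gene null
#'
#' Ranks all scored genes, flags the alpha prefix (ties by block-maximum
#' rank, so a score exactly at the cutoff is flagged as part of its block
#' only if the whole block fits the prefix), and returns the subset of
#' pathway genes. Pathway genes without a score are reported as unscored
#' rather than dropped.
#'
#' @param score_table data.frame from [gene_scores()].
#' @param pathway_ids gene ids of the pathway of interest; default all genes.
#' @param tail extreme direction.
#' @return `score_table` rows for the pathway, with `rank`, `p_e`,
#'   `flag_05`, `flag_01`, `unscored` columns added.
#' @export
nominate_candidate_genes <- function(score_table, pathway_ids = NULL,
                                     tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  rk <- rank_and_p(score_table$extreme_value, tail, "genes")
  out <- cbind(score_table,
               rank = rk$rank, p_e = rk$p_e,
               flag_05 = flag_significant(rk, 0.05),
               flag_01 = flag_significant(rk, 0.01),
               unscored = is.na(score_table$extreme_value))
  if (!is.null(pathway_ids))
    out <- out[out$gene_id %in% pathway_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-sided Kolmogorov-Smirnov pathway-enrichment test
#'
#' Tests whether the pathway's statistic distribution is shifted toward high
#' values relative to the non-pathway background:
#' \eqn{D^+ = \sup_x [F_{background}(x) - F_{pathway}(x)]}, with the
#' asymptotic one-sided p-value \eqn{\exp(-2 D^2 nm/(n+m))} capped at 1.
#' A pathway stochastically *smaller* than background gives D = 0, p = 1.
#'
#' @param pathway_values statistic values of pathway items.
#' @param background_values values of non-pathway items (must exclude the
#'   pathway items).
#' @return list with `d` (the one-sided statistic), `p`, `n_pathway`,
#'   `n_background`.
#' @export
ks_pathway_test <- function(pathway_values, background_values) {
  x <- pathway_values[!is.na(pathway_values)]
  y <- background_values[!is.na(background_values)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  pts <- sort(unique(c(x, y)))
  n <- length(x); m <- length(y)
  d <- max(0, findInterval(pts, sort(y)) / m - findInterval(pts, sort(x)) / n)
  p <- min(1, exp(-2 * d^2 * n * m / (n + m)))
  list(d = d, p = p, n_pathway = n, n_background = m)
}
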