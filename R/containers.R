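#' altsweep: multi-statistic selection scans for a focal population
#'
#' Tools for detecting recent positive selection in one focal population
#' contrasted with two reference populations: per-SNP locus-specific branch
#' lengths from pairwise Weir-Cockerham FST, sliding-window lnRH and
#' standardized-difference-of-Tajima's-D statistics, a long-range-haplotype
#' (EHH/REHH) scan with gamma-tail significance, empirical outlier p-values,
#' hypergeometric clustering of significant loci into megabase regions, and
#' gene/pathway ranking against a per-gene extreme-value null. A forward-time
#' Wright-Fisher simulator generates three-population sweep data with truth
#' labels for end-to-end validation.
#'
#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib altsweep, .registration = TRUE
#' @importFrom stats ave pgamma phyper rbinom rpois runif sd setNames rgamma
#' @importFrom utils head tail
#' @name altsweep-package
#' @keywords internal
"_PACKAGE"

VALID_ANCESTRAL <- c("ref", "alt", "unknown")
VALID_MARKER_CLASS <- c("snp", "cnp")
VALID_PATHWAY_TAGS <- c("HIF", "RAS", "globin", "none")

#' Construct a marker table
#'
#' A marker table is the per-marker map shared by every panel in an analysis:
#' one row per biallelic marker (SNP or biallelic copy-number polymorphism),
#' with 1-based positions following the VCF convention. Positions must be
#' strictly increasing within each chromosome.
#'
#' @param marker_id character vector of unique marker identifiers.
#' @param chrom character vector of chromosome labels.
#' @param pos integer vector of 1-based positions.
#' @param allele_ref,allele_alt reference / alternate allele strings; must
#'   differ at every marker.
#' @param ancestral which allele is ancestral: `"ref"`, `"alt"` or
#'   `"unknown"` (recycled).
#' @param marker_class `"snp"` or `"cnp"` (recycled). Biallelic CNPs are
#'   carried through every statistic exactly like SNPs.
#' @return A `data.frame` of class `marker_table`.
#' @export
marker_table <- function(marker_id, chrom, pos, allele_ref, allele_alt,
                         ancestral = "unknown", marker_class = "snp") {
  n <- length(marker_id)
  mt <- data.frame(
    marker_id = as.character(marker_id),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    allele_ref = as.character(allele_ref),
    allele_alt = as.character(allele_alt),
    ancestral = rep_len(as.character(ancestral), n),
    marker_class = rep_len(as.character(marker_class), n),
    stringsAsFactors = FALSE
  )
  class(mt) <- c("marker_table", "data.frame")
  validate_marker_table(mt)
}

validate_marker_table <- function(mt) {
  stopifnot(is.data.frame(mt))
  if (anyDuplicated(mt$marker_id))
    stop("duplicated marker ids: ",
         paste(head(mt$marker_id[duplicated(mt$marker_id)], 3), collapse = ", "))
  if (any(mt$allele_ref == mt$allele_alt))
    stop("ref and alt alleles identical at marker(s): ",
         paste(head(mt$marker_id[mt$allele_ref == mt$allele_alt], 3), collapse = ", "))
  bad_anc <- !mt$ancestral %in% VALID_ANCESTRAL
  if (any(bad_anc))
    stop("invalid ancestral codes: ", paste(unique(mt$ancestral[bad_anc]), collapse = ", "))
  bad_cls <- !mt$marker_class %in% VALID_MARKER_CLASS
  if (any(bad_cls))
    stop("invalid marker_class codes: ", paste(unique(mt$marker_class[bad_cls]), collapse = ", "))
  for (ch in unique(mt$chrom)) {
    p <- mt$pos[mt$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions not strictly increasing on ", ch)
  }
  mt
}

#' Construct a diploid genotype panel
#'
#' Genotypes are coded as alt-allele dosages 0/1/2 with `NA` for missing
#' calls; missing data are never imputed. Columns align with a
#' [marker_table()].
#'
#' @param population_label single population name.
#' @param sample_ids character vector, one per row of `genotypes`.
#' @param genotypes samples x markers integer matrix with entries in
#'   `{0, 1, 2, NA}`.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(population_label, sample_ids, genotypes) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  dimnames(genotypes) <- NULL
  if (nrow(genotypes) != length(sample_ids))
    stop("genotype row count must equal number of samples")
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) && (min(vals) < 0L || max(vals) > 2L))
    stop("genotype entries must be 0, 1, 2 or NA")
  structure(
    list(population_label = as.character(population_label),
         sample_ids = as.character(sample_ids),
         genotypes = genotypes,
         ploidy = 2L),
    class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %s: %d samples x %d markers (%.2f%% missing)\n",
              x$population_label, nrow(x$genotypes), ncol(x$genotypes),
              100 * mean(is.na(x$genotypes))))
  invisible(x)
}

#' Construct a phased haplotype panel
#'
#' Two rows per sample (haplotype rows `2i - 1` and `2i` belong to sample
#' `i`), alleles coded 0 (ref) / 1 (alt) with `NA` for missing.
#'
#' @param population_label single population name.
#' @param haplotypes (2 x samples) x markers matrix with entries `{0, 1, NA}`.
#' @param sample_ids character vector of length `nrow(haplotypes) / 2`.
#' @param phased logical flag; the long-range-haplotype scan requires `TRUE`.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(population_label, haplotypes, sample_ids = NULL,
                            phased = TRUE) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  dimnames(haplotypes) <- NULL
  if (nrow(haplotypes) %% 2L != 0L)
    stop("haplotype matrix must have an even number of rows (2 per sample)")
  vals <- haplotypes[!is.na(haplotypes)]
  if (length(vals) && (min(vals) < 0L || max(vals) > 1L))
    stop("haplotype entries must be 0, 1 or NA")
  if (is.null(sample_ids))
    sample_ids <- paste0("S", seq_len(nrow(haplotypes) / 2L))
  if (length(sample_ids) != nrow(haplotypes) / 2L)
    stop("need one sample id per haplotype pair")
  structure(
    list(population_label = as.character(population_label),
         haplotypes = haplotypes,
         sample_ids = as.character(sample_ids),
         phased = isTRUE(phased)),
    class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %s: %d haplotypes x %d markers (phased=%s)\n",
              x$population_label, nrow(x$haplotypes), ncol(x$haplotypes),
              x$phased))
  invisible(x)
}

#' Collapse a haplotype panel to diploid genotypes
#'
#' Sums haplotype pairs into alt-allele dosages; a pair with any missing
#' allele collapses to a missing genotype.
#'
#' @param hpanel a [haplotype_panel()].
#' @return A [genotype_panel()] with one row per sample.
#' @export
collapse_haplotypes <- function(hpanel) {
  stopifnot(inherits(hpanel, "haplotype_panel"))
  h <- hpanel$haplotypes
  idx1 <- seq(1L, nrow(h), by = 2L)
  g <- h[idx1, , drop = FALSE] + h[idx1 + 1L, , drop = FALSE]
  genotype_panel(hpanel$population_label, hpanel$sample_ids, g)
}

#' Construct a gene annotation table
#'
#' Gene spans use 1-based inclusive coordinates internally. Each gene carries
#' a pathway tag from the fixed set `HIF` (hypoxia-inducible-factor pathway),
#' `RAS` (renin-angiotensin system), `globin`, or `none`.
#'
#' @param gene_id character vector of unique gene ids.
#' @param chrom chromosome labels.
#' @param start,end 1-based inclusive span; `start <= end` required.
#' @param pathway_tag pathway membership (recycled; default `"none"`).
#' @return A `data.frame` of class `gene_table`.
#' @export
gene_table <- function(gene_id, chrom, start, end, pathway_tag = "none") {
  n <- length(gene_id)
  gt <- data.frame(
    gene_id = as.character(gene_id),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    pathway_tag = rep_len(as.character(pathway_tag), n),
    stringsAsFactors = FALSE
  )
  if (any(gt$start > gt$end))
    stop("gene start > end for: ",
         paste(head(gt$gene_id[gt$start > gt$end], 3), collapse = ", "))
  bad <- !gt$pathway_tag %in% VALID_PATHWAY_TAGS
  if (any(bad))
    stop("invalid pathway tags: ", paste(unique(gt$pathway_tag[bad]), collapse = ", "))
  class(gt) <- c("gene_table", "data.frame")
  gt
}

# subset a marker table + aligned panels by a logical/integer marker index
subset_markers <- function(markers, panels, keep) {
  mt <- markers[keep, , drop = FALSE]
  rownames(mt) <- NULL
  class(mt) <- c("marker_table", "data.frame")
  panels <- lapply(panels, function(p) {
    if (inherits(p, "genotype_panel")) {
      genotype_panel(p$population_label, p$sample_ids,
                     p$genotypes[, keep, drop = FALSE])
    } else {
      haplotype_panel(p$population_label, p$haplotypes[, keep, drop = FALSE],
                      p$sample_ids, p$phased)
    }
  })
  list(markers = mt, panels = panels)
}
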