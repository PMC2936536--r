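#' Read a two-column sample-to-population map
#'
#' @param path TSV file with a header line naming columns `sample` and
#'   `population`.
#' @return data.frame with columns `sample`, `population`.
#' @export
read_sample_map <- function(path) {
  sm <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE,
                          colClasses = "character")
  if (!all(c("sample", "population") %in% names(sm)))
    stop("sample map must have columns 'sample' and 'population'")
  if (anyDuplicated(sm$sample))
    stop("duplicated sample ids in sample map")
  sm[, c("sample", "population")]
}

#' Write a sample-to-population map
#'
#' @param panels list of [genotype_panel()] or [haplotype_panel()] objects.
#' @param path output TSV path.
#' @export
write_sample_map <- function(panels, path) {
  sm <- do.call(rbind, lapply(panels, function(p)
    data.frame(sample = p$sample_ids, population = p$population_label,
               stringsAsFactors = FALSE)))
  data.table::fwrite(sm, path, sep = "\t")
  invisible(path)
}

# parse a GT character matrix (markers x samples) into alt dosages;
# returns list(dosage, phased_matrix)
parse_gt_matrix <- function(gt, path) {
  gt <- as.matrix(gt)
  miss <- grepl(".", gt, fixed = TRUE)
  ok <- grepl("^[01][/|][01]$", gt)
  bad <- which(!ok & !miss)
  if (length(bad)) {
    line <- ((bad[1] - 1) %% nrow(gt)) + 1
    stop("malformed genotype '", gt[bad[1]], "' at record ", line,
         " of ", path)
  }
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  dos[ok] <- (substr(gt[ok], 1, 1) == "1") + (substr(gt[ok], 3, 3) == "1")
  phased <- matrix(FALSE, nrow(gt), ncol(gt))
  phased[ok] <- substr(gt[ok], 2, 2) == "|"
  list(dosage = dos, phased = phased, called = ok)
}

# shared VCF ingestion: returns markers (sorted), per-sample dosage and
# haplotype matrices, phased flags, skipped multi-allelic count
read_vcf_core <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  multi <- n_alt != 1L
  n_skipped <- sum(multi)
  if (n_skipped > 0) {
    message("skipping ", n_skipped, " multi-allelic record(s)")
    vcf <- vcf[!multi, ]
    alt <- VariantAnnotation::alt(vcf)
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  ref_a <- as.character(VariantAnnotation::ref(vcf))
  alt_a <- as.character(unlist(alt))
  anc <- rep("unknown", length(ref_a))
  if ("AA" %in% names(info)) {
    aa <- as.character(info$AA)
    anc[!is.na(aa) & aa == ref_a] <- "ref"
    anc[!is.na(aa) & aa == alt_a] <- "alt"
  }
  mclass <- rep("snp", length(ref_a))
  if ("MC" %in% names(info)) {
    mc <- as.character(info$MC)
    mclass[!is.na(mc) & mc %in% VALID_MARKER_CLASS] <- mc[!is.na(mc) & mc %in% VALID_MARKER_CLASS]
  }
  mclass[startsWith(alt_a, "<")] <- "cnp"
  mt <- data.frame(
    marker_id = names(rr), chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr), allele_ref = ref_a, allele_alt = alt_a,
    ancestral = anc, marker_class = mclass, stringsAsFactors = FALSE)
  ord <- order(mt$chrom, mt$pos)
  gt <- VariantAnnotation::geno(vcf)$GT[ord, , drop = FALSE]
  mt <- mt[ord, , drop = FALSE]
  parsed <- parse_gt_matrix(gt, path)
  mt <- marker_table(mt$marker_id, mt$chrom, mt$pos, mt$allele_ref,
                     mt$allele_alt, mt$ancestral, mt$marker_class)
  list(markers = mt, gt = gt, parsed = parsed,
       samples = colnames(gt), n_skipped = n_skipped)
}

split_into_panels <- function(dosage, samples, sample_map, path) {
  sm <- if (is.character(sample_map)) read_sample_map(sample_map) else sample_map
  absent <- setdiff(sm$sample, samples)
  if (length(absent))
    stop("sample(s) in map absent from ", path, ": ",
         paste(head(absent, 5), collapse = ", "))
  extra <- setdiff(samples, sm$sample)
  if (length(extra))
    message("dropping ", length(extra), " sample(s) not in the population map")
  lapply(split(sm$sample, sm$population), function(ids) {
    genotype_panel(sm$population[match(ids[1], sm$sample)], ids,
                   t(dosage[, match(ids, samples), drop = FALSE]))
  })
}

#' Read diploid genotypes for one or more populations
#'
#' Ingests a VCF 4.x file or the package's transposed tab-separated genotype
#' dialect (markers as rows; columns `marker_id`, `chrom`, `pos`,
#' `allele_ref`, `allele_alt`, `ancestral`, optional `marker_class`, then one
#' 0/1/2/NA dosage column per sample). Multi-allelic VCF records are skipped
#' with a message; markers are sorted by chromosome and position.
#'
#' @param path input file.
#' @param sample_map path to a sample map TSV (see [read_sample_map()]) or an
#'   equivalent data.frame assigning each sample to a population.
#' @param format `"vcf"` or `"tsv"`.
#' @return list with elements `markers` ([marker_table()]), `panels` (named
#'   list of [genotype_panel()], one per population) and `n_skipped`.
#' @export
read_genotypes <- function(path, sample_map, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") {
    core <- read_vcf_core(path)
    panels <- split_into_panels(core$parsed$dosage, core$samples, sample_map, path)
    return(list(markers = core$markers, panels = panels,
                n_skipped = core$n_skipped))
  }
  tab <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE,
                           na.strings = c("NA", "."))
  fixed <- c("marker_id", "chrom", "pos", "allele_ref", "allele_alt", "ancestral")
  if (!all(fixed %in% names(tab)))
    stop("genotype TSV must start with columns: ", paste(fixed, collapse = ", "))
  mclass <- if ("marker_class" %in% names(tab)) tab$marker_class else "snp"
  sample_cols <- setdiff(names(tab), c(fixed, "marker_class"))
  ord <- order(tab$chrom, tab$pos)
  tab <- tab[ord, , drop = FALSE]
  mclass <- rep_len(mclass, nrow(tab))[ord]
  mt <- marker_table(tab$marker_id, tab$chrom, tab$pos, tab$allele_ref,
                     tab$allele_alt, tab$ancestral, mclass)
  dosage <- as.matrix(tab[, sample_cols, drop = FALSE])
  storage.mode(dosage) <- "integer"
  bad <- which(!is.na(dosage) & !(dosage %in% 0:2))
  if (length(bad)) {
    line <- ((bad[1] - 1) %% nrow(dosage)) + 1
    stop("malformed genotype value at record ", line, " of ", path)
  }
  panels <- split_into_panels(dosage, sample_cols, sample_map, path)
  list(markers = mt, panels = panels, n_skipped = 0L)
}

#' Read phased haplotypes
#'
#' Reads a VCF whose GT fields all use the phased `|` separator, or the
#' transposed haplotype TSV dialect (marker columns as in the genotype TSV,
#' then two columns `<sample>_1`, `<sample>_2` per sample holding 0/1/NA
#' alleles). Any unphased diploid record is an error: the long-range
#' haplotype scan needs known phase.
#'
#' @inheritParams read_genotypes
#' @return list with `markers`, `panels` (named list of [haplotype_panel()])
#'   and `n_skipped`.
#' @export
read_haplotypes <- function(path, sample_map, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  sm <- if (is.character(sample_map)) read_sample_map(sample_map) else sample_map
  if (format == "vcf") {
    core <- read_vcf_core(path)
    unph <- core$parsed$called & !core$parsed$phased
    if (any(unph)) {
      rec <- which(rowSums(unph) > 0)[1]
      stop("unphased genotype at record ", rec, " of ", path,
           " ('", core$gt[unph][1], "'): phased input required")
    }
    g1 <- matrix(NA_integer_, nrow(core$gt), ncol(core$gt))
    g2 <- g1
    ok <- core$parsed$called
    g1[ok] <- as.integer(substr(core$gt[ok], 1, 1))
    g2[ok] <- as.integer(substr(core$gt[ok], 3, 3))
    samples <- core$samples
    markers <- core$markers
    n_skipped <- core$n_skipped
  } else {
    tab <- data.table::fread(path, header = TRUE, sep = "\t",
                             data.table = FALSE, na.strings = c("NA", "."))
    fixed <- c("marker_id", "chrom", "pos", "allele_ref", "allele_alt", "ancestral")
    if (!all(fixed %in% names(tab)))
      stop("haplotype TSV must start with columns: ", paste(fixed, collapse = ", "))
    mclass <- if ("marker_class" %in% names(tab)) tab$marker_class else "snp"
    hap_cols <- setdiff(names(tab), c(fixed, "marker_class"))
    if (!all(grepl("_[12]$", hap_cols)))
      stop("haplotype columns must be named <sample>_1 / <sample>_2")
    ord <- order(tab$chrom, tab$pos)
    tab <- tab[ord, , drop = FALSE]
    mclass <- rep_len(mclass, length(ord))[ord]
    markers <- marker_table(tab$marker_id, tab$chrom, tab$pos, tab$allele_ref,
                            tab$allele_alt, tab$ancestral, mclass)
    samples <- unique(sub("_[12]$", "", hap_cols))
    g1 <- as.matrix(tab[, paste0(samples, "_1"), drop = FALSE])
    g2 <- as.matrix(tab[, paste0(samples, "_2"), drop = FALSE])
    storage.mode(g1) <- "integer"; storage.mode(g2) <- "integer"
    n_skipped <- 0L
  }
  absent <- setdiff(sm$sample, samples)
  if (length(absent))
    stop("sample(s) in map absent from ", path, ": ",
         paste(head(absent, 5), collapse = ", "))
  panels <- lapply(split(sm$sample, sm$population), function(ids) {
    idx <- match(ids, samples)
    h <- matrix(NA_integer_, 2L * length(ids), nrow(markers))
    h[seq(1, 2 * length(ids), 2), ] <- t(g1[, idx, drop = FALSE])
    h[seq(2, 2 * length(ids), 2), ] <- t(g2[, idx, drop = FALSE])
    haplotype_panel(sm$population[match(ids[1], sm$sample)], h, ids, TRUE)
  })
  list(markers = markers, panels = panels, n_skipped = n_skipped)
}

#' Read gene annotations from a BED-like file
#'
#' Columns: chrom, start, end (0-based half-open, per BED), gene id, and an
#' optional 5th column with a pathway tag (`HIF`, `RAS`, `globin`; anything
#' absent defaults to `none`). Coordinates are converted to the package's
#' 1-based inclusive convention on read.
#'
#' @param path BED file, no header.
#' @return A [gene_table()].
#' @export
read_gene_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- data.table::fread(path, header = FALSE, data.table = FALSE,
                           fill = TRUE, colClasses = list(character = 1))
  if (ncol(tab) < 4) stop("gene BED needs at least 4 columns")
  if (any(tab[[2]] >= tab[[3]])) {
    bad <- which(tab[[2]] >= tab[[3]])[1]
    stop("start >= end at line ", bad, " of ", path)
  }
  tag <- if (ncol(tab) >= 5) as.character(tab[[5]]) else "none"
  tag[is.na(tag) | tag == ""] <- "none"
  gene_table(tab[[4]], tab[[1]], tab[[2]] + 1L, tab[[3]], tag)
}

#' Write gene annotations as BED
#'
#' Internal 1-based inclusive spans are converted back to BED 0-based
#' half-open coordinates.
#'
#' @param genes a [gene_table()].
#' @param path output path.
#' @export
write_gene_bed <- function(genes, path) {
  data.table::fwrite(
    data.frame(genes$chrom, genes$start - 1L, genes$end, genes$gene_id,
               genes$pathway_tag),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

marker_info_string <- function(markers) {
  aa <- ifelse(markers$ancestral == "ref", markers$allele_ref,
               ifelse(markers$ancestral == "alt", markers$allele_alt, NA))
  ifelse(is.na(aa), paste0("MC=", markers$marker_class),
         paste0("AA=", aa, ";MC=", markers$marker_class))
}

vcf_header_lines <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##source=altsweep",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##INFO=<ID=MC,Number=1,Type=String,Description=\"Marker class (snp or cnp)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

#' Write genotype panels to a VCF file
#'
#' Emits unphased diploid GT fields; ancestral alleles go to the `AA` INFO
#' tag and the marker class to `MC`, so a read/write round trip is lossless.
#'
#' @param markers a [marker_table()].
#' @param panels list of [genotype_panel()] aligned to `markers`.
#' @param path output path.
#' @export
write_genotypes_vcf <- function(markers, panels, path) {
  gt_of <- c("0/0", "0/1", "1/1")
  cols <- lapply(panels, function(p) {
    m <- matrix("./.", ncol(p$genotypes), nrow(p$genotypes))
    g <- t(p$genotypes)
    m[!is.na(g)] <- gt_of[g[!is.na(g)] + 1L]
    m
  })
  body <- cbind(markers$chrom, markers$pos, markers$marker_id,
                markers$allele_ref, markers$allele_alt, ".", "PASS",
                marker_info_string(markers), "GT", do.call(cbind, cols))
  samples <- unlist(lapply(panels, `[[`, "sample_ids"), use.names = FALSE)
  writeLines(c(vcf_header_lines(samples),
               apply(body, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' Write phased haplotype panels to a VCF file
#'
#' @param markers a [marker_table()].
#' @param panels list of [haplotype_panel()] aligned to `markers`.
#' @param path output path.
#' @export
write_haplotypes_vcf <- function(markers, panels, path) {
  cols <- lapply(panels, function(p) {
    h <- p$haplotypes
    i1 <- seq(1, nrow(h), 2)
    a1 <- t(h[i1, , drop = FALSE]); a2 <- t(h[i1 + 1L, , drop = FALSE])
    m <- matrix("./.", nrow(a1), ncol(a1))
    ok <- !is.na(a1) & !is.na(a2)
    m[ok] <- paste0(a1[ok], "|", a2[ok])
    m
  })
  body <- cbind(markers$chrom, markers$pos, markers$marker_id,
                markers$allele_ref, markers$allele_alt, ".", "PASS",
                marker_info_string(markers), "GT", do.call(cbind, cols))
  samples <- unlist(lapply(panels, `[[`, "sample_ids"), use.names = FALSE)
  writeLines(c(vcf_header_lines(samples),
               apply(body, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' Write genotype panels to the transposed TSV dialect
#'
#' @inheritParams write_genotypes_vcf
#' @export
write_genotypes_tsv <- function(markers, panels, path) {
  out <- as.data.frame(markers)
  for (p in panels) {
    g <- as.data.frame(t(p$genotypes))
    names(g) <- p$sample_ids
    out <- cbind(out, g)
  }
  data.table::fwrite(out, path, sep = "\t", na = "NA")
  invisible(path)
}

#' Write haplotype panels to the transposed TSV dialect
#'
#' Two columns `<sample>_1`, `<sample>_2` per sample.
#'
#' @inheritParams write_haplotypes_vcf
#' @export
write_haplotypes_tsv <- function(markers, panels, path) {
  out <- as.data.frame(markers)
  for (p in panels) {
    h <- p$haplotypes
    i1 <- seq(1, nrow(h), 2)
    g <- as.data.frame(matrix(NA_integer_, ncol(h), nrow(h)))
    g[, seq(1, nrow(h), 2)] <- t(h[i1, , drop = FALSE])
    g[, seq(2, nrow(h), 2)] <- t(h[i1 + 1L, , drop = FALSE])
    names(g)[seq(1, nrow(h), 2)] <- paste0(p$sample_ids, "_1")
    names(g)[seq(2, nrow(h), 2)] <- paste0(p$sample_ids, "_2")
    out <- cbind(out, g)
  }
  data.table::fwrite(out, path, sep = "\t", na = "NA")
  invisible(path)
}
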