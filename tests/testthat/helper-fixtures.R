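# Hand-written toy fixtures (built in code at test time) ------------------

toy_gt <- matrix(c(  # 5 markers x 6 samples, alt dosages
  0L, 1L, 2L, 0L, 1L, 2L,
  0L, 0L, 1L, 1L, 2L, 2L,
  2L, 2L, 2L, 0L, 0L, 0L,
  0L, 1L, 0L, 1L, 0L, 1L,
  1L, 1L, NA, 0L, 2L, 0L
), nrow = 5, byrow = TRUE)

toy_samples <- c("A1", "A2", "B1", "B2", "C1", "C2")

toy_vcf_lines <- function(phased = FALSE, triallelic = FALSE,
                          unphased_row = NA) {
  sep <- if (phased) "|" else "/"
  gt_of <- c(paste0("0", sep, "0"), paste0("0", sep, "1"),
             paste0("1", sep, "1"))
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"AA\">",
           "##INFO=<ID=MC,Number=1,Type=String,Description=\"MC\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", toy_samples), collapse = "\t"))
  ref <- c("A", "C", "G", "T", "A")
  alt <- c("G", "T", "A", "C", "T")
  pos <- c(100L, 250L, 400L, 550L, 700L)
  body <- vapply(1:5, function(i) {
    gts <- ifelse(is.na(toy_gt[i, ]), paste0(".", sep, "."),
                  gt_of[toy_gt[i, ] + 1L])
    if (!is.na(unphased_row) && i == unphased_row && phased)
      gts[1] <- sub("\\|", "/", gts[1])
    paste(c("chr1", pos[i], paste0("s", i), ref[i], alt[i], ".", "PASS",
            paste0("AA=", ref[i], ";MC=snp"), "GT", gts), collapse = "\t")
  }, "")
  if (triallelic) {
    tri <- paste(c("chr1", "320", "s_tri", "A", "G,T", ".", "PASS", "MC=snp",
                   "GT", rep(paste0("0", sep, "0"), 6)), collapse = "\t")
    body <- append(body, tri, after = 2)
  }
  c(hdr, body)
}

write_toy_vcf <- function(path, ...) {
  writeLines(toy_vcf_lines(...), path)
  path
}

toy_sample_map <- function() {
  data.frame(sample = toy_samples,
             population = rep(c("popA", "popB", "popC"), each = 2),
             stringsAsFactors = FALSE)
}

# quick single-population panel from a markers x samples dosage matrix
quick_panel <- function(g, label = "pop") {
  genotype_panel(label, paste0(label, seq_len(ncol(g))), t(g))
}

# markers evenly spaced on one chromosome
quick_markers <- function(n, chrom = "chr1", spacing = 1000L,
                          ancestral = "ref") {
  marker_table(paste0("m", seq_len(n)), chrom, seq_len(n) * spacing,
               "A", "G", ancestral)
}

small_sim_config <- function(.seed, ...) {
  defaults <- list(seed = .seed, n_e = 50L, t1 = 60L, t2 = 30L, burn_in = 20L,
                   chrom_lengths = c(chr1 = 3e5),
                   sample_sizes = c(highland = 15L, lowland = 15L,
                                    outgroup = 15L))
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
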