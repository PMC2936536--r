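test_that("toy VCF reads into three aligned population panels", {
  vcf <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"))
  got <- read_genotypes(vcf, toy_sample_map(), format = "vcf")
  expect_equal(nrow(got$markers), 5)
  expect_named(got$panels, c("popA", "popB", "popC"))
  expect_equal(got$markers$pos, c(100L, 250L, 400L, 550L, 700L))
  expect_equal(got$markers$ancestral, rep("ref", 5))
  expect_equal(unname(got$panels$popA$genotypes[, 1]), c(0L, 1L))
  expect_equal(unname(got$panels$popC$genotypes[1, ]),
               c(1L, 2L, 0L, 0L, 2L))  # sample C1 across markers
  expect_true(is.na(got$panels$popB$genotypes[1, 5]))
})

test_that("multi-allelic records are skipped with a count", {
  vcf <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"),
                       triallelic = TRUE)
  expect_message(got <- read_genotypes(vcf, toy_sample_map()),
                 "multi-allelic")
  expect_equal(nrow(got$markers), 5)
  expect_equal(got$n_skipped, 1L)
  expect_false("s_tri" %in% got$markers$marker_id)
})

test_that("sample-map mismatches error; extras are dropped", {
  vcf <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"))
  bad <- rbind(toy_sample_map(),
               data.frame(sample = "ZZ", population = "popZ"))
  expect_error(read_genotypes(vcf, bad), "absent")
  expect_message(got <- read_genotypes(vcf, toy_sample_map()[-1, ]),
                 "dropping 1 sample")
  expect_equal(length(got$panels$popA$sample_ids), 1)
})

test_that("read -> write -> read round trip is identity (vcf and tsv)", {
  vcf <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"))
  got <- read_genotypes(vcf, toy_sample_map())
  for (fmt in c("vcf", "tsv")) {
    out <- withr::local_tempfile(fileext = paste0(".", fmt))
    if (fmt == "vcf") write_genotypes_vcf(got$markers, got$panels, out)
    else write_genotypes_tsv(got$markers, got$panels, out)
    back <- read_genotypes(out, toy_sample_map(), format = fmt)
    expect_equal(as.data.frame(back$markers), as.data.frame(got$markers))
    for (p in names(got$panels))
      expect_equal(unname(back$panels[[p]]$genotypes),
                   unname(got$panels[[p]]$genotypes), info = fmt)
  }
})

test_that("tsv and vcf dialects produce identical data", {
  vcf <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"))
  got <- read_genotypes(vcf, toy_sample_map())
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes_tsv(got$markers, got$panels, tsv)
  got2 <- read_genotypes(tsv, toy_sample_map(), format = "tsv")
  expect_equal(as.data.frame(got2$markers), as.data.frame(got$markers))
  expect_equal(lapply(got2$panels, `[[`, "genotypes"),
               lapply(got$panels, `[[`, "genotypes"))
})

test_that("phased haplotypes read as 2 rows per sample and collapse back", {
  vcf <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"), phased = TRUE)
  hap <- read_haplotypes(vcf, toy_sample_map())
  expect_equal(nrow(hap$panels$popA$haplotypes), 4)
  gen <- read_genotypes(vcf, toy_sample_map())
  for (p in names(hap$panels))
    expect_equal(collapse_haplotypes(hap$panels[[p]])$genotypes,
                 gen$panels[[p]]$genotypes)
  # haplotype tsv round trip
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_haplotypes_tsv(hap$markers, hap$panels, tsv)
  back <- read_haplotypes(tsv, toy_sample_map(), format = "tsv")
  expect_equal(lapply(back$panels, `[[`, "haplotypes"),
               lapply(hap$panels, `[[`, "haplotypes"))
})

test_that("unphased records are rejected when phase is required", {
  vcf <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"),
                       phased = TRUE, unphased_row = 3)
  expect_error(read_haplotypes(vcf, toy_sample_map()), "unphased")
})

test_that("gene BED coordinates convert to 1-based inclusive", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t999\t2000\tG1\tHIF",
               "chr1\t1500\t2500\tG2",
               "chr2\t0\t100\tG3\tnone"), bed)
  genes <- read_gene_annotations(bed)
  expect_equal(genes$start, c(1000L, 1501L, 1L))
  expect_equal(genes$end, c(2000L, 2500L, 100L))
  expect_equal(genes$pathway_tag, c("HIF", "none", "none"))
  expect_equal(nrow(genes), 3)  # overlapping genes both retained
  writeLines("chr1\t2000\t1000\tG1", bed)
  expect_error(read_gene_annotations(bed), "start >= end")
  # round trip through the writer
  bed2 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t999\t2000\tG1\tHIF", "chr1\t1500\t2500\tG2\tnone"), bed)
  g1 <- read_gene_annotations(bed)
  write_gene_bed(g1, bed2)
  expect_equal(read_gene_annotations(bed2), g1)
})

test_that("call-rate filter keeps >= 95% and is idempotent", {
  set.seed(1)
  g <- matrix(0L, 60, 49)  # 60 markers x 49 samples
  g[1, 1:3] <- NA   # 46/49 = 0.939 -> removed
  g[2, 1:2] <- NA   # 47/49 = 0.959 -> kept
  mk <- quick_markers(60)
  panel <- quick_panel(g, "p")
  suppressMessages(f <- filter_by_call_rate(list(panel), mk))
  expect_equal(f$n_removed, 1L)
  expect_false("m1" %in% f$markers$marker_id)
  expect_true("m2" %in% f$markers$marker_id)
  suppressMessages(f2 <- filter_by_call_rate(f$panels, f$markers))
  expect_equal(f2$n_removed, 0L)
  expect_equal(as.data.frame(f2$markers), as.data.frame(f$markers))
  # call rate exactly 0.95 is kept ("95% or greater"): 19/20 samples called
  g20 <- matrix(0L, 1, 20); g20[1, 1] <- NA
  suppressMessages(
    f3 <- filter_by_call_rate(list(quick_panel(g20, "q")), quick_markers(1)))
  expect_equal(f3$n_removed, 0L)
  expect_error(filter_by_call_rate(list(panel), mk, population_set = character()),
               "empty")
})

test_that("chromosome classes partition markers; Y/MT dropped", {
  mk <- marker_table(paste0("m", 1:6),
                     c("chr1", "chr1", "chrX", "chr2", "chrY", "chrM"),
                     c(10L, 20L, 10L, 10L, 10L, 10L), "A", "G")
  expect_message(sp <- split_by_chromosome_class(mk), "Y/mitochondrial")
  expect_equal(sp$autosomal, c(1L, 2L, 4L))
  expect_equal(sp$x, 3L)
  expect_equal(sp$dropped, c(5L, 6L))
  expect_length(intersect(sp$autosomal, sp$x), 0)
  expect_setequal(c(sp$autosomal, sp$x, sp$dropped), 1:6)
  bad <- marker_table("m1", "scaffold_7", 5L, "A", "G")
  expect_error(split_by_chromosome_class(bad), "scaffold_7")
  noX <- marker_table("m1", "chr1", 5L, "A", "G")
  expect_length(split_by_chromosome_class(noX)$x, 0)
})

test_that("container invariants are enforced", {
  expect_error(marker_table(c("a", "a"), "chr1", c(1L, 2L), "A", "G"),
               "duplicated")
  expect_error(marker_table("a", "chr1", 1L, "A", "A"), "identical")
  expect_error(marker_table(c("a", "b"), "chr1", c(5L, 5L), "A", "G"),
               "increasing")
  expect_error(genotype_panel("p", "s1", matrix(3L, 1, 1)), "0, 1, 2")
  expect_error(haplotype_panel("p", matrix(0L, 3, 2)), "even")
  expect_error(gene_table("g", "chr1", 10L, 5L), "start > end")
  expect_error(gene_table("g", "chr1", 1L, 5L, "WNT"), "invalid pathway")
})
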