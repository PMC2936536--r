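test_that("identical seeds give bit-identical simulations", {
  a <- simulate_three_populations(small_sim_config(21))
  b <- simulate_three_populations(small_sim_config(21))
  expect_identical(a$markers, b$markers)
  expect_identical(lapply(a$genotypes, `[[`, "genotypes"),
                   lapply(b$genotypes, `[[`, "genotypes"))
  expect_identical(lapply(a$haplotypes, `[[`, "haplotypes"),
                   lapply(b$haplotypes, `[[`, "haplotypes"))
  c <- simulate_three_populations(small_sim_config(22))
  expect_false(identical(a$genotypes$highland$genotypes,
                         c$genotypes$highland$genotypes))
})

test_that("haplotypes and genotypes are mutually consistent", {
  sim <- simulate_three_populations(small_sim_config(23))
  for (p in names(sim$genotypes)) {
    expect_identical(collapse_haplotypes(sim$haplotypes[[p]])$genotypes,
                     sim$genotypes[[p]]$genotypes)
    h <- sim$haplotypes[[p]]$haplotypes
    expect_true(all(h %in% c(0L, 1L, NA)))
  }
  expect_s3_class(sim$markers, "marker_table")
  expect_equal(sim$markers$ancestral, rep("ref", nrow(sim$markers)))
})

test_that("missing data is injected near the configured rate", {
  sim <- simulate_three_populations(small_sim_config(24, missing_rate = 0.1))
  miss <- mean(is.na(sim$genotypes$highland$genotypes))
  expect_gt(miss, 0.05)
  expect_lt(miss, 0.15)
  none <- simulate_three_populations(small_sim_config(25, missing_rate = 0))
  expect_false(anyNA(none$genotypes$highland$genotypes))
})

test_that("sweep truth is recorded and the focal allele is swept", {
  sim <- simulate_three_populations(small_sim_config(26, s = 0.15, t2 = 50L))
  expect_true(sim$truth$sweep)
  fi <- match(sim$truth$focal_marker, sim$markers$marker_id)
  expect_false(is.na(fi))
  expect_equal(sim$markers$pos[fi], sim$truth$focal_pos)
  expect_gt(sim$truth$final_daf[["highland"]],
            sim$truth$final_daf[["lowland"]])
  neutral <- simulate_three_populations(small_sim_config(27))
  expect_false(neutral$truth$sweep)
})

test_that("neutral replicates are centered: lnRH and the D difference", {
  stats <- sapply(1:10, function(sd) {
    cfg <- small_sim_config(4300 + sd, chrom_lengths = c(chr1 = 5e5))
    sim <- simulate_three_populations(cfg)
    grid <- make_windows(cfg$chrom_lengths)
    rh <- window_lnrh(sim$genotypes$highland, sim$genotypes$lowland,
                      sim$markers, grid)
    dh <- tajimas_d(sim$genotypes$highland, sim$markers, grid)
    dl <- tajimas_d(sim$genotypes$lowland, sim$markers, grid)
    c(lnrh = mean(rh$lnrh, na.rm = TRUE),
      ddiff = mean(dh$d - dl$d, na.rm = TRUE))
  })
  expect_lt(abs(mean(stats["lnrh", ])), 0.5)
  expect_lt(abs(mean(stats["ddiff", ])), 0.5)
})

test_that("annotation track tiles genes and tags the sweep target", {
  cfg <- sim_config(seed = 28, chrom_lengths = c(chr1 = 1e6))
  sim <- simulate_three_populations(cfg)
  ann <- generate_annotation_track(sim$markers, cfg)
  expect_equal(nrow(ann$genes), 20)  # 1 Mb / (20 kb + 30 kb)
  expect_true(all(ann$genes$end - ann$genes$start + 1L == 20000L))
  expect_true(is.na(ann$true_gene))
  expect_equal(sum(ann$genes$pathway_tag == "HIF"), cfg$n_hif)
  expect_equal(sum(ann$genes$pathway_tag == "RAS"), cfg$n_ras)
  expect_equal(sum(ann$genes$pathway_tag == "globin"), cfg$n_globin)
  # sweep: exactly one HIF gene contains the focal marker
  cfg2 <- small_sim_config(29, s = 0.15, t2 = 50L)
  sim2 <- simulate_three_populations(cfg2)
  ann2 <- generate_annotation_track(sim2$markers, cfg2, sim2$truth)
  tg <- ann2$genes[ann2$genes$gene_id == ann2$true_gene, ]
  expect_equal(tg$pathway_tag, "HIF")
  expect_true(tg$start <= sim2$truth$focal_pos &&
                tg$end >= sim2$truth$focal_pos)
  # zero pathway sizes -> all tags none
  cfg3 <- sim_config(seed = 30, chrom_lengths = c(chr1 = 1e6),
                     n_hif = 0L, n_ras = 0L, n_globin = 0L)
  ann3 <- generate_annotation_track(sim$markers, cfg3)
  expect_true(all(ann3$genes$pathway_tag == "none"))
  expect_error(generate_annotation_track(
    sim$markers, sim_config(seed = 1, chrom_lengths = c(chr1 = 1e4))),
    "too short")
})

test_that("an X-labelled chromosome flows through the class split", {
  cfg <- small_sim_config(31, chrom_lengths = c(chr1 = 2e5, chrX = 1e5))
  sim <- simulate_three_populations(cfg)
  sp <- split_by_chromosome_class(sim$markers)
  expect_gt(length(sp$x), 0)
  expect_equal(length(sp$autosomal) + length(sp$x), nrow(sim$markers))
})

test_that("fixture sets are complete, reproducible and guarded", {
  dir <- withr::local_tempdir()
  sim <- simulate_three_populations(small_sim_config(32))
  man <- write_fixture_set(sim, dir)
  expect_setequal(man$file,
                  c("genotypes.vcf", "genotypes.tsv", "haplotypes.vcf",
                    "sample_map.tsv", "genes.bed", "truth.json",
                    "config.json"))
  expect_true(all(file.exists(file.path(dir, man$file))))
  expect_error(write_fixture_set(sim, dir), "manifest")
  # same seed, fresh directory -> identical checksums
  dir2 <- withr::local_tempdir()
  sim2 <- simulate_three_populations(small_sim_config(32))
  man2 <- write_fixture_set(sim2, dir2)
  expect_equal(man$md5, man2$md5)
  # the emitted files read back into the same panels
  got <- read_genotypes(file.path(dir, "genotypes.vcf"),
                        file.path(dir, "sample_map.tsv"))
  expect_equal(got$panels$highland$genotypes,
               sim$genotypes$highland$genotypes,
               ignore_attr = TRUE)
  hap <- read_haplotypes(file.path(dir, "haplotypes.vcf"),
                         file.path(dir, "sample_map.tsv"))
  expect_equal(nrow(hap$panels$highland$haplotypes),
               nrow(sim$haplotypes$highland$haplotypes))
})
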