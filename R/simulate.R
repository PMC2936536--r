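#' Configuration for the three-population sweep simulator
#'
#' The simulated world emulates an array-genotyping study of one highland
#' (focal) population against a close lowland reference and a more distant
#' outgroup: three Wright-Fisher populations related by two splits, a marker
#' lattice of common biallelic variants (about one per 3 kb), baseline
#' between-population differentiation of order 0.05-0.15, high call rates,
#' and optionally one focal variant under additive selection in the highland
#' branch only.
#'
#' @param seed integer random seed; identical seeds give identical output.
#' @param n_e diploid effective size per population (default 500).
#' @param t1 generations ago of the outgroup split (default 300).
#' @param t2 generations ago of the highland/lowland split (default 150;
#'   must be `< t1`). Under pure drift the expected highland-lowland FST is
#'   `1 - (1 - 1/(2 n_e))^t2`.
#' @param s additive selection coefficient on the focal derived allele in
#'   the highland population (genotype fitnesses 1, 1+s, 1+2s); 0 = neutral.
#' @param chrom_lengths named vector of chromosome lengths in bp (name a
#'   chromosome `"chrX"` to exercise the separate-X analysis path).
#' @param marker_spacing mean bp between markers (default 3000).
#' @param recomb_rate per-bp per-generation crossover probability (default
#'   2e-7, which preserves a human-like population recombination rate
#'   4*N_e*r of about 4e-4 per bp at the rescaled N_e).
#' @param sample_sizes named vector: diploid samples drawn per population.
#' @param missing_rate per-genotype missing probability (default 0.02, so
#'   the 95% call-rate filter is exercised but removes few markers).
#' @param burn_in generations of within-pool evolution before the first
#'   split, to build linkage disequilibrium (default 100).
#' @param freq_range ancestral derived-allele frequency truncation (default
#'   `c(0.05, 0.95)`, mimicking array-ascertained common variants).
#' @param ascertain_maf optional minor-allele-frequency floor applied to the
#'   pooled final sample, re-creating array ascertainment (0 = off).
#' @param sweep_init_range root-population frequency window from which the
#'   focal standing variant is picked when `s > 0`; rare in the root, hence
#'   rare in the outgroup, so the sweep signal is highland-specific.
#' @param max_retries highland-branch re-draws allowed if the focal allele
#'   is lost (default 10).
#' @param gene_size,gene_gap,n_hif,n_ras,n_globin annotation-track tiling
#'   and pathway-set sizes used by [generate_annotation_track()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed, n_e = 500L, t1 = 300L, t2 = 150L, s = 0,
                       chrom_lengths = c(chr1 = 2.5e6),
                       marker_spacing = 3000L, recomb_rate = 2e-7,
                       sample_sizes = c(highland = 50L, lowland = 50L,
                                        outgroup = 50L),
                       missing_rate = 0.02, burn_in = 100L,
                       freq_range = c(0.05, 0.95), ascertain_maf = 0,
                       sweep_init_range = c(0.05, 0.10), max_retries = 10L,
                       gene_size = 20000L, gene_gap = 30000L,
                       n_hif = 8L, n_ras = 2L, n_globin = 3L) {
  stopifnot(t2 < t1, n_e >= 2, marker_spacing > 0, recomb_rate >= 0,
            s >= 0, missing_rate >= 0, missing_rate < 1,
            length(sample_sizes) == 3, !is.null(names(chrom_lengths)))
  structure(as.list(environment()), class = "sim_config")
}

# Internal haplotype pools are markers x haplotypes (column-major friendly:
# a haplotype is one contiguous column). Haplotype columns 2i-1, 2i belong
# to individual i. The per-generation loop lives in C++ (src/wf.cpp).
evolve_pop <- function(H, gens, n_e, cx_mean, pos, len, s = 0, focal = NA) {
  f <- if (is.na(focal)) -1L else as.integer(focal) - 1L
  res <- wf_evolve_cpp(H, as.integer(gens), cx_mean, as.numeric(pos),
                       as.numeric(len), s, f)
  structure(res$H, lost = res$lost)
}

# simulate one chromosome; sweep at `focal` marker (index) if s > 0
simulate_chromosome <- function(cfg, len, n_markers, sweep_here) {
  pos <- as.integer((seq_len(n_markers) - 1L) * ((len %/% n_markers)) +
                      sample.int(len %/% n_markers, n_markers, replace = TRUE))
  grid <- seq(cfg$freq_range[1], cfg$freq_range[2], by = 0.005)
  p0 <- sample(grid, n_markers, replace = TRUE, prob = 1 / grid)
  n2 <- 2L * cfg$n_e
  H <- matrix(rbinom(n_markers * n2, 1L, rep(p0, times = n2)), n_markers, n2)
  cx_mean <- cfg$recomb_rate * len
  H <- evolve_pop(H, cfg$burn_in, cfg$n_e, cx_mean, pos, len)

  # outgroup splits t1 generations ago
  H_out <- evolve_pop(H, cfg$t1, cfg$n_e, cx_mean, pos, len)
  # shared highland/lowland ancestor until t2
  H_anc <- evolve_pop(H, cfg$t1 - cfg$t2, cfg$n_e, cx_mean, pos, len)

  focal <- NA_integer_
  if (sweep_here && cfg$s > 0) {
    # the adaptive variant is standing variation that is rare in the root
    # population (so it is rare in the outgroup too) and still segregating
    # in the highland/lowland ancestor at sweep onset; it must sit inside a
    # tiled gene span, near mid-chromosome
    root_freq <- rowMeans(H)
    anc_freq <- rowMeans(H_anc)
    pitch <- cfg$gene_size + cfg$gene_gap
    in_gene <- ((pos - 1L) %% pitch) < cfg$gene_size
    cand <- which(root_freq >= cfg$sweep_init_range[1] &
                    root_freq <= cfg$sweep_init_range[2] &
                    anc_freq > 0 & in_gene)
    if (!length(cand)) stop("no standing variant available for the sweep")
    focal <- cand[which.min(abs(pos[cand] - len / 2))]
  }

  H_low <- evolve_pop(H_anc, cfg$t2, cfg$n_e, cx_mean, pos, len)
  H_high <- evolve_pop(H_anc, cfg$t2, cfg$n_e, cx_mean, pos, len,
                       s = cfg$s, focal = focal)
  tries <- 0L
  while (isTRUE(attr(H_high, "lost")) && tries < cfg$max_retries) {
    tries <- tries + 1L
    H_high <- evolve_pop(H_anc, cfg$t2, cfg$n_e, cx_mean, pos, len,
                         s = cfg$s, focal = focal)
  }
  if (isTRUE(attr(H_high, "lost")))
    stop("focal allele lost in all ", cfg$max_retries, " highland re-draws")
  list(pos = pos, focal = focal,
       pools = list(highland = H_high, lowland = H_low, outgroup = H_out))
}

#' Simulate three populations with an optional highland sweep
#'
#' Discrete-generation Wright-Fisher evolution with recombination on a
#' marker lattice. An ancestral pool with derived-allele frequencies drawn
#' from a truncated 1/x (neutral-spectrum-shaped) grid evolves for a burn-in
#' period; the outgroup splits `t1` generations ago, the highland/lowland
#' pair `t2` generations ago, and additive selection acts on one focal
#' standing variant in the highland branch only. No new mutations arise: the
#' lattice mimics array-ascertained common variants. Allele 0 is the
#' ancestral (root) state at every marker.
#'
#' @param cfg a [sim_config()].
#' @return list with `markers` ([marker_table()]), `genotypes` /
#'   `haplotypes` (named lists of panels for highland, lowland, outgroup),
#'   `truth` (focal marker, per-population final derived-allele frequencies,
#'   sweep flag) and `config`.
#' @export
simulate_three_populations <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  bases <- c("A", "C", "G", "T")
  chroms <- names(cfg$chrom_lengths)
  per_chrom <- lapply(seq_along(chroms), function(ci) {
    len <- cfg$chrom_lengths[[ci]]
    n_markers <- max(2L, as.integer(len %/% cfg$marker_spacing))
    simulate_chromosome(cfg, len, n_markers, sweep_here = (ci == 1L))
  })
  pops <- c("highland", "lowland", "outgroup")
  n_tot <- sum(vapply(per_chrom, function(x) length(x$pos), integer(1)))

  # marker table (allele 0 = ancestral = ref)
  ref <- sample(bases, n_tot, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  mt <- marker_table(
    marker_id = sprintf("mk%06d", seq_len(n_tot)),
    chrom = rep(chroms, vapply(per_chrom, function(x) length(x$pos), integer(1))),
    pos = unlist(lapply(per_chrom, `[[`, "pos"), use.names = FALSE),
    allele_ref = ref, allele_alt = alt, ancestral = "ref")

  haps <- list(); genos <- list()
  for (p in pops) {
    n_samp <- cfg$sample_sizes[[p]]
    hmat <- matrix(0L, 2L * n_samp, n_tot)
    off <- 0L
    for (pc in per_chrom) {
      pool <- pc$pools[[p]]
      idx <- sample.int(ncol(pool) / 2L, n_samp)
      cols <- as.vector(rbind(2L * idx - 1L, 2L * idx))
      hmat[, off + seq_len(nrow(pool))] <- t(pool[, cols, drop = FALSE])
      off <- off + nrow(pool)
    }
    if (cfg$missing_rate > 0) {
      miss <- matrix(runif(n_samp * n_tot) < cfg$missing_rate, n_samp, n_tot)
      big <- miss[rep(seq_len(n_samp), each = 2L), , drop = FALSE]
      hmat[big] <- NA_integer_
    }
    ids <- sprintf("%s%03d", toupper(substr(p, 1, 1)), seq_len(n_samp))
    haps[[p]] <- haplotype_panel(p, hmat, ids, phased = TRUE)
    genos[[p]] <- collapse_haplotypes(haps[[p]])
  }

  keep <- rep(TRUE, n_tot)
  if (cfg$ascertain_maf > 0) {
    pooled <- do.call(rbind, lapply(haps, `[[`, "haplotypes"))
    p_all <- colMeans(pooled, na.rm = TRUE)
    keep <- pmin(p_all, 1 - p_all) >= cfg$ascertain_maf
    sub <- subset_markers(mt, c(haps, genos), keep)
    mt <- sub$markers
    haps <- sub$panels[seq_along(haps)]
    genos <- sub$panels[length(haps) + seq_along(genos)]
  }

  focal_global <- NA_integer_
  if (cfg$s > 0) {
    fi <- per_chrom[[1]]$focal  # chromosome 1 index == global index pre-filter
    focal_global <- if (keep[fi]) sum(keep[seq_len(fi)]) else NA_integer_
  }
  truth <- list(
    sweep = cfg$s > 0,
    focal_marker = if (!is.na(focal_global)) mt$marker_id[focal_global] else NA,
    focal_chrom = if (!is.na(focal_global)) mt$chrom[focal_global] else NA,
    focal_pos = if (!is.na(focal_global)) mt$pos[focal_global] else NA,
    final_daf = if (!is.na(focal_global))
      vapply(haps, function(h)
        mean(h$haplotypes[, focal_global], na.rm = TRUE), numeric(1))
    else NULL)
  list(markers = mt, genotypes = genos, haplotypes = haps, truth = truth,
       config = cfg)
}

#' Synthetic gene annotation track with pathway tags
#'
#' Tiles each simulated chromosome with non-overlapping genes (`gene_size`
#' bp separated by `gene_gap` bp, anchored at position 1) and assigns
#' pathway tags, mirroring a study design with a hypoxia-response (HIF)
#' pathway, a small renin-angiotensin (RAS) set and a globin family. When a
#' sweep was simulated, the gene containing the focal marker is tagged HIF
#' and recorded as the true target.
#'
#' @param markers the simulated [marker_table()].
#' @param cfg the [sim_config()] used.
#' @param truth the `truth` element returned by
#'   [simulate_three_populations()] (optional; enables target tagging).
#' @return list with `genes` (a [gene_table()]) and `true_gene` (gene id or
#'   `NA`).
#' @export
generate_annotation_track <- function(markers, cfg, truth = NULL) {
  pitch <- cfg$gene_size + cfg$gene_gap
  rows <- list()
  for (ch in names(cfg$chrom_lengths)) {
    len <- cfg$chrom_lengths[[ch]]
    starts <- seq(1L, len, by = pitch)
    starts <- starts[starts + cfg$gene_size - 1L <= len]
    if (!length(starts)) stop("chromosome ", ch, " too short for one gene")
    rows[[ch]] <- data.frame(chrom = ch, start = as.integer(starts),
                             end = as.integer(starts + cfg$gene_size - 1L))
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  tab$gene_id <- sprintf("gene%03d", seq_len(nrow(tab)))
  tab$pathway_tag <- "none"
  true_gene <- NA_character_
  if (!is.null(truth) && isTRUE(truth$sweep) && !is.na(truth$focal_pos)) {
    hit <- which(tab$chrom == truth$focal_chrom &
                   tab$start <= truth$focal_pos & tab$end >= truth$focal_pos)
    if (length(hit) != 1L)
      stop("focal marker does not fall inside exactly one tiled gene")
    tab$pathway_tag[hit] <- "HIF"
    true_gene <- tab$gene_id[hit]
  }
  free <- which(tab$pathway_tag == "none")
  want <- c(HIF = cfg$n_hif - sum(tab$pathway_tag == "HIF"),
            RAS = cfg$n_ras, globin = cfg$n_globin)
  for (tag in names(want)) {
    k <- min(want[[tag]], length(free))
    if (k > 0) {
      # deterministic, evenly spaced assignment: same config -> same track
      pick <- free[unique(round(seq(1, length(free), length.out = k)))]
      tab$pathway_tag[pick] <- tag
      free <- setdiff(free, pick)
    }
  }
  genes <- gene_table(tab$gene_id, tab$chrom, tab$start, tab$end,
                      tab$pathway_tag)
  list(genes = genes, true_gene = true_gene)
}

#' Write a complete simulated fixture set
#'
#' Emits every input the pipeline consumes -- phased VCF, genotype VCF and
#' TSV, sample map, gene BED, truth JSON, config JSON -- plus a manifest
#' with MD5 checksums. Re-running with the same seed reproduces identical
#' checksums.
#'
#' @param sim result of [simulate_three_populations()].
#' @param dir output directory (created if absent).
#' @param overwrite allow replacing an existing manifest.
#' @return invisibly, the manifest as a data.frame.
#' @export
write_fixture_set <- function(sim, dir, overwrite = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest_path <- file.path(dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite)
    stop("manifest already exists in ", dir, "; use overwrite = TRUE")
  ann <- generate_annotation_track(sim$markers, sim$config, sim$truth)
  files <- c(genotypes_vcf = "genotypes.vcf", genotypes_tsv = "genotypes.tsv",
             haplotypes_vcf = "haplotypes.vcf", sample_map = "sample_map.tsv",
             genes_bed = "genes.bed", truth = "truth.json",
             config = "config.json")
  paths <- file.path(dir, files)
  names(paths) <- names(files)
  write_genotypes_vcf(sim$markers, sim$genotypes, paths["genotypes_vcf"])
  write_genotypes_tsv(sim$markers, sim$genotypes, paths["genotypes_tsv"])
  write_haplotypes_vcf(sim$markers, sim$haplotypes, paths["haplotypes_vcf"])
  write_sample_map(sim$genotypes, paths["sample_map"])
  write_gene_bed(ann$genes, paths["genes_bed"])
  jsonlite::write_json(c(sim$truth, list(true_gene = ann$true_gene)),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  cfg <- unclass(sim$config)
  jsonlite::write_json(cfg, paths["config"], auto_unbox = TRUE, digits = NA)
  manifest <- data.frame(file = unname(files),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  invisible(manifest)
}
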