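test_that("derived-allele frequency respects ancestral coding", {
  mk <- marker_table(c("m1", "m2", "m3"), "chr1", c(1000L, 2000L, 3000L),
                     "A", "G", c("ref", "alt", "unknown"))
  h <- haplotype_panel("p", matrix(c(1L, 1L, 1L, 0L,
                                     1L, 1L, 1L, 0L,
                                     1L, 1L, 1L, 1L), 4, 3))
  daf <- derived_allele_frequency(h, mk)
  expect_equal(daf[1], 0.75)        # ancestral = ref, derived = alt
  expect_equal(daf[2], 0.25)        # ancestral = alt, derived = ref
  expect_true(is.na(daf[3]))        # unknown ancestral -> excluded
  g <- collapse_haplotypes(h)
  expect_equal(derived_allele_frequency(g, mk), daf)
  # the WGLRH filter is strictly > 0.85
  expect_true(0.86 > 0.85 && !(0.85 > 0.85))
})

test_that("core definition: spans, carriers, minimum frequency", {
  mk <- quick_markers(7)
  h4 <- haplotype_panel("p", matrix(1L, 4, 7))
  cores <- define_cores(h4, mk)
  expect_length(cores, 1)
  expect_equal(cores[[1]]$frequency, 1)
  expect_equal(cores[[1]]$carriers, 1:4)
  # {AAAAAAA x3, AAAAAAB x1}: only the 3-carrier core survives
  hm <- matrix(0L, 4, 7); hm[4, 7] <- 1L
  cores <- define_cores(haplotype_panel("p", hm), mk)
  expect_length(cores, 1)
  expect_equal(length(cores[[1]]$carriers), 3)
  expect_equal(cores[[1]]$frequency, 0.75)
  # fewer markers than the core size -> empty list
  expect_length(define_cores(haplotype_panel("p", matrix(1L, 4, 6)),
                             quick_markers(6)), 0)
  # rows with missing core alleles are dropped for that span
  hna <- matrix(1L, 6, 7); hna[1, 3] <- NA
  cores <- define_cores(haplotype_panel("p", hna), mk)
  expect_equal(cores[[1]]$carriers, 2:6)
})

test_that("EHH arithmetic and pair-enumeration oracle", {
  mk <- quick_markers(15)          # 1kb spacing; core = markers 1..7
  base <- matrix(0L, 4, 15)
  core <- list(chrom = "chr1", span = 1:7, start_pos = 1000L,
               end_pos = 7000L, string = "0000000", carriers = 1:4,
               frequency = 1)
  h <- haplotype_panel("p", base)
  expect_equal(ehh(core, h, mk, 0), 1)
  expect_equal(ehh(core, h, mk, 8000), 1)     # identical carriers
  # 4 carriers splitting 2 + 2 beyond the core
  sp <- base; sp[3:4, 8:15] <- 1L
  expect_equal(ehh(core, haplotype_panel("p", sp), mk, 8000), 1 / 3)
  # 2 carriers differing at the first flanking marker -> 0 beyond it
  two <- matrix(0L, 2, 15); two[2, 8] <- 1L
  core2 <- modifyList(core, list(carriers = 1:2))
  expect_equal(ehh(core2, haplotype_panel("p", two), mk, 1000), 0)
  # random panels vs exhaustive pair enumeration
  set.seed(14)
  for (i in 1:300) {
    nh <- sample(4:12, 1)
    hm <- matrix(rbinom(nh * 15, 1, 0.5), nh, 15)
    hm[sample(length(hm), 3)] <- NA
    hp <- haplotype_panel("p", hm[seq_len(2 * (nh %/% 2)), , drop = FALSE])
    carriers <- sort(sample(seq_len(2 * (nh %/% 2)), sample(3:4, 1)))
    co <- modifyList(core, list(carriers = carriers))
    d <- sample(c(2000, 5000, 8000), 1)
    ext <- which(mk$pos > 7000 & mk$pos <= 7000 + d)
    want <- ehh_oracle(hp$haplotypes, carriers, ext)
    got <- ehh(co, hp, mk, d)
    if (is.na(want)) expect_true(is.na(got)) else expect_equal(got, want)
  }
})

test_that("EHH is non-increasing with distance", {
  set.seed(15)
  hm <- matrix(rbinom(10 * 40, 1, 0.5), 10, 40)
  hm[, 1:7] <- 0L
  mk <- quick_markers(40)
  hp <- haplotype_panel("p", hm)
  core <- list(chrom = "chr1", span = 1:7, start_pos = mk$pos[1],
               end_pos = mk$pos[7], string = "0000000", carriers = 1:10,
               frequency = 1)
  e <- vapply(seq(0, 33000, by = 3000),
              function(d) ehh(core, hp, mk, d), numeric(1))
  expect_equal(e[1], 1)
  expect_true(all(diff(e) <= 1e-12))
})

test_that("REHH relates a core to the carrier-weighted others", {
  mk <- quick_markers(20)
  hm <- matrix(0L, 8, 20)
  hm[5:8, 1] <- 1L            # two cores over span 1 (single-marker core)
  hm[7:8, 10] <- 1L           # the second core decays
  hp <- haplotype_panel("p", hm)
  mkc <- function(carriers, str) list(chrom = "chr1", span = 1,
                                      start_pos = 1000L, end_pos = 1000L,
                                      string = str, carriers = carriers,
                                      frequency = length(carriers) / 8)
  rr <- rehh(list(mkc(1:4, "0"), mkc(5:8, "1")), hp, mk, 19000)
  expect_equal(rr$ehh[1], 1)
  expect_equal(rr$ehh[2], 1 / 3)      # carriers split 2+2
  expect_equal(rr$rehh[1], 3)
  expect_equal(rr$rehh[2], 1 / 3)
  expect_true(all(is.na(rehh(list(mkc(1:4, "0")), hp, mk, 19000)$rehh)))
})

test_that("gamma MLE recovers parameters and is a likelihood optimum", {
  set.seed(16)
  for (i in 1:5) {
    x <- rgamma(10000, shape = 2, scale = 3)
    fit <- fit_gamma_mle(x)
    expect_lt(abs(fit$shape - 2) / 2, 0.05)
    expect_lt(abs(fit$scale - 3) / 3, 0.05)
    ll <- function(k, th) sum(stats::dgamma(x, shape = k, scale = th, log = TRUE))
    base <- ll(fit$shape, fit$scale)
    expect_gte(base, ll(fit$shape * 1.1, fit$scale))
    expect_gte(base, ll(fit$shape * 0.9, fit$scale))
    expect_gte(base, ll(fit$shape, fit$scale * 1.1))
    expect_gte(base, ll(fit$shape, fit$scale * 0.9))
  }
  expect_error(fit_gamma_mle(rep(2, 50)), "constant")
  expect_error(fit_gamma_mle(c(1, -1, 2)), "positive")
})

test_that("BH step-up matches the oracle on random p-vectors", {
  expect_equal(sum(bh_fdr(c(0.01, 0.02, 0.04, 0.5), 0.05)), 2)
  expect_equal(sum(bh_fdr(rep(1, 10), 0.05)), 0)
  expect_true(bh_fdr(0.05, 0.05))    # single p = q/m boundary
  set.seed(17)
  for (i in 1:1000) {
    m <- sample(1:50, 1)
    p <- runif(m)^sample(1:3, 1)
    expect_equal(bh_fdr(p, 0.05), stats::p.adjust(p, "BH") <= 0.05)
  }
})

test_that("wglrh_scan: neutral calibration and sweep recovery", {
  # default-world replicates (the 500-kb evaluation distance needs a
  # full-size chromosome); replicate count scaled down to 8 for runtime
  rej <- vapply(1:6, function(sd) {
    sim <- simulate_three_populations(sim_config(seed = 4200 + sd, s = 0))
    sc <- suppressMessages(wglrh_scan(sim$haplotypes$highland, sim$markers))
    expect_gt(nrow(sc), 50)          # the null is actually exercised
    mean(sc$fdr_reject)
  }, numeric(1))
  expect_lte(mean(rej), 2 * 0.05)
  # sweep to high frequency: a core whose 500-kb region spans the focal
  # marker is flagged in the majority of replicates
  hit <- vapply(1:8, function(sd) {
    sim <- simulate_three_populations(sim_config(seed = 4100 + sd, s = 0.05))
    if (sim$truth$final_daf[["highland"]] <= 0.85) return(NA)
    sc <- suppressMessages(wglrh_scan(sim$haplotypes$highland, sim$markers))
    sig <- sc[sc$significant, , drop = FALSE]
    nrow(sig) > 0 && any(sig$start_pos - 5e5 <= sim$truth$focal_pos &
                           sig$end_pos + 5e5 >= sim$truth$focal_pos)
  }, logical(1))
  expect_gt(mean(hit, na.rm = TRUE), 0.5)
})

test_that("wglrh_scan with no ancestral states warns and flags nothing", {
  sim <- simulate_three_populations(small_sim_config(4200))
  mk <- sim$markers
  mk$ancestral <- "unknown"
  expect_warning(sc <- wglrh_scan(sim$haplotypes$highland, mk,
                                  min_bin = 20L),
                 "no ancestral states")
  expect_equal(sum(sc$significant), 0)
})

test_that("CNP boundary REHH excludes markers inside the copy-number span", {
  mk <- quick_markers(21, spacing = 1000L)
  mk$marker_class[11] <- "cnp"
  hm <- matrix(0L, 8, 21)
  hm[5:8, 11] <- 1L                     # CNP at 0.5 frequency
  hp <- haplotype_panel("p", hm)
  rr <- cnp_rehh_at_boundary(hp, mk, "m11", distance_bp = 20000)
  expect_equal(rr$ehh, c(1, 1))         # identical flanks per class
  expect_equal(rr$rehh, c(1, 1))
  # fixed CNP -> single core, REHH undefined
  hm2 <- hm; hm2[, 11] <- 1L
  rf <- cnp_rehh_at_boundary(haplotype_panel("p", hm2), mk, "m11",
                             distance_bp = 20000)
  expect_equal(nrow(rf), 1)
  expect_true(is.na(rf$rehh))
  # a disrupting marker inside the CNP span changes EHH unless excluded
  hm3 <- hm; hm3[c(1, 5), 13] <- 1L     # inside span [11000, 15000]
  e_with <- cnp_rehh_at_boundary(haplotype_panel("p", hm3), mk, "m11",
                                 distance_bp = 20000)
  e_excl <- cnp_rehh_at_boundary(haplotype_panel("p", hm3), mk, "m11",
                                 cnp_span = c(11000, 15000),
                                 distance_bp = 20000)
  expect_lt(e_with$ehh[1], 1)
  expect_equal(e_excl$ehh, c(1, 1))
  expect_error(cnp_rehh_at_boundary(hp, mk, "nope"), "unknown marker")
})
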