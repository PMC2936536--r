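#' Per-marker allele counts for a genotype panel
#'
#' Missing genotypes are excluded from the called-chromosome count; there is
#' no imputation. `het_count` is the number of heterozygous individuals and
#' feeds the genotype-level Weir-Cockerham estimator.
#'
#' @param panel a [genotype_panel()].
#' @param marker_index optional integer vector of marker columns (default:
#'   all markers).
#' @return data.frame with columns `n_chrom`, `alt_count`, `het_count`, one
#'   row per requested marker. An all-missing marker yields `n_chrom = 0`.
#' @export
allele_counts <- function(panel, marker_index = NULL) {
  g <- panel$genotypes
  if (!is.null(marker_index)) {
    if (any(marker_index < 1 | marker_index > ncol(g)))
      stop("marker_index out of range")
    g <- g[, marker_index, drop = FALSE]
  }
  called <- !is.na(g)
  data.frame(
    n_chrom = 2L * colSums(called),
    alt_count = colSums(g, na.rm = TRUE),
    het_count = colSums(g == 1L & called, na.rm = TRUE)
  )
}

#' Unbiased expected heterozygosity
#'
#' \eqn{H = 2 \hat p (1 - \hat p) \, n/(n-1)} with \eqn{n} the number of
#' called chromosomes: the small-sample-corrected gene diversity. Markers
#' with fewer than 2 called chromosomes are undefined (`NA`).
#'
#' @param counts data.frame from [allele_counts()].
#' @return numeric vector of H values in \[0, 1\].
#' @export
expected_heterozygosity <- function(counts) {
  n <- counts$n_chrom
  p <- counts$alt_count / n
  h <- 2 * p * (1 - p) * n / (n - 1)
  h[n < 2] <- NA_real_
  h
}

#' Pairwise Weir-Cockerham FST
#'
#' The two-population moment estimator \eqn{\hat\theta = a/(a+b+c)} of Weir &
#' Cockerham (1984), using the full genotype-level form with the observed
#' heterozygosity term (so within-individual allele correlation is accounted
#' for). Vectorized over markers.
#'
#' Markers monomorphic for the same allele in both populations (zero total
#' variance) are undefined and returned as `NA`; negative estimates are
#' reported as computed — clipping happens only on entry to [lsbl()].
#'
#' @param counts1,counts2 per-population [allele_counts()] data.frames.
#' @param variant `"genotype"` (default) for the full estimator with the
#'   h-bar term; `"haploid"` treats each called chromosome as a haploid
#'   individual (sensitivity check).
#' @return data.frame with columns `theta`, `a`, `b`, `c`.
#' @export
wc_fst <- function(counts1, counts2, variant = c("genotype", "haploid")) {
  variant <- match.arg(variant)
  if (variant == "genotype") {
    n1 <- counts1$n_chrom / 2; n2 <- counts2$n_chrom / 2
    h1 <- ifelse(n1 > 0, counts1$het_count / n1, 0)
    h2 <- ifelse(n2 > 0, counts2$het_count / n2, 0)
  } else {
    n1 <- counts1$n_chrom; n2 <- counts2$n_chrom
    h1 <- h2 <- 0
  }
  p1 <- counts1$alt_count / counts1$n_chrom
  p2 <- counts2$alt_count / counts2$n_chrom
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  theta <- ifelse(denom > 0, a / denom, NA_real_)
  undef <- counts1$n_chrom < 2 | counts2$n_chrom < 2 | nbar <= 1
  theta[undef] <- a[undef] <- b[undef] <- cc[undef] <- NA_real_
  data.frame(theta = theta, a = a, b = b, c = cc)
}

#' Locus-specific branch lengths from three pairwise FST values
#'
#' Triangulates three pairwise FST estimates into per-population branch
#' lengths: \eqn{d_A = (F_{AB} + F_{AC} - F_{BC})/2} and cyclic permutations.
#' Negative pairwise estimates are floored at 0 before triangulation, so
#' the identity \eqn{d_A + d_B = \max(F_{AB}, 0)} holds exactly; resulting
#' negative branch lengths are reported as computed. With three populations
#' the focal branch is equivalent to a population-specific FST.
#'
#' @param fst_ab,fst_ac,fst_bc numeric vectors of pairwise theta estimates
#'   (`NA` = undefined; propagates).
#' @return data.frame with columns `d_a`, `d_b`, `d_c`.
#' @export
lsbl <- function(fst_ab, fst_ac, fst_bc) {
  ab <- pmax(fst_ab, 0); ac <- pmax(fst_ac, 0); bc <- pmax(fst_bc, 0)
  data.frame(
    d_a = (ab + ac - bc) / 2,
    d_b = (ab + bc - ac) / 2,
    d_c = (ac + bc - ab) / 2
  )
}

#' Mean pairwise FST around a genomic position
#'
#' Unweighted mean of the defined per-marker theta values within
#' `center +/- radius` on one chromosome; used to summarize differentiation
#' in a candidate region (typical radii: 100 kb and 500 kb).
#'
#' @param markers a [marker_table()].
#' @param fst_track numeric theta per marker, aligned to `markers`.
#' @param chrom chromosome label.
#' @param center span midpoint in bp.
#' @param radius half-width in bp.
#' @return single numeric mean, or `NA` if no defined marker falls in the
#'   span.
#' @export
region_mean_fst <- function(markers, fst_track, chrom, center, radius) {
  stopifnot(length(fst_track) == nrow(markers), radius > 0)
  in_span <- markers$chrom == chrom &
    markers$pos >= center - radius & markers$pos <= center + radius
  vals <- fst_track[in_span]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Per-marker LSBL scan for a population triangulation
#'
#' Convenience wrapper: computes allele counts, the three pairwise
#' Weir-Cockerham estimates and the branch lengths for every marker, with
#' the focal population as branch A.
#'
#' @param panel_focal,panel_ref1,panel_ref2 [genotype_panel()] objects
#'   aligned to the same markers.
#' @param variant passed to [wc_fst()].
#' @return data.frame with pairwise thetas (`fst_fr1`, `fst_fr2`, `fst_r12`)
#'   and branches (`lsbl_focal`, `lsbl_ref1`, `lsbl_ref2`).
#' @export
lsbl_scan <- function(panel_focal, panel_ref1, panel_ref2,
                      variant = "genotype") {
  cf <- allele_counts(panel_focal)
  c1 <- allele_counts(panel_ref1)
  c2 <- allele_counts(panel_ref2)
  f01 <- wc_fst(cf, c1, variant)$theta
  f02 <- wc_fst(cf, c2, variant)$theta
  f12 <- wc_fst(c1, c2, variant)$theta
  # a pair monomorphic for the same allele has a 0/0 theta; at markers still
  # polymorphic across the triangulation (e.g. a completed focal sweep with
  # both references fixed ancestral) the pair shows no differentiation, so
  # its theta enters the triangulation as 0 rather than dropping the locus
  tot_alt <- cf$alt_count + c1$alt_count + c2$alt_count
  tot_n <- cf$n_chrom + c1$n_chrom + c2$n_chrom
  poly3 <- tot_alt > 0 & tot_alt < tot_n
  mono_zero <- function(theta, ca, cb) {
    fix <- ca$alt_count + cb$alt_count == 0 |
      ca$alt_count + cb$alt_count == ca$n_chrom + cb$n_chrom
    ifelse(is.na(theta) & fix & poly3 & ca$n_chrom >= 2 & cb$n_chrom >= 2,
           0, theta)
  }
  f01 <- mono_zero(f01, cf, c1)
  f02 <- mono_zero(f02, cf, c2)
  f12 <- mono_zero(f12, c1, c2)
  br <- lsbl(f01, f02, f12)
  data.frame(fst_fr1 = f01, fst_fr2 = f02, fst_r12 = f12,
             lsbl_focal = br$d_a, lsbl_ref1 = br$d_b, lsbl_ref2 = br$d_c)
}
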