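#' Derived-allele frequency per marker
#'
#' Frequency of the derived (non-ancestral) allele among called chromosomes.
#' Markers with unknown ancestral state are `NA` and are excluded from the
#' long-range-haplotype scan; the scan's high-frequency filter passes only
#' strictly above the threshold (0.86 passes at 0.85, 0.85 exactly fails).
#'
#' @param panel a [genotype_panel()] or [haplotype_panel()].
#' @param markers aligned [marker_table()] supplying ancestral states.
#' @return numeric vector of derived-allele frequencies (`NA` when ancestral
#'   is unknown or no chromosome is called).
#' @export
derived_allele_frequency <- function(panel, markers) {
  if (inherits(panel, "haplotype_panel")) {
    h <- panel$haplotypes
    n <- colSums(!is.na(h))
    alt <- colSums(h, na.rm = TRUE)
  } else {
    cnt <- allele_counts(panel)
    n <- cnt$n_chrom
    alt <- cnt$alt_count
  }
  p_alt <- ifelse(n > 0, alt / n, NA_real_)
  out <- ifelse(markers$ancestral == "ref", p_alt,
                ifelse(markers$ancestral == "alt", 1 - p_alt, NA_real_))
  as.numeric(out)
}

#' Partition markers into non-overlapping core spans and list core haplotypes
#'
#' Cores are the distinct allelic strings over spans of `core_size`
#' consecutive markers (step = `core_size`, so spans do not overlap and do
#' not cross chromosome boundaries). Haplotype rows with a missing allele
#' inside a span are dropped for that span; cores carried by fewer than
#' `min_carriers` rows are discarded.
#'
#' @param hpanel a phased [haplotype_panel()].
#' @param markers aligned [marker_table()].
#' @param core_size markers per core span (default 7).
#' @param min_carriers minimum carrier count (default 3).
#' @return list of cores; each is a list with `chrom`, `span` (marker index
#'   range), `start_pos`, `end_pos`, `string`, `carriers` (haplotype row
#'   indices), `frequency` (among rows complete over the span).
#' @export
define_cores <- function(hpanel, markers, core_size = 7L, min_carriers = 3L) {
  stopifnot(inherits(hpanel, "haplotype_panel"))
  if (!hpanel$phased) stop("phased haplotypes required")
  h <- hpanel$haplotypes
  cores <- list()
  for (ch in unique(markers$chrom)) {
    midx <- which(markers$chrom == ch)
    if (length(midx) < core_size) next
    starts <- seq(1L, length(midx) - core_size + 1L, by = core_size)
    for (s in starts) {
      span <- midx[s:(s + core_size - 1L)]
      sub <- h[, span, drop = FALSE]
      complete <- rowSums(is.na(sub)) == 0L
      rows <- which(complete)
      if (length(rows) < min_carriers) next
      strings <- apply(sub[rows, , drop = FALSE], 1, paste, collapse = "")
      for (str in unique(strings)) {
        carriers <- rows[strings == str]
        if (length(carriers) < min_carriers) next
        cores[[length(cores) + 1L]] <- list(
          chrom = ch, span = span,
          start_pos = markers$pos[span[1]],
          end_pos = markers$pos[span[core_size]],
          string = str, carriers = carriers,
          frequency = length(carriers) / length(rows))
      }
    }
  }
  cores
}

# fraction of carrier pairs identical over the extension columns; a pair is
# compared over the sites where both alleles are called, so sporadic
# missingness does not void whole haplotypes (with complete data this
# equals sum over distinct strings of C(c_h,2) / C(c,2))
pairwise_homozygosity <- function(sub) {
  n <- nrow(sub)
  if (n < 2) return(NA_real_)
  a <- sub == 1L; a[is.na(a)] <- FALSE
  b <- sub == 0L; b[is.na(b)] <- FALSE
  mm <- tcrossprod(a, b)            # mismatches where i has 1 and j has 0
  mism <- mm + t(mm)
  sum(mism[upper.tri(mism)] == 0) / choose(n, 2)
}

#' Extended haplotype homozygosity of a core
#'
#' The probability that two randomly drawn carrier chromosomes of the core
#' are identical over all markers out to `distance_bp` from the core's
#' edges. EHH(0) = 1 by construction and EHH is non-increasing with
#' distance. Carrier pairs are compared over mutually called sites, so a
#' missing allele masks one site for that pair rather than discarding the
#' haplotype (row-wise dropping would leave no complete carrier over a
#' 500-kb extension at realistic missing rates).
#'
#' @param core a core from [define_cores()] (or a compatible list).
#' @param hpanel the [haplotype_panel()] the core was defined on.
#' @param markers aligned [marker_table()].
#' @param distance_bp extension distance from each core edge.
#' @param side `"both"` (default), `"left"` or `"right"`.
#' @param exclude optional marker indices never used in the extension (e.g.
#'   SNPs inside a copy-number-variant span).
#' @return EHH value in \[0, 1\], or `NA` if fewer than 2 informative
#'   carriers remain.
#' @export
ehh <- function(core, hpanel, markers, distance_bp, side = "both",
                exclude = integer()) {
  stopifnot(distance_bp >= 0)
  h <- hpanel$haplotypes
  on_chrom <- markers$chrom == core$chrom
  left <- which(on_chrom & markers$pos < core$start_pos &
                  markers$pos >= core$start_pos - distance_bp)
  right <- which(on_chrom & markers$pos > core$end_pos &
                   markers$pos <= core$end_pos + distance_bp)
  ext <- switch(side, both = c(left, right), left = left, right = right,
                stop("side must be both, left or right"))
  ext <- setdiff(ext, c(core$span, exclude))
  if (!length(ext)) {
    if (length(core$carriers) < 2) return(NA_real_)
    return(1)
  }
  pairwise_homozygosity(h[core$carriers, ext, drop = FALSE])
}

#' Relative EHH of each core on a shared span
#'
#' REHH = EHH of the core divided by the carrier-weighted average EHH of
#' every other core on the same span, at the evaluation distance (default
#' 500 kb). Undefined when the span carries a single core or the competing
#' cores have zero EHH.
#'
#' @param cores list of cores sharing one span (>= 2 for a defined result).
#' @param hpanel,markers as in [ehh()].
#' @param distance_bp evaluation distance, default 500 kb.
#' @return data.frame with one row per core: `frequency`, `ehh`, `ehh_others`,
#'   `rehh`.
#' @export
rehh <- function(cores, hpanel, markers, distance_bp = 500000) {
  e <- vapply(cores, function(co) ehh(co, hpanel, markers, distance_bp),
              numeric(1))
  w <- vapply(cores, function(co) length(co$carriers), numeric(1))
  n <- length(cores)
  out <- data.frame(frequency = vapply(cores, `[[`, numeric(1), "frequency"),
                    ehh = e, ehh_others = NA_real_, rehh = NA_real_)
  if (n < 2) return(out)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    ok <- others[!is.na(e[others])]
    if (!length(ok)) next
    eo <- sum(w[ok] * e[ok]) / sum(w[ok])
    out$ehh_others[i] <- eo
    if (!is.na(e[i]) && eo > 0) out$rehh[i] <- e[i] / eo
  }
  out
}

#' Gamma maximum-likelihood fit
#'
#' Shape/scale MLE by Newton iteration on the profile score
#' \eqn{\log k - \psi(k) = \log \bar x - \overline{\log x}}, relative
#' tolerance 1e-8. Requires strictly positive, non-constant input.
#'
#' @param values positive numeric vector.
#' @return list with `shape`, `scale`.
#' @export
fit_gamma_mle <- function(values) {
  x <- values[!is.na(values)]
  if (any(x <= 0)) stop("gamma MLE requires strictly positive values")
  if (length(x) < 2 || sd(x) == 0)
    stop("gamma MLE undefined for constant input")
  s <- log(mean(x)) - mean(log(x))
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (it in 1:100) {
    delta <- (log(k) - digamma(k) - s) / (1 / k - trigamma(k))
    k_new <- k - delta
    if (k_new <= 0) k_new <- k / 2
    if (abs(k_new - k) < 1e-8 * k) { k <- k_new; break }
    k <- k_new
  }
  list(shape = k, scale = mean(x) / k)
}

#' Benjamini-Hochberg step-up rejections
#'
#' @param p_values p-values in (0, 1].
#' @param q false-discovery-rate level (default 0.05).
#' @return logical rejection flags in input order.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  m <- length(p_values)
  if (!m) return(logical(0))
  ord <- order(p_values)
  ps <- p_values[ord]
  below <- which(ps <= q * seq_len(m) / m)
  flags <- logical(m)
  if (length(below)) flags[ord[seq_len(max(below))]] <- TRUE
  flags
}

#' Whole-genome long-range-haplotype (REHH) scan
#'
#' For every core haplotype: REHH at the evaluation distance, an upper-tail
#' p-value against a gamma null fitted by maximum likelihood within the
#' core's frequency bin, Benjamini-Hochberg FDR control across all tested
#' cores, and a final restriction of the reported significant set to cores
#' carrying a high-frequency derived allele (panel derived-allele frequency
#' strictly above `daf_threshold` at a core marker where the core holds the
#' derived allele). Frequency bins with fewer than `min_bin` REHH values
#' fall back to a gamma fit pooled over all cores.
#'
#' @param hpanel phased [haplotype_panel()].
#' @param markers aligned [marker_table()] with ancestral states.
#' @param core_size,min_carriers core construction, see [define_cores()].
#' @param distance_bp REHH evaluation distance (default 500 kb).
#' @param bin_width core-frequency bin width for the gamma null (default
#'   0.05).
#' @param min_bin minimum REHH values per bin for a bin-specific fit.
#' @param q FDR level.
#' @param daf_threshold derived-allele-frequency filter (strict, default
#'   0.85).
#' @return data.frame of class `rehh_scan`, one row per core with a defined
#'   REHH: span coordinates, `core` string, `frequency`, `rehh`, `bin`,
#'   `shape`, `scale`, `p`, `fdr_reject`, `derived_flag` and `significant`
#'   (`fdr_reject & derived_flag`).
#' @export
wglrh_scan <- function(hpanel, markers, core_size = 7L, min_carriers = 3L,
                       distance_bp = 500000, bin_width = 0.05, min_bin = 30L,
                       q = 0.05, daf_threshold = 0.85) {
  cores <- define_cores(hpanel, markers, core_size, min_carriers)
  daf <- derived_allele_frequency(hpanel, markers)
  if (all(is.na(daf)))
    warning("no ancestral states available: significant set will be empty")
  rows <- list()
  span_key <- vapply(cores, function(co) paste(co$chrom, co$span[1]), "")
  for (key in unique(span_key)) {
    grp <- cores[span_key == key]
    rr <- rehh(grp, hpanel, markers, distance_bp)
    for (i in seq_along(grp)) {
      co <- grp[[i]]
      alleles <- as.integer(strsplit(co$string, "")[[1]])
      anc <- markers$ancestral[co$span]
      carries_derived <- (anc == "ref" & alleles == 1L) |
        (anc == "alt" & alleles == 0L)
      dflag <- any(carries_derived & !is.na(daf[co$span]) &
                     daf[co$span] > daf_threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = co$chrom, start_pos = co$start_pos, end_pos = co$end_pos,
        core = co$string, frequency = co$frequency,
        ehh = rr$ehh[i], rehh = rr$rehh[i], derived_flag = dflag,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(chrom = character(), start_pos = integer(),
                      end_pos = integer(), core = character(),
                      frequency = numeric(), ehh = numeric(),
                      rehh = numeric(), derived_flag = logical())
  n_undefined <- sum(is.na(out$rehh))
  if (n_undefined > 0)
    message(n_undefined, " core(s) with undefined REHH dropped from testing")
  out <- out[!is.na(out$rehh) & out$rehh > 0, , drop = FALSE]
  out$bin <- floor(pmin(out$frequency, 1 - 1e-9) / bin_width)
  out$shape <- rep(NA_real_, nrow(out))
  out$scale <- rep(NA_real_, nrow(out))
  out$p <- rep(NA_real_, nrow(out))
  if (nrow(out)) {
    global_fit <- if (sum(!is.na(out$rehh)) >= 2 && sd(out$rehh) > 0)
      fit_gamma_mle(out$rehh) else NULL
    for (b in unique(out$bin)) {
      idx <- which(out$bin == b)
      fit <- if (length(idx) >= min_bin && sd(out$rehh[idx]) > 0)
        fit_gamma_mle(out$rehh[idx]) else global_fit
      if (is.null(fit)) next
      out$shape[idx] <- fit$shape
      out$scale[idx] <- fit$scale
      out$p[idx] <- pmax(pgamma(out$rehh[idx], shape = fit$shape,
                                scale = fit$scale, lower.tail = FALSE),
                         .Machine$double.xmin)
    }
  }
  out$fdr_reject <- rep(FALSE, nrow(out))
  tested <- which(!is.na(out$p))
  if (length(tested))
    out$fdr_reject[tested] <- bh_fdr(out$p[tested], q)
  out$significant <- out$fdr_reject & out$derived_flag
  rownames(out) <- NULL
  class(out) <- c("rehh_scan", "data.frame")
  out
}

#' REHH of a biallelic copy-number polymorphism at its boundary
#'
#' Treats the CNP as a single-marker core located at the boundary of the
#' copy-number window: each allele class among phased haplotypes forms a
#' core, EHH/REHH are computed over SNPs within `distance_bp` of the
#' boundary, and SNPs falling inside the CNP span itself are excluded from
#' the extension.
#'
#' @param hpanel phased [haplotype_panel()] including the CNP as a marker.
#' @param markers aligned [marker_table()].
#' @param cnp_id marker id of the CNP (`marker_class == "cnp"`).
#' @param cnp_span optional `c(start, end)` of the copy-number window in bp;
#'   markers inside it are excluded from the extension.
#' @param distance_bp extension distance (default 500 kb).
#' @param min_carriers minimum carriers per allele class.
#' @return data.frame with one row per allele class present: `allele`,
#'   `frequency`, `ehh`, `rehh` (`NA` REHH when the CNP is fixed).
#' @export
cnp_rehh_at_boundary <- function(hpanel, markers, cnp_id, cnp_span = NULL,
                                 distance_bp = 500000, min_carriers = 2L) {
  mi <- match(cnp_id, markers$marker_id)
  if (is.na(mi)) stop("unknown marker id: ", cnp_id)
  h <- hpanel$haplotypes
  excl <- integer()
  if (!is.null(cnp_span))
    excl <- which(markers$chrom == markers$chrom[mi] &
                    markers$pos >= cnp_span[1] & markers$pos <= cnp_span[2])
  called <- which(!is.na(h[, mi]))
  cores <- list()
  for (a in unique(h[called, mi])) {
    carriers <- called[h[called, mi] == a]
    if (length(carriers) < min_carriers) next
    cores[[length(cores) + 1L]] <- list(
      chrom = markers$chrom[mi], span = mi,
      start_pos = markers$pos[mi], end_pos = markers$pos[mi],
      string = as.character(a), carriers = carriers,
      frequency = length(carriers) / length(called))
  }
  if (!length(cores))
    return(data.frame(allele = integer(), frequency = numeric(),
                      ehh = numeric(), rehh = numeric()))
  e <- vapply(cores, function(co)
    ehh(co, hpanel, markers, distance_bp, exclude = excl), numeric(1))
  w <- vapply(cores, function(co) length(co$carriers), numeric(1))
  re <- rep(NA_real_, length(cores))
  if (length(cores) >= 2) {
    for (i in seq_along(cores)) {
      others <- setdiff(seq_along(cores), i)
      ok <- others[!is.na(e[others])]
      if (!length(ok)) next
      eo <- sum(w[ok] * e[ok]) / sum(w[ok])
      if (!is.na(e[i]) && eo > 0) re[i] <- e[i] / eo
    }
  }
  data.frame(allele = as.integer(vapply(cores, `[[`, "", "string")),
             frequency = vapply(cores, `[[`, numeric(1), "frequency"),
             ehh = e, rehh = re)
}
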