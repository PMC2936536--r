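#' Upper tail of the hypergeometric distribution
#'
#' \eqn{P(X \ge k)} for X ~ Hypergeometric(N, K, n): the chance of drawing
#' at least `k` significant items in a sample of `n` from a genome with `K`
#' significant among `N`. Vectorized over `k`, `n`.
#'
#' @param k observed significant items in the region.
#' @param big_k genome-wide significant items.
#' @param n items in the region.
#' @param big_n genome-wide items.
#' @return tail probability in (0, 1].
#' @export
hypergeom_tail <- function(k, big_k, n, big_n) {
  if (any(k < 0 | k > n | n > big_n | big_k > big_n | big_k < 0))
    stop("hypergeometric bounds violated: need 0 <= k <= n <= N, 0 <= K <= N")
  phyper(k - 1, big_k, big_n - big_k, n, lower.tail = FALSE)
}

#' Hypergeometric scan of non-overlapping megabase regions
#'
#' Partitions each chromosome into non-overlapping `region_size` bins
#' anchored at position 1, and asks for each bin whether it contains more
#' significant items (markers for a per-SNP statistic, windows for a
#' sliding-window statistic) than expected by chance, via the upper
#' hypergeometric tail. P-values are Bonferroni-corrected by the number of
#' tested (non-empty) regions; a region is significant when the corrected
#' p-value is at or below `region_alpha`.
#'
#' @param chrom chromosome label per item.
#' @param pos position per item in bp (a window is placed by its start).
#' @param flags logical significance per item (from the empirical 5% tail);
#'   `NA` items are dropped.
#' @param region_size bin width in bp, default 1 Mb.
#' @param region_alpha corrected-p threshold, default 0.004.
#' @param statistic_name label carried into the output.
#' @return data.frame of class `region_scan`: `chrom`, `start`, `end`, `n`,
#'   `k`, `p`, `p_bonf`, `significant`, `statistic_name`.
#' @export
scan_megabase_regions <- function(chrom, pos, flags, region_size = 1e6,
                                  region_alpha = 0.004,
                                  statistic_name = "stat") {
  ok <- !is.na(flags)
  chrom <- chrom[ok]; pos <- pos[ok]; flags <- flags[ok]
  if (!length(flags))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      n = integer(), k = integer(), p = numeric(),
                      p_bonf = numeric(), significant = logical(),
                      statistic_name = character()))
  big_n <- length(flags)
  big_k <- sum(flags)
  bin <- floor((pos - 1) / region_size)
  key <- paste(chrom, bin, sep = ":")
  n <- tapply(flags, key, length)
  k <- tapply(flags, key, sum)
  keys <- names(n)
  ch <- sub(":[^:]*$", "", keys)
  b <- as.numeric(sub("^.*:", "", keys))
  p <- hypergeom_tail(as.integer(k), big_k, as.integer(n), big_n)
  n_tested <- length(keys)
  p_bonf <- pmin(1, p * n_tested)
  out <- data.frame(chrom = ch, start = as.integer(b * region_size + 1),
                    end = as.integer((b + 1) * region_size),
                    n = as.integer(n), k = as.integer(k), p = p,
                    p_bonf = p_bonf, significant = p_bonf <= region_alpha,
                    statistic_name = statistic_name,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  class(out) <- c("region_scan", "data.frame")
  out
}

#' Nominate candidate regions from three region scans
#'
#' A megabase region is a selection-nominated candidate when it is
#' significant for the standardized difference of D *and* for at least one
#' of LSBL or lnRH. Adjacent nominated megabases on a chromosome are merged
#' into runs of consecutive significance, whose length is reported.
#'
#' @param lsbl_regions,lnrh_regions,dstd_regions [scan_megabase_regions()]
#'   outputs for the three statistics (region sets need not be identical; a
#'   region absent from a scan counts as not significant there).
#' @return data.frame of nominated megabase regions with per-statistic
#'   significance flags, `run_id` and `run_length`.
#' @export
nominate_regions <- function(lsbl_regions, lnrh_regions, dstd_regions) {
  key <- function(r) paste(r$chrom, r$start, sep = ":")
  all_keys <- unique(c(key(lsbl_regions), key(lnrh_regions), key(dstd_regions)))
  sig_in <- function(r) all_keys %in% key(r)[r$significant]
  sig_lsbl <- sig_in(lsbl_regions)
  sig_lnrh <- sig_in(lnrh_regions)
  sig_dstd <- sig_in(dstd_regions)
  nominated <- sig_dstd & (sig_lsbl | sig_lnrh)
  ch <- sub(":[^:]*$", "", all_keys)
  st <- as.numeric(sub("^.*:", "", all_keys))
  size <- 1e6
  for (r in list(lsbl_regions, lnrh_regions, dstd_regions))
    if (nrow(r)) { size <- r$end[1] - r$start[1] + 1; break }
  out <- data.frame(chrom = ch, start = st, end = st + size - 1,
                    sig_lsbl = sig_lsbl, sig_lnrh = sig_lnrh,
                    sig_dstd = sig_dstd, stringsAsFactors = FALSE)
  out <- out[nominated, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  if (nrow(out)) {
    new_run <- c(TRUE, !(out$chrom[-1] == out$chrom[-nrow(out)] &
                           out$start[-1] == out$start[-nrow(out)] + size))
    out$run_id <- cumsum(new_run)
    out$run_length <- as.integer(ave(out$run_id, out$run_id, FUN = length))
  } else {
    out$run_id <- integer(0)
    out$run_length <- integer(0)
  }
  rownames(out) <- NULL
  out
}

#' Intersect CNV intervals with candidate regions
#'
#' Any-base-overlap intersection (abutting intervals, `end + 1 == start`, do
#' not overlap) between copy-number-variant calls and nominated or
#' extended-haplotype regions, both as 1-based inclusive spans.
#'
#' @param cnvs data.frame with `chrom`, `start`, `end` and optionally an id
#'   column.
#' @param regions data.frame with `chrom`, `start`, `end`.
#' @return data.frame pairing each overlapping CNV row with its region row.
#' @export
overlap_cnv_regions <- function(cnvs, regions) {
  if (!nrow(cnvs) || !nrow(regions))
    return(data.frame(cnv_row = integer(), region_row = integer()))
  g1 <- GenomicRanges::GRanges(cnvs$chrom,
                               IRanges::IRanges(cnvs$start, cnvs$end))
  g2 <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start, regions$end))
  hits <- GenomicRanges::findOverlaps(g1, g2)
  out <- data.frame(cnv_row = S4Vectors::queryHits(hits),
                    region_row = S4Vectors::subjectHits(hits))
  cn <- cnvs[out$cnv_row, , drop = FALSE]
  names(cn) <- paste0("cnv_", names(cn))
  rg <- regions[out$region_row, , drop = FALSE]
  names(rg) <- paste0("region_", names(rg))
  cbind(out, cn, rg, row.names = NULL)
}

#' Write regions as a BED file
#'
#' @param regions data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive; converted to BED 0-based half-open).
#' @param path output path.
#' @param name optional character vector for the BED name column.
#' @export
write_regions_bed <- function(regions, path, name = NULL) {
  out <- data.frame(regions$chrom, regions$start - 1L, regions$end)
  if (!is.null(name)) out$name <- name
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
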