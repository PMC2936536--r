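#' Build a sliding-window grid
#'
#' Overlapping windows of `size` bp advancing by `step` bp, anchored at
#' position 1 of each chromosome; a window is emitted while it fits entirely
#' on the chromosome (`start <= length - size + 1`). Defaults follow the
#' scan convention of 100-kb windows with a 25-kb offset.
#'
#' @param chrom_lengths named integer vector of chromosome lengths in bp.
#' @param size window size in bp.
#' @param step offset between consecutive window starts in bp.
#' @return data.frame of class `window_grid` with columns `chrom`, `start`,
#'   `end` (1-based inclusive).
#' @export
make_windows <- function(chrom_lengths, size = 100000L, step = 25000L) {
  if (size <= 0 || step <= 0) stop("size and step must be positive")
  if (size %% step != 0)
    warning("window size is not a multiple of step")
  if (is.null(names(chrom_lengths)))
    stop("chrom_lengths must be a named vector")
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    if (len < size) return(NULL)
    starts <- seq.int(1L, len - size + 1L, by = step)
    data.frame(chrom = ch, start = as.integer(starts),
               end = as.integer(starts + size - 1L),
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(grid))
    grid <- data.frame(chrom = character(), start = integer(), end = integer())
  class(grid) <- c("window_grid", "data.frame")
  grid
}

# index ranges (lo, hi) of markers per window, using sorted positions;
# hi < lo means an empty window
window_marker_ranges <- function(markers, grid) {
  lo <- integer(nrow(grid)); hi <- integer(nrow(grid))
  for (ch in unique(grid$chrom)) {
    widx <- which(grid$chrom == ch)
    midx <- which(markers$chrom == ch)
    pos <- markers$pos[midx]
    lo[widx] <- findInterval(grid$start[widx] - 1L, pos) + 1L
    hi[widx] <- findInterval(grid$end[widx], pos)
    lo[widx] <- midx[1] - 1L + lo[widx]
    hi[widx] <- midx[1] - 1L + hi[widx]
    if (!length(midx)) { lo[widx] <- 1L; hi[widx] <- 0L }
  }
  list(lo = lo, hi = hi)
}

# windowed sum of a per-marker vector (NA treated as 0) via cumulative sums
window_sum <- function(x, rng) {
  cs <- c(0, cumsum(ifelse(is.na(x), 0, x)))
  cs[rng$hi + 1L] - cs[rng$lo]
}

#' Window-averaged heterozygosity and lnRH
#'
#' Per window, each population's heterozygosity is the mean unbiased expected
#' heterozygosity over the markers it contains; lnRH is the natural log of
#' the focal/reference ratio. Strongly negative lnRH marks a
#' population-specific loss of diversity in the focal panel. Windows with no
#' markers, or zero mean heterozygosity in either population, are undefined.
#'
#' @param panel_focal,panel_ref [genotype_panel()] objects on the same
#'   markers.
#' @param markers the aligned [marker_table()].
#' @param grid a [make_windows()] grid.
#' @return data.frame with `n_markers`, `h_focal`, `h_ref`, `lnrh`.
#' @export
window_lnrh <- function(panel_focal, panel_ref, markers, grid) {
  stopifnot(ncol(panel_focal$genotypes) == nrow(markers),
            ncol(panel_ref$genotypes) == nrow(markers))
  rng <- window_marker_ranges(markers, grid)
  hf <- expected_heterozygosity(allele_counts(panel_focal))
  hr <- expected_heterozygosity(allele_counts(panel_ref))
  nf <- window_sum(!is.na(hf), rng)
  nr <- window_sum(!is.na(hr), rng)
  mean_f <- ifelse(nf > 0, window_sum(hf, rng) / nf, NA_real_)
  mean_r <- ifelse(nr > 0, window_sum(hr, rng) / nr, NA_real_)
  lnrh <- ifelse(!is.na(mean_f) & !is.na(mean_r) & mean_f > 0 & mean_r > 0,
                 log(mean_f / mean_r), NA_real_)
  data.frame(n_markers = rng$hi - rng$lo + 1L,
             h_focal = mean_f, h_ref = mean_r, lnrh = lnrh)
}

#' Tajima's D normalizing constants
#'
#' The a1, a2, b1, b2, c1, c2, e1, e2 constants of Tajima (1989), which
#' depend only on the number of sampled chromosomes `n`.
#'
#' @param n chromosomes sampled (>= 4).
#' @return named list of the eight constants.
#' @export
tajima_constants <- function(n) {
  if (n < 4) stop("Tajima's D requires n >= 4 chromosomes")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Sliding-window Tajima's D
#'
#' Per window, `S` counts markers segregating within the panel and pi sums
#' the per-site unbiased heterozygosity \eqn{2\hat p(1-\hat p)n/(n-1)} over
#' segregating sites (per-site `n` = called chromosomes). The normalizing
#' constants use the full panel size `n = 2 x samples`; residual per-site
#' missingness below the call-rate filter is ignored. Windows with `S = 0`
#' are undefined, not zero.
#'
#' Negative D reflects an excess of rare variants, the footprint of a recent
#' sweep (or of population growth -- the scan ranks windows empirically
#' rather than testing against a neutral model).
#'
#' @param panel a [genotype_panel()].
#' @param markers aligned [marker_table()].
#' @param grid a [make_windows()] grid.
#' @return data.frame with `S`, `pi`, `d`.
#' @export
tajimas_d <- function(panel, markers, grid) {
  stopifnot(ncol(panel$genotypes) == nrow(markers))
  n_full <- 2L * nrow(panel$genotypes)
  k <- tajima_constants(n_full)
  cnt <- allele_counts(panel)
  seg <- cnt$alt_count > 0 & cnt$alt_count < cnt$n_chrom & cnt$n_chrom >= 2
  p <- cnt$alt_count / cnt$n_chrom
  site_pi <- ifelse(seg, 2 * p * (1 - p) * cnt$n_chrom / (cnt$n_chrom - 1), 0)
  rng <- window_marker_ranges(markers, grid)
  S <- window_sum(seg, rng)
  pi <- window_sum(site_pi, rng)
  vd <- k$e1 * S + k$e2 * S * (S - 1)
  d <- ifelse(S > 0, (pi - S / k$a1) / sqrt(vd), NA_real_)
  data.frame(S = S, pi = pi, d = d)
}

#' Standardize Tajima's D across windows
#'
#' \eqn{(D_i - \mu)/SD} with the mean and sample standard deviation taken
#' over all defined windows of one chromosome class (autosomes and X are
#' standardized separately by the caller).
#'
#' @param d numeric vector of per-window D (NA = undefined).
#' @return standardized vector, NA preserved.
#' @export
standardize_d <- function(d) {
  ok <- !is.na(d)
  if (sum(ok) < 2) stop("need >= 2 defined windows to standardize")
  s <- sd(d[ok])
  if (s == 0) {
    warning("zero variance across windows; standardized D set to 0")
    return(ifelse(ok, 0, NA_real_))
  }
  (d - mean(d[ok])) / s
}

#' Standardized difference of Tajima's D between two populations
#'
#' Per window, \eqn{\Delta_i = D_{focal,i} - D_{ref,i}}; the output is
#' \eqn{(\Delta_i - \mu_\Delta)/SD_\Delta} over all windows where both are
#' defined. Strongly negative values mark windows where the focal population
#' carries a rare-variant excess that its reference does not.
#'
#' @param d_focal,d_ref aligned per-window D vectors.
#' @return standardized difference vector, NA where either input is NA.
#' @export
std_diff_d <- function(d_focal, d_ref) {
  stopifnot(length(d_focal) == length(d_ref))
  delta <- d_focal - d_ref
  ok <- !is.na(delta)
  if (sum(ok) < 2) stop("need >= 2 defined windows")
  s <- sd(delta[ok])
  if (s == 0) {
    warning("zero variance of D differences; output set to 0")
    return(ifelse(ok, 0, NA_real_))
  }
  (delta - mean(delta[ok])) / s
}

#' Eligibility mask for windows entering the lower-tail ranking
#'
#' In `"two_stage"` mode only windows with negative standardized focal D are
#' eligible, reproducing a scan that first screens for a rare-variant excess
#' in the focal population. The default `"tail_only"` keeps every defined
#' window: the ranked distribution is then the full window set, which is
#' what makes the alpha-quantile significant-window counts exact fractions
#' of the totals.
#'
#' @param d_std_focal standardized focal-population D per window.
#' @param delta_d_std standardized difference of D per window.
#' @param mode `"tail_only"` or `"two_stage"`.
#' @return logical eligibility per window.
#' @export
flag_negative_focal <- function(d_std_focal, delta_d_std,
                                mode = c("tail_only", "two_stage")) {
  mode <- match.arg(mode)
  defined <- !is.na(d_std_focal) & !is.na(delta_d_std)
  if (mode == "tail_only") defined else defined & d_std_focal < 0
}

#' Full window-statistic track for a focal/reference pair
#'
#' Runs [window_lnrh()], [tajimas_d()] for both panels, [standardize_d()]
#' and [std_diff_d()] on one grid and assembles the per-window track.
#'
#' @inheritParams window_lnrh
#' @return data.frame: `chrom`, `start`, `end`, `n_markers`, `h_focal`,
#'   `h_ref`, `lnrh`, `d_focal`, `d_ref`, `d_std_focal`, `delta_d_std`.
#' @export
window_stat_track <- function(panel_focal, panel_ref, markers, grid) {
  rh <- window_lnrh(panel_focal, panel_ref, markers, grid)
  df <- tajimas_d(panel_focal, markers, grid)
  dr <- tajimas_d(panel_ref, markers, grid)
  cbind(grid[, c("chrom", "start", "end")], rh,
        data.frame(d_focal = df$d, d_ref = dr$d,
                   d_std_focal = standardize_d(df$d),
                   delta_d_std = std_diff_d(df$d, dr$d)))
}
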