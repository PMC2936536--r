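#' Round half away from zero
#'
#' Commercial rounding (`0.5 -> 1`), as opposed to R's banker's rounding.
#' This is the rule under which the alpha-quantile significant-marker counts
#' are exact: e.g. `round_half_up(0.05 * 36160) = 1808`.
#'
#' @param x numeric vector (non-negative in all package uses).
#' @return numeric vector rounded to integers.
#' @export
round_half_up <- function(x) floor(x + 0.5)

#' Empirical ranks and p-values for a genome-wide statistic
#'
#' Ranks every defined value by decreasing extremity in the stated tail
#' (upper for branch lengths, lower for lnRH and the standardized difference
#' of D) and assigns the empirical p-value \eqn{P_E = (rank-1)/N}: the
#' proportion of the genome-wide distribution strictly more extreme, the
#' form that reproduces published worked examples of rank/total/P_E triples
#' at 4-decimal rounding. Tied values all receive the maximum
#' (most conservative) rank of their tied block. Autosomes and the X
#' chromosome form separate empirical distributions: call once per
#' chromosome class.
#'
#' @param values numeric statistic vector; `NA`s are excluded from ranking
#'   and returned as `NA` rows.
#' @param tail `"upper"` or `"lower"`: which extreme counts as rank 1.
#' @param chromosome_class label stored in the output (e.g. `"autosome"`,
#'   `"x"`).
#' @return data.frame with `value`, `rank`, `n`, `p_e`, `p_e_4dp` (the
#'   4-decimal rounding used in output files), `chromosome_class`.
#' @export
rank_and_p <- function(values, tail = c("upper", "lower"),
                       chromosome_class = "autosome") {
  tail <- match.arg(tail)
  ok <- !is.na(values)
  if (!any(ok)) stop("no defined values to rank")
  n <- sum(ok)
  r <- rep(NA_integer_, length(values))
  key <- if (tail == "upper") -values[ok] else values[ok]
  r[ok] <- as.integer(rank(key, ties.method = "max"))
  p <- (r - 1) / n
  data.frame(value = values, rank = r, n = ifelse(ok, n, NA_integer_),
             p_e = p, p_e_4dp = round_half_up(p * 1e4) / 1e4,
             chromosome_class = chromosome_class,
             stringsAsFactors = FALSE)
}

#' Expected number of significant values at an empirical threshold
#'
#' The size of the alpha tail of an empirical distribution of `N` values:
#' `round_half_up(alpha * N)`. This is exactly the number of flags
#' [flag_significant()] raises.
#'
#' @param n total ranked values (>= 1).
#' @param alpha tail probability, typically 0.05 or 0.01.
#' @return integer count.
#' @export
significant_count <- function(n, alpha) {
  stopifnot(n >= 1, alpha > 0, alpha < 1)
  as.integer(round_half_up(alpha * n))
}

#' Flag values in the alpha tail of the empirical distribution
#'
#' A value is significant iff its rank is within the first
#' `round_half_up(alpha * N)` ranks; the flag set is therefore a prefix of
#' the ranking, and ties at the cutoff (which share the block-maximum rank)
#' are included or excluded as a block.
#'
#' @param ranks data.frame from [rank_and_p()], or an integer rank vector.
#' @param alpha tail probability.
#' @param n total ranked values; taken from `ranks$n` when a data.frame is
#'   supplied.
#' @return logical vector (`NA` ranks give `FALSE`).
#' @export
flag_significant <- function(ranks, alpha = 0.05, n = NULL) {
  if (is.data.frame(ranks)) {
    if (is.null(n)) n <- ranks$n[which(!is.na(ranks$n))[1]]
    ranks <- ranks$rank
  }
  if (is.null(n)) stop("n must be supplied with a bare rank vector")
  out <- !is.na(ranks) & ranks <= significant_count(n, alpha)
  out
}
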