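#' Filter markers by per-population call rate
#'
#' A marker is retained only when its genotype call rate is at or above
#' `threshold` in *every* population listed in `population_set` ("95% or
#' greater" keeps a call rate of exactly 0.95). The filter is applied before
#' any statistic is computed, and is idempotent.
#'
#' @param panels named list of [genotype_panel()] sharing a marker table.
#' @param markers the aligned [marker_table()].
#' @param threshold minimum call rate, in (0, 1]. Default 0.95.
#' @param population_set which populations' call rates must all pass; defaults
#'   to every panel supplied.
#' @return list with filtered `markers`, `panels` (all panels, subset to the
#'   kept markers) and `n_removed`.
#' @export
filter_by_call_rate <- function(panels, markers, threshold = 0.95,
                                population_set = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  labels <- vapply(panels, `[[`, "", "population_label")
  if (is.null(population_set)) population_set <- labels
  if (length(population_set) == 0) stop("population_set must not be empty")
  missing_pop <- setdiff(population_set, labels)
  if (length(missing_pop))
    stop("population(s) not found: ", paste(missing_pop, collapse = ", "))
  keep <- rep(TRUE, nrow(markers))
  for (p in panels[match(population_set, labels)]) {
    cr <- 1 - colMeans(is.na(p$genotypes))
    keep <- keep & cr >= threshold
  }
  n_removed <- sum(!keep)
  if (n_removed > 0)
    message("call-rate filter removed ", n_removed, " of ", nrow(markers),
            " markers")
  out <- subset_markers(markers, panels, keep)
  out$n_removed <- n_removed
  out
}

#' Partition markers into autosomal and X-chromosome sets
#'
#' The genome scan treats the X chromosome as its own empirical distribution,
#' so downstream ranking runs separately per class. Y and mitochondrial
#' markers are dropped (with a message); any other unrecognized chromosome
#' label is an error.
#'
#' @param markers a [marker_table()].
#' @return list with integer index vectors `autosomal`, `x`, and `dropped`.
#' @export
split_by_chromosome_class <- function(markers) {
  lab <- sub("^chr", "", markers$chrom)
  auto <- grepl("^[0-9]+$", lab)
  x <- lab %in% c("X", "x")
  drop <- lab %in% c("Y", "y", "M", "MT", "Mt", "mt")
  bad <- !(auto | x | drop)
  if (any(bad))
    stop("unrecognized chromosome label(s): ",
         paste(unique(markers$chrom[bad]), collapse = ", "))
  if (any(drop))
    message("dropping ", sum(drop), " Y/mitochondrial marker(s)")
  list(autosomal = which(auto), x = which(x), dropped = which(drop))
}
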