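# Target-set overlap: is the intersection of two gene sets larger (or
# smaller) than chance, given a stated gene universe?

#' Build the 2x2 overlap contingency table
#'
#' @param set_a,set_b character vectors of gene IDs; both must be subsets
#'   of `universe` unless `strict = FALSE`, in which case they are
#'   intersected with it (with a warning).
#' @param universe character vector of all gene IDs under consideration.
#' @return list of class `overlap_table` with counts `n_both`, `n_a_only`,
#'   `n_b_only`, `n_neither` and `universe_size`.
#' @param strict error on non-subset inputs (default) instead of
#'   auto-intersecting.
#' @export
contingency <- function(set_a, set_b, universe, strict = TRUE) {
  universe <- unique(universe)
  set_a <- unique(set_a); set_b <- unique(set_b)
  stray <- setdiff(c(setdiff(set_a, universe), setdiff(set_b, universe)), NULL)
  if (length(stray)) {
    if (strict) {
      stop("gene ID(s) outside the universe: ",
           paste(utils::head(stray, 5), collapse = ", "),
           if (length(stray) > 5) sprintf(" (and %d more)", length(stray) - 5))
    }
    warning(length(stray), " gene ID(s) outside the universe dropped")
    set_a <- intersect(set_a, universe)
    set_b <- intersect(set_b, universe)
  }
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  structure(list(
    n_both = sum(in_a & in_b),
    n_a_only = sum(in_a & !in_b),
    n_b_only = sum(!in_a & in_b),
    n_neither = sum(!in_a & !in_b),
    universe_size = length(universe)
  ), class = "overlap_table")
}

#' Two-tailed Fisher's exact test on an overlap table
#'
#' The two-tailed p-value follows the probability-mass convention: the sum
#' of hypergeometric probabilities of all tables with the observed margins
#' that are at most as probable as the observed table (as in
#' [stats::fisher.test()]). Degenerate margins (an empty set or a set equal
#' to the universe) admit a single table and give p = 1. The odds ratio is
#' the sample cross-product ratio (`Inf` when a denominator cell is 0 and
#' the numerator is positive); fold enrichment is observed over expected
#' overlap under independence.
#'
#' @param table an `overlap_table` from [contingency()].
#' @return list of class `overlap_result` with elements `table`,
#'   `odds_ratio`, `p_two_tailed`, `fold_enrichment`.
#' @export
fisher_exact_two_tailed <- function(table) {
  stopifnot(inherits(table, "overlap_table"))
  m <- matrix(c(table$n_both, table$n_a_only, table$n_b_only,
                table$n_neither), nrow = 2L, byrow = TRUE)
  p <- stats::fisher.test(m, alternative = "two.sided")$p.value
  num <- as.numeric(table$n_both) * table$n_neither
  den <- as.numeric(table$n_a_only) * table$n_b_only
  or <- if (den == 0) { if (num == 0) NaN else Inf } else num / den
  na <- table$n_both + table$n_a_only
  nb <- table$n_both + table$n_b_only
  fe <- if (na > 0 && nb > 0) {
    table$n_both * as.numeric(table$universe_size) / (as.numeric(na) * nb)
  } else NA_real_
  structure(list(table = table, odds_ratio = or,
                 p_two_tailed = min(1, p), fold_enrichment = fe),
            class = "overlap_result")
}

#' Test overlap between two gene sets
#'
#' Convenience wrapper: builds the contingency table over the universe and
#' runs the two-tailed Fisher's exact test.
#'
#' @inheritParams contingency
#' @return An `overlap_result` (see [fisher_exact_two_tailed()]).
#' @export
overlap_test <- function(set_a, set_b, universe, strict = TRUE) {
  fisher_exact_two_tailed(contingency(set_a, set_b, universe, strict))
}

#' @export
print.overlap_result <- function(x, ...) {
  t <- x$table
  cat(sprintf(
    "overlap %d | A-only %d | B-only %d | neither %d (universe %d)\n",
    t$n_both, t$n_a_only, t$n_b_only, t$n_neither, t$universe_size))
  cat(sprintf("odds ratio %.3g, fold enrichment %.3g, two-tailed p = %.3g\n",
              x$odds_ratio, x$fold_enrichment, x$p_two_tailed))
  invisible(x)
}
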