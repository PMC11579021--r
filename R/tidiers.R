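# broom-style accessors for the report object.

#' Tidy a subgenome report
#'
#' @param x A `subgenome_report`.
#' @param ... Unused.
#' @return The contrast table: one row per statistical contrast with
#'   `event`, `test`, `statistic`, `p_value`, `p_adjust`, `family`.
#' @export
tidy.subgenome_report <- function(x, ...) {
  x$contrasts
}

#' One-row summary of a subgenome report
#'
#' @param x A `subgenome_report`.
#' @param ... Unused.
#' @return One-row tibble: feature totals, the AS homoeolog-overlap
#'   percentages, and the smallest adjusted p-value.
#' @export
glance.subgenome_report <- function(x, ...) {
  tibble::tibble(
    n_lncrna = x$n_lncrna,
    n_circrna = x$n_circrna,
    n_editing_sites = x$n_editing_sites,
    overlap_both_pct = unname(x$overlap_as$percent["both"]),
    overlap_a_only_pct = unname(x$overlap_as$percent["A_only"]),
    overlap_b_only_pct = unname(x$overlap_as$percent["B_only"]),
    min_p_adjust = suppressWarnings(min(x$contrasts$p_adjust)),
    n_contrasts = nrow(x$contrasts)
  )
}
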