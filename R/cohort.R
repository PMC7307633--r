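# Cohort-level tabulation and the depth-vs-basal-TDBL association.

#' Tabulate a cohort of reconstructions
#'
#' Builds one row per cell from morphometry summaries and, per age group,
#' the Spearman rank correlation between normalised soma depth in layer 2
#' and total basal dendritic branch length — the superficial-to-deep
#' gradient of basal tree size that separates layer 2a from layer 2b
#' neurons. The association needs at least 3 cells in a group and
#' non-constant inputs; otherwise it is reported as missing.
#'
#' @param summaries list of [morphometry_summary()] objects whose
#'   `metadata` carries `age_group`, `cell_class` and `depth_norm`.
#' @return data.frame (class `cohort_table`), one row per cell with columns
#'   `age_group`, `cell_class`, `depth_norm` and apical/basal scalar
#'   morphometrics; the per-age-group association table
#'   (`age_group`, `n`, `spearman_rho`) is in `attr(, "association")`.
#' @export
cohort_table <- function(summaries) {
  stopifnot(is.list(summaries), length(summaries) >= 1L)
  rows <- lapply(summaries, function(s) {
    stopifnot(inherits(s, "morphometry_summary"))
    md <- s$metadata
    data.frame(
      age_group = md$age_group %||% NA_character_,
      cell_class = md$cell_class %||% NA_character_,
      depth_norm = md$depth_norm %||% NA_real_,
      apical_NB = s$apical$NB, apical_TDBL = s$apical$TDBL,
      apical_mean_BL = s$apical$mean_BL,
      apical_stems = s$apical$n_stems, apical_tips = s$apical$n_tips,
      apical_intermediate = s$apical$n_intermediate,
      basal_NB = s$basal$NB, basal_TDBL = s$basal$TDBL,
      basal_mean_BL = s$basal$mean_BL,
      basal_stems = s$basal$n_stems, basal_tips = s$basal$n_tips,
      basal_intermediate = s$basal$n_intermediate,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  groups <- unique(tab$age_group)
  assoc <- do.call(rbind, lapply(groups, function(g) {
    sub <- tab[is.na(g) & is.na(tab$age_group) |
                 (!is.na(tab$age_group) & !is.na(g) & tab$age_group == g), ]
    rho <- NA_real_
    ok <- nrow(sub) >= 3L &&
      all(is.finite(sub$depth_norm)) &&
      stats::sd(sub$depth_norm) > 0 && stats::sd(sub$basal_TDBL) > 0
    if (ok)
      rho <- stats::cor(sub$depth_norm, sub$basal_TDBL, method = "spearman")
    data.frame(age_group = g, n = nrow(sub), spearman_rho = rho,
               stringsAsFactors = FALSE)
  }))
  attr(tab, "association") <- assoc
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d cells\n", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...\n")
  cat("depth vs basal TDBL (Spearman), per age group:\n")
  print.data.frame(attr(x, "association"))
  invisible(x)
}
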