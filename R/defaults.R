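#' Method defaults
#'
#' The parameter values the method is defined with: 1,000 permutation
#' replicates, GDS weights \{1, 2, 3\} (none / yeast / mouse evidence),
#' GISTIC call domain \{-2, ..., 2\}, top-5 per-pathway summary tables and
#' top-10 QC tables, cohort-network visualization cuts of 1/3 (SCNA
#' prevalence) and 0.10 (mutation rate), and log2-ratio discretization cuts
#' of +/-0.3 (single copy) and +/-1.3 (multi-copy).
#'
#' @return Named list of default parameter values.
#' @export
#' @examples
#' haptrig_defaults()$n_reps
haptrig_defaults <- function() {
  list(
    n_reps        = 1000L,
    alpha         = 0.05,
    gds_weights   = c(none = 1L, yeast = 2L, mouse = 3L),
    gistic_domain = -2L:2L,
    k_summary     = 5L,
    k_qc          = 10L,
    scna_edge_cut = 1 / 3,
    mut_cut       = 0.10,
    log2_cuts     = c(t_del2 = -1.3, t_del1 = -0.3, t_amp1 = 0.3, t_amp2 = 1.3),
    scorer        = "gds_linear"
  )
}

#' Bonferroni comparison-count presets
#'
#' Two presets mirror the published analyses: `"pan_kegg"` tests all 187
#' distinct human KEGG pathways in one cohort; `"proteostasis_pan_cancer"`
#' tests 6 proteostasis pathways across 21 cancer types (126 comparisons).
#'
#' @param preset `"pan_kegg"` or `"proteostasis_pan_cancer"`.
#' @return Integer number of comparisons.
#' @export
#' @examples
#' bonferroni_preset("pan_kegg")
bonferroni_preset <- function(preset = c("pan_kegg", "proteostasis_pan_cancer")) {
  preset <- match.arg(preset)
  c(pan_kegg = 187L, proteostasis_pan_cancer = 126L)[[preset]]
}
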