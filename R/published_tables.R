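# -- Published summary tables --------------------------------------------
#
# The original study's printed summary tables (cohort characteristics and
# per-haplogroup counts with their tested/untested flags) are shipped as
# plain CSV data.  They serve three purposes: desk-scale reproduction
# checks (count percentages, minimum-carrier partition, family Bonferroni
# thresholds), calibration defaults for the synthetic cohort generator,
# and report layouts.

published_path <- function(file)
  system.file("extdata", "published", file, package = "mthaplotau")

#' Published cohort-characteristics percentages
#'
#' Category counts with their printed denominators and percentages for
#' the study cohort (sex, clinical subtype, Braak stage, Thal phase).
#' Percentages use non-missing denominators.
#'
#' @return Data frame `group`, `variable`, `level`, `numerator`,
#'   `denominator`, `printed_pct`.
#' @export
published_table1 <- function() {
  utils::read.csv(published_path("table1_percentages.csv"),
                  stringsAsFactors = FALSE,
                  colClasses = c(level = "character"))
}

#' Published per-haplogroup counts for the risk analyses
#'
#' One row per analysis haplogroup row with carrier counts (and printed
#' percentages) in controls, PSP and CBD, plus the printed tested /
#' untested flags of both risk comparisons.
#'
#' @return Data frame with columns `row_label`, `members`
#'   (semicolon-joined node names), `n_control`, `pct_control`, `n_psp`,
#'   `pct_psp`, `n_cbd`, `pct_cbd`, `tested_psp`, `tested_cbd`.
#' @export
published_table2 <- function() {
  utils::read.csv(published_path("table2_haplogroup_counts.csv"),
                  stringsAsFactors = FALSE)
}

#' Published per-haplogroup carrier counts in the tau-scored case subsets
#'
#' @param disease `"PSP"` (N = 764 scored cases) or `"CBD"` (N = 150).
#' @return Data frame `row_label`, `members`, `n`, `tested`.
#' @export
published_tau_counts <- function(disease = c("PSP", "CBD")) {
  disease <- match.arg(disease)
  f <- if (disease == "PSP") "table3_psp_tau_rows.csv"
       else "table4_cbd_tau_rows.csv"
  utils::read.csv(published_path(f), stringsAsFactors = FALSE)
}

#' Default per-node haplogroup frequencies from the published controls
#'
#' Exclusive per-node frequencies over the control column of the
#' published risk table: nested combined rows are resolved to their
#' member nodes, and the two rows printed only in combined form
#' ("R and R0", "HV and HV0a") are split evenly across their members.
#'
#' @param tree A `haplo_tree` (nodes absent from the counts get
#'   frequency 0).
#' @return Named numeric vector over the tree's nodes, summing to 1.
#' @export
control_haplogroup_freqs <- function(tree = default_tree()) {
  t2 <- published_table2()
  single <- t2[!grepl(";", t2$members), , drop = FALSE]
  counts <- stats::setNames(single$n_control, single$members)
  # combined-only rows: split evenly over members
  for (lab in c("R and R0", "HV and HV0a")) {
    row <- t2[t2$row_label == lab, ]
    members <- strsplit(row$members, ";")[[1]]
    counts[members] <- row$n_control / length(members)
  }
  freqs <- rep(0, length(tree$nodes))
  names(freqs) <- names(tree$nodes)
  common <- intersect(names(counts), names(freqs))
  freqs[common] <- counts[common]
  freqs / sum(freqs)
}

#' Format a count with its percentage
#'
#' `"564 (54.1%)"`-style formatting with percentages to one decimal and
#' the non-missing denominator.
#'
#' @param n Numerator count(s).
#' @param denom Denominator.
#' @return Character vector; dashes when `denom` is zero.
#' @export
fmt_count_pct <- function(n, denom) {
  if (length(denom) == 1L) denom <- rep(denom, length(n))
  ifelse(denom > 0,
         sprintf("%d (%.1f%%)", as.integer(n), round(100 * n / denom, 1)),
         "-")
}

#' Format a p-value the way the published tables print them
#'
#' Two significant figures, expanding to up to four decimals for small
#' values (e.g. `0.0023`).
#'
#' @param p Numeric p-values.
#' @return Character vector.
#' @export
fmt_pvalue <- function(p) {
  ifelse(is.na(p), "-",
         ifelse(p < 1e-4, format(signif(p, 2), scientific = TRUE),
                ifelse(p < 0.01, sprintf("%.4f", signif(p, 2)),
                       sprintf("%.2g", signif(p, 2)))))
}
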