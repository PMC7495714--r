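# -- Study pipeline ------------------------------------------------------
#
# run_study() composes the whole chain: raw calls -> genotype QC ->
# haplogroup calling -> European filter -> tau aggregation -> association
# families -> report tables.  Inputs come either from files or from the
# synthetic generator, never both.

#' Build and validate a study run configuration
#'
#' Exactly one of a `simulate` block ([sim_config()]) or the set of input
#' file paths must be given.
#'
#' @param tree_path Path to a tree document (default: the shipped
#'   European tree).
#' @param genotype_path,subject_path,tau_path Input TSV paths (file
#'   mode).
#' @param simulate A [sim_config()] (simulate mode).
#' @param min_delta,rate_threshold,min_count,alpha Pipeline thresholds.
#' @param output_dir Directory for report tables; `NULL` disables
#'   writing.
#' @return A list of class `run_config`.
#' @export
run_config <- function(tree_path = NULL, genotype_path = NULL,
                       subject_path = NULL, tau_path = NULL,
                       simulate = NULL, min_delta = 5,
                       rate_threshold = 0.95, min_count = 10,
                       alpha = 0.05, output_dir = NULL) {
  file_mode <- !is.null(genotype_path) || !is.null(subject_path) ||
    !is.null(tau_path)
  problems <- character(0)
  if (file_mode && !is.null(simulate))
    problems <- c(problems,
                  "give either input paths or a simulate block, not both")
  if (!file_mode && is.null(simulate))
    problems <- c(problems, "one of input paths or simulate block required")
  if (file_mode && (is.null(genotype_path) || is.null(subject_path)))
    problems <- c(problems,
                  "file mode needs genotype_path and subject_path")
  if (min_delta < 0 || rate_threshold <= 0 || rate_threshold > 1 ||
      min_count <= 0 || alpha <= 0 || alpha >= 1)
    problems <- c(problems, "thresholds out of range")
  if (length(problems))
    stop("invalid run config:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  structure(list(tree_path = tree_path, genotype_path = genotype_path,
                 subject_path = subject_path, tau_path = tau_path,
                 simulate = simulate, min_delta = min_delta,
                 rate_threshold = rate_threshold, min_count = min_count,
                 alpha = alpha, output_dir = output_dir),
            class = "run_config")
}

#' Run the full study pipeline
#'
#' Executes QC, haplogroup calling, European filtering, tau aggregation
#' and every association family, and assembles the report bundle: one
#' result table per family, a cohort characteristics table, the
#' assignment table, a QC/attrition log accounting for every input
#' subject exactly once, and a machine-readable list of all results.
#' Tables are written as TSV under `config$output_dir` when set.
#'
#' @param config A [run_config()].
#' @param tree Optional pre-loaded `haplo_tree` (overrides
#'   `config$tree_path`).
#' @return The report bundle (list), invisibly when written to disk.
#' @export
run_study <- function(config, tree = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(tree))
    tree <- if (is.null(config$tree_path)) default_tree()
            else load_tree(config$tree_path)

  if (!is.null(config$simulate)) {
    sim <- simulate_cohort(config$simulate, tree)
    subjects <- sim$subjects; raw <- sim$raw_calls
    tau_scores <- sim$tau_scores; truth <- sim$truth
  } else {
    raw <- read_genotype_tsv(config$genotype_path)
    subjects <- utils::read.delim(config$subject_path,
                                  stringsAsFactors = FALSE)
    tau_scores <- if (!is.null(config$tau_path))
      utils::read.delim(config$tau_path, stringsAsFactors = FALSE)
    else NULL
    truth <- NULL
  }

  qc <- qc_cohort(raw, tree$panel, config$rate_threshold, config$min_delta)
  assignments <- call_haplogroups(qc$genotypes, tree, qc$qc_table)
  part <- filter_european(assignments, tree)

  analysed <- merge(subjects, part$kept[, c("sample_id", "haplogroup",
                                            "super_haplogroup")],
                    by.x = "subject_id", by.y = "sample_id")
  dropped <- merge(subjects, part$removed[, c("sample_id",
                                              "removal_reason")],
                   by.x = "subject_id", by.y = "sample_id")
  missing_calls <- setdiff(subjects$subject_id,
                           c(analysed$subject_id, dropped$subject_id))
  if (length(missing_calls))
    dropped <- rbind(dropped,
                     cbind(subjects[subjects$subject_id %in% missing_calls, ,
                                    drop = FALSE],
                           removal_reason = "no_genotype_data"))

  tau_summary <- if (!is.null(tau_scores) && nrow(tau_scores))
    summarize_tau(tau_scores)
  else NULL

  families <- list(
    PSP_risk = run_risk_family(analysed, "PSP", min_count = config$min_count,
                               alpha = config$alpha),
    CBD_risk = run_risk_family(analysed, "CBD", min_count = config$min_count,
                               alpha = config$alpha),
    PSP_duration_onset = run_onset_duration_family(
      analysed, min_count = config$min_count, alpha = config$alpha))
  if (!is.null(tau_summary)) {
    families$PSP_tau <- run_tau_family(analysed, tau_summary, "PSP",
                                       min_count = config$min_count,
                                       alpha = config$alpha)
    if (any(tau_summary$group == "CBD"))
      families$CBD_tau <- run_tau_family(analysed, tau_summary, "CBD",
                                         min_count = config$min_count,
                                         alpha = config$alpha)
  }
  super_rows <- super_analysis_rows(tree)
  if (length(super_rows)) {
    families$PSP_risk_super <- run_risk_family(
      analysed, "PSP", rows = super_rows, min_count = config$min_count,
      alpha = config$alpha, secondary = TRUE)
    families$CBD_risk_super <- run_risk_family(
      analysed, "CBD", rows = super_rows, min_count = config$min_count,
      alpha = config$alpha, secondary = TRUE)
  }

  bundle <- list(
    characteristics = characteristics_table(analysed, tau_summary),
    assignments = assignments,
    qc_log = list(qc_table = qc$qc_table,
                  analysed = analysed$subject_id,
                  dropped = dropped[, c("subject_id", "removal_reason")]),
    families = families,
    tau_summary = tau_summary,
    truth = truth)

  if (!is.null(config$output_dir)) {
    write_report_bundle(bundle, config$output_dir)
    return(invisible(bundle))
  }
  bundle
}

median_range <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return("-")
  sprintf("%.2f (%.2f, %.2f)", stats::median(x), min(x), max(x))
}

#' Cohort characteristics table
#'
#' Per-group summaries in the published layout: median (minimum, maximum)
#' for continuous variables, count (percentage to one decimal) for
#' categorical ones.  Percentages use the non-missing denominator of each
#' variable; empty groups print dashes.
#'
#' @param subjects Analysed subject table.
#' @param tau_summary Optional output of [summarize_tau()], adding
#'   per-measure tau burden rows.
#' @return Data frame `variable`, `level`, one column per group.
#' @export
characteristics_table <- function(subjects, tau_summary = NULL) {
  groups <- c("PSP", "CBD", "control")
  rows <- list()
  add <- function(variable, level, values)
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, level = level,
      t(stats::setNames(values, groups)), check.names = FALSE,
      stringsAsFactors = FALSE)

  by_group <- function(f) vapply(groups, function(g)
    f(subjects[subjects$group == g, , drop = FALSE]), character(1))

  add("N", "", by_group(function(d) as.character(nrow(d))))
  add("Age (years)", "", by_group(function(d) median_range(d$age)))
  for (lv in c("male", "female"))
    add("Sex", lv, by_group(function(d) {
      denom <- sum(!is.na(d$sex))
      if (!denom) "-" else fmt_count_pct(sum(d$sex == lv, na.rm = TRUE),
                                         denom)
    }))
  add("Age of onset (years)", "",
      by_group(function(d) if (all(is.na(d$age_of_onset))) "-"
               else median_range(d$age_of_onset)))
  add("Disease duration (years)", "",
      by_group(function(d) if (all(is.na(d$disease_duration))) "-"
               else median_range(d$disease_duration)))
  for (lv in 0:6)
    add("Braak stage", as.character(lv), by_group(function(d) {
      denom <- sum(!is.na(d$braak))
      if (!denom) "-" else fmt_count_pct(sum(d$braak == lv, na.rm = TRUE),
                                         denom)
    }))
  for (lv in 0:5)
    add("Thal phase", as.character(lv), by_group(function(d) {
      denom <- sum(!is.na(d$thal))
      if (!denom) "-" else fmt_count_pct(sum(d$thal == lv, na.rm = TRUE),
                                         denom)
    }))
  if (!is.null(tau_summary)) {
    for (msr in unique(tau_summary$measure)) {
      ts <- tau_summary[tau_summary$measure == msr & tau_summary$included, ]
      add(paste(msr, "tau pathology score"), "",
          vapply(groups, function(g) {
            x <- ts$mean_score[ts$group == g]
            if (!length(x)) "-" else median_range(x)
          }, character(1)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

format_family_table <- function(family) {
  res <- family$results
  est <- ifelse(res$tested,
                sprintf("%.2f (%.2f, %.2f)", res$estimate, res$ci_low,
                        res$ci_high), "-")
  data.frame(haplogroup = res$haplogroup,
             measure = if ("measure" %in% names(res)) res$measure else "",
             outcome = if ("outcome_name" %in% names(res)) res$outcome_name
                       else "",
             n_exposed = res$n_exposed, estimate_ci = est,
             p_value = fmt_pvalue(res$p_value), tested = res$tested,
             significant = res$significant, stringsAsFactors = FALSE)
}

write_report_bundle <- function(bundle, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(output_dir, f), sep = "\t", row.names = FALSE,
    quote = FALSE)
  wt(bundle$characteristics, "characteristics.tsv")
  wt(bundle$assignments, "assignments.tsv")
  wt(bundle$qc_log$qc_table, "qc_log.tsv")
  wt(bundle$qc_log$dropped, "dropped_subjects.tsv")
  for (nm in names(bundle$families)) {
    fam <- bundle$families[[nm]]
    wt(format_family_table(fam), paste0("family_", nm, ".tsv"))
  }
  if (!is.null(bundle$tau_summary)) wt(bundle$tau_summary, "tau_summary.tsv")
  results_json <- list(
    schema_version = "1.0",
    families = lapply(bundle$families, function(f)
      list(label = f$label, m_tests = f$m_tests, threshold = f$threshold,
           results = f$results)))
  jsonlite::write_json(results_json,
                       file.path(output_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(output_dir)
}
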