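# -- Desk-scale reproduction checks and simulation experiments -----------
#
# The published summary tables shipped with the package are treated as
# inputs: their printed counts feed the same minimum-carrier and
# Bonferroni machinery the pipeline applies to real data, so the
# tested/untested partition, the family thresholds and the printed
# percentages can be recomputed from scratch.  The simulation experiments
# measure end-to-end parameter recovery of the full pipeline on synthetic
# cohorts with known ground truth.

#' Crude odds ratio from a 2x2 of carrier counts
#'
#' Cross-product odds ratio of carrier status between cases and controls,
#' e.g. for the H4/CBD cell: (9/162) / (11/899).
#'
#' @param n_case,total_case Carriers and group size among cases.
#' @param n_control,total_control Same for controls.
#' @return The crude OR.
#' @export
crude_odds_ratio <- function(n_case, total_case, n_control, total_control) {
  (n_case / (total_case - n_case)) /
    (n_control / (total_control - n_control))
}

#' Recompute the tested/untested partition of the risk analyses
#'
#' Applies the minimum-carrier rule to the published carrier counts: a
#' row is tested when cases plus controls carry it at least `min_count`
#' times.  Returns the recomputed flag next to the published one.
#'
#' @param disease `"PSP"` or `"CBD"`.
#' @param min_count Carrier minimum (default 10).
#' @return Data frame `row_label`, `n_carriers`, `tested`,
#'   `tested_published`.
#' @export
recompute_risk_partition <- function(disease = c("PSP", "CBD"),
                                     min_count = 10) {
  disease <- match.arg(disease)
  t2 <- published_table2()
  n_case <- if (disease == "PSP") t2$n_psp else t2$n_cbd
  published <- if (disease == "PSP") t2$tested_psp else t2$tested_cbd
  carriers <- n_case + t2$n_control
  data.frame(row_label = t2$row_label, n_carriers = carriers,
             tested = vapply(carriers, min_count_filter, logical(1),
                             min_count = min_count),
             tested_published = published, stringsAsFactors = FALSE)
}

#' Recompute all four primary Bonferroni thresholds from printed counts
#'
#' Rebuilds each family's tested set from its published carrier counts
#' (risk families: carriers across cases and controls; tau families:
#' carriers among scored cases, with the H4 override in the CBD family)
#' and derives the family threshold through [bonferroni_family()].
#'
#' @param alpha Family alpha (default 0.05).
#' @return Data frame `family`, `m_tests`, `threshold`.
#' @export
recompute_family_thresholds <- function(alpha = 0.05) {
  mk_results <- function(labels, tested, family)
    data.frame(haplogroup = labels, comparison = family, n_exposed = 0L,
               estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
               p_value = ifelse(tested, 1, NA_real_), tested = tested,
               unstable = FALSE, exclusion_reason = NA_character_,
               significant = FALSE, stringsAsFactors = FALSE)
  fams <- list()
  for (disease in c("PSP", "CBD")) {
    part <- recompute_risk_partition(disease)
    fams[[paste0(disease, "_risk")]] <- mk_results(
      part$row_label, part$tested, paste0(disease, "_risk"))
    tc <- published_tau_counts(disease)
    force <- if (disease == "CBD") "H4" else character(0)
    tested <- vapply(seq_len(nrow(tc)), function(i)
      min_count_filter(tc$n[i], label = tc$row_label[i],
                       force_test = force), logical(1))
    fams[[paste0(disease, "_tau")]] <- mk_results(
      tc$row_label, tested, paste0(disease, "_tau"))
  }
  out <- do.call(rbind, lapply(names(fams), function(nm) {
    fam <- bonferroni_family(fams[[nm]], alpha)
    data.frame(family = nm, m_tests = fam$m_tests,
               threshold = fam$threshold, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Recompute every printed count percentage of the summary tables
#'
#' Re-derives each printed percentage from its printed numerator and
#' denominator (characteristics table categories and the three
#' haplogroup-frequency columns of the risk table) at the printed
#' one-decimal precision.
#'
#' @return Data frame `table`, `label`, `numerator`, `denominator`,
#'   `computed_pct`, `printed_pct`, `abs_error`.
#' @export
recompute_published_percentages <- function() {
  t1 <- published_table1()
  rows1 <- data.frame(
    table = "characteristics",
    label = paste(t1$group, t1$variable, t1$level),
    numerator = t1$numerator, denominator = t1$denominator,
    printed_pct = t1$printed_pct, stringsAsFactors = FALSE)
  t2 <- published_table2()
  totals <- c(control = 910L, psp = 1042L, cbd = 171L)
  rows2 <- do.call(rbind, lapply(names(totals), function(col) {
    data.frame(table = "haplogroup_frequencies",
               label = paste(col, t2$row_label),
               numerator = t2[[paste0("n_", col)]],
               denominator = totals[[col]],
               printed_pct = t2[[paste0("pct_", col)]],
               stringsAsFactors = FALSE)
  }))
  out <- rbind(rows1, rows2)
  out$computed_pct <- round(100 * out$numerator / out$denominator, 1)
  out$abs_error <- abs(out$computed_pct - out$printed_pct)
  out
}

#' Perfect-data round-trip accuracy of the haplogroup caller
#'
#' For every node of the tree, synthesises a sample carrying exactly the
#' node's defining path (derived on path, ancestral elsewhere, no noise)
#' and checks that the full QC + calling chain returns that node.
#'
#' @param tree A `haplo_tree`.
#' @return Fraction of nodes recovered (root counts as recovered when
#'   reported `unassigned`).
#' @export
caller_roundtrip_accuracy <- function(tree = default_tree()) {
  cfg <- sim_config(nocall_rate = 0, intensity_sd = 0)
  hits <- vapply(names(tree$nodes), function(nm) {
    raw <- simulate_genotypes(nm, tree, cfg, seed = 1, sample_id = nm)
    a <- assign_haplogroup(qc_sample(raw, tree$panel), tree)
    if (nm == tree$root) identical(a$status, "unassigned")
    else identical(a$haplogroup, nm)
  }, logical(1))
  mean(hits)
}

#' Agreement between the caller and a brute-force assignment oracle
#'
#' Simulates noisy samples with haplogroups drawn uniformly over the
#' tree, then compares the vectorised caller against an unpruned
#' brute-force enumeration: every node is path-checked directly from
#' [defining_path()], the deepest match taken, and every disjoint
#' clade's defining SNPs scanned for contradictions.
#'
#' @param n_samples Number of simulated samples.
#' @param seed Seed.
#' @param tree A `haplo_tree`.
#' @return Fraction of samples on which caller and oracle agree in
#'   status and haplogroup.
#' @export
caller_oracle_agreement <- function(n_samples = 1000, seed = 1,
                                    tree = default_tree()) {
  cfg <- sim_config(seed = seed)
  set.seed(seed)
  haps <- sample(names(tree$nodes), n_samples, replace = TRUE)
  raw <- do.call(rbind, lapply(seq_len(n_samples), function(i)
    simulate_genotypes(haps[i], tree, cfg,
                       seed = subject_seed(seed, i),
                       sample_id = sprintf("o%05d", i))))
  qc <- qc_cohort(raw, tree$panel)
  vec <- call_haplogroups(qc$genotypes, tree, qc$qc_table)

  oracle_one <- function(sample) {
    if (!isTRUE(sample$passed_qc))
      return(list(haplogroup = NA_character_, status = "failed_qc"))
    depth <- vapply(names(tree$nodes), function(nm)
      length(ancestors_of(tree, nm)), integer(1))
    ok <- vapply(names(tree$nodes), function(nm) {
      path <- defining_path(tree, nm)
      if (!nrow(path)) return(TRUE)
      got <- sample$calls[as.character(path$position)]
      all(!is.na(got) & got == path$derived)
    }, logical(1))
    cands <- names(tree$nodes)[ok]
    best <- cands[depth[cands] == max(depth[cands])]
    if (length(best) > 1L)
      return(list(haplogroup = NA_character_, status = "conflict"))
    for (nm in disjoint_clades(tree, best)) {
      snps <- tree$nodes[[nm]]$snps
      for (k in seq_len(nrow(snps))) {
        got <- sample$calls[as.character(snps$position[k])]
        if (!is.na(got) && got == snps$derived[k])
          return(list(haplogroup = NA_character_, status = "conflict"))
      }
    }
    if (best == tree$root)
      return(list(haplogroup = NA_character_, status = "unassigned"))
    list(haplogroup = best, status = "assigned")
  }

  ids <- qc$qc_table$sample_id
  agree <- vapply(ids, function(id) {
    o <- oracle_one(qc$samples[[id]])
    row <- vec[vec$sample_id == id, ]
    identical(row$status, o$status) &&
      (o$status != "assigned" || identical(row$haplogroup, o$haplogroup))
  }, logical(1))
  mean(agree)
}

#' Coverage of an injected disease odds ratio by the pipeline's CI
#'
#' Repeatedly simulates a case-control study with a known odds ratio
#' injected for one haplogroup, runs the full chain (genotype
#' simulation, QC, haplogroup calling, European filter, adjusted
#' logistic fit) and records whether the reported 95% CI covers the
#' truth.  Defaults mirror the headline configuration: OR 4.5 for H4
#' against CBD at the published control frequencies and group sizes.
#'
#' @param n_reps Number of replicate studies.
#' @param seed Seed (each replicate derives its own).
#' @param haplogroup Haplogroup receiving the injection.
#' @param true_or Injected odds ratio.
#' @param disease `"PSP"` or `"CBD"`.
#' @param n_case,n_control Group sizes (defaults: published CBD study).
#' @return List with `coverage`, per-replicate `estimates`, and the
#'   number of informative replicates `n_reps`.
#' @export
or_coverage_experiment <- function(n_reps = 200, seed = 1,
                                   haplogroup = "H4", true_or = 4.5,
                                   disease = "CBD", n_case = 171,
                                   n_control = 910) {
  tree <- default_tree()
  rows <- stats::setNames(list(haplogroup), haplogroup)
  covered <- logical(n_reps)
  estimates <- numeric(n_reps)
  lo <- stats::setNames(list(stats::setNames(log(true_or), haplogroup)),
                        disease)
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(
      n_psp = if (disease == "PSP") n_case else 0L,
      n_cbd = if (disease == "CBD") n_case else 0L,
      n_control = n_control, risk_log_odds = lo,
      tau_scored_fraction = c(PSP = 0, CBD = 0),  # risk-only replicates
      seed = subject_seed(seed, 3000000 + r))
    sim <- simulate_cohort(cfg, tree)
    qc <- qc_cohort(sim$raw_calls, tree$panel)
    part <- filter_european(call_haplogroups(qc$genotypes, tree,
                                             qc$qc_table), tree)
    subj <- merge(sim$subjects,
                  part$kept[, c("sample_id", "haplogroup")],
                  by.x = "subject_id", by.y = "sample_id")
    fam <- run_risk_family(subj, disease, rows = rows)
    res <- fam$results
    covered[r] <- isTRUE(res$tested) && res$ci_low <= true_or &&
      true_or <= res$ci_high
    estimates[r] <- if (isTRUE(res$tested)) res$estimate else NA_real_
  }
  list(coverage = mean(covered), estimates = estimates, n_reps = n_reps)
}

#' Recovery of an injected tau score shift
#'
#' Simulates case-only cohorts with a latent tau score shift injected
#' for carriers of one haplogroup, runs tau aggregation and the adjusted
#' linear model, and reports sign recovery and the mean estimate.
#' Defaults mirror the reported NT deficit for the HV lineage in PSP.
#'
#' @param n_reps Replicates.
#' @param seed Seed.
#' @param haplogroups Carrier set defining the analysis row.
#' @param measure Tau measure shifted and analysed.
#' @param shift Latent-scale shift injected for carriers.
#' @param n_case Number of cases (default: published scored PSP subset).
#' @return List with `sign_rate` (fraction of replicates recovering the
#'   sign among tested ones), `mean_estimate`, `n_tested`.
#' @export
tau_shift_experiment <- function(n_reps = 50, seed = 1,
                                 haplogroups = c("HV", "HV0a"),
                                 measure = "NT", shift = -0.35,
                                 n_case = 764) {
  tree <- default_tree()
  label <- paste(haplogroups, collapse = " and ")
  rows <- stats::setNames(list(haplogroups), label)
  est <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- sim_config(
      n_psp = n_case, n_cbd = 0L, n_control = 0L,
      tau_shifts = data.frame(haplogroup = haplogroups, measure = measure,
                              shift = shift, stringsAsFactors = FALSE),
      tau_scored_fraction = c(PSP = 1, CBD = 1),
      seed = subject_seed(seed, 4000000 + r))
    sim <- simulate_cohort(cfg, tree)
    qc <- qc_cohort(sim$raw_calls, tree$panel)
    part <- filter_european(call_haplogroups(qc$genotypes, tree,
                                             qc$qc_table), tree)
    subj <- merge(sim$subjects,
                  part$kept[, c("sample_id", "haplogroup")],
                  by.x = "subject_id", by.y = "sample_id")
    ts <- summarize_tau(sim$tau_scores)
    fam <- run_tau_family(subj, ts, "PSP", measures = measure,
                          rows = rows, force_test = label)
    res <- fam$results
    if (isTRUE(res$tested)) est[r] <- res$estimate
  }
  tested <- !is.na(est)
  list(sign_rate = mean(sign(est[tested]) == sign(shift)),
       mean_estimate = mean(est[tested]), n_tested = sum(tested))
}

#' Null calibration of the whole pipeline
#'
#' Simulates zero-effect studies at the published scale, runs every
#' primary association family and counts how often a family reports any
#' Bonferroni-significant haplogroup.  Under the null each family's
#' chance of any flag is at most alpha, so the rate over (replicate,
#' family) pairs should not exceed alpha beyond Monte-Carlo error.
#'
#' Under the published correction scheme a family's threshold is
#' `alpha` divided by its number of tested *haplogroups*, while tau
#' families test each haplogroup for four measures (and the
#' onset/duration family for two outcomes).  The Bonferroni-expected
#' number of false flags in a family is therefore the sum of the
#' threshold over all tested results, not `alpha`; both the expectation
#' and the observed counts are returned so they can be compared
#' directly.
#'
#' @param n_reps Number of replicate studies.
#' @param seed Seed.
#' @param n_psp,n_cbd,n_control Group sizes (published defaults).
#' @return List with `n_flags` / `expected_flags` (observed and
#'   Bonferroni-expected significant results over all replicates),
#'   `flag_rate` / `expected_flag_rate` (per tested result),
#'   `family_rate` / `expected_family_rate` (fraction of (replicate,
#'   family) pairs with >= 1 flag, against its union-bound
#'   expectation), `n_pairs` and `n_results`.
#' @export
null_calibration_experiment <- function(n_reps = 100, seed = 1,
                                        n_psp = 1042, n_cbd = 171,
                                        n_control = 910) {
  fam_hits <- 0L; n_pairs <- 0L
  n_flags <- 0L; n_results <- 0L
  expected_flags <- 0; expected_any <- 0
  primary <- c("PSP_risk", "CBD_risk", "PSP_duration_onset", "PSP_tau",
               "CBD_tau")
  for (r in seq_len(n_reps)) {
    cfg <- run_config(simulate = sim_config(
      n_psp = n_psp, n_cbd = n_cbd, n_control = n_control,
      seed = subject_seed(seed, 5000000 + r)))
    bundle <- run_study(cfg)
    for (nm in intersect(primary, names(bundle$families))) {
      fam <- bundle$families[[nm]]
      if (fam$m_tests == 0L) next
      k <- sum(fam$results$tested)   # tested (row, outcome) results
      n_pairs <- n_pairs + 1L
      fam_hits <- fam_hits + as.integer(any(fam$results$significant))
      n_flags <- n_flags + sum(fam$results$significant)
      n_results <- n_results + k
      expected_flags <- expected_flags + k * fam$threshold
      expected_any <- expected_any + min(1, k * fam$threshold)
    }
  }
  list(n_flags = n_flags, expected_flags = expected_flags,
       flag_rate = n_flags / n_results,
       expected_flag_rate = expected_flags / n_results,
       family_rate = fam_hits / n_pairs,
       expected_family_rate = expected_any / n_pairs,
       n_pairs = n_pairs, n_results = n_results)
}
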