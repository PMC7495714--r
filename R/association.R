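# -- Haplogroup association models ---------------------------------------
#
# Every haplogroup row is a one-vs-rest indicator over the analysed
# subjects (nested rows, e.g. "H" and "H1", are separate tests).  Risk is
# modelled by age- and sex-adjusted logistic regression (Wald OR, CI, p);
# tau burden, disease duration and age of onset by covariate-adjusted
# ordinary least squares.  Rows with fewer than `min_count` carriers in
# the analysed subjects are not tested.  Each family of similar tests gets
# its own Bonferroni threshold alpha / m, rounded to 4 decimals;
# secondary (super-haplogroup) families use alpha unadjusted.

#' Default one-vs-rest analysis rows
#'
#' The haplogroup rows entering an analysis: each assigned node on its
#' own plus the published combined rows (e.g. all H-lineage haplogroups
#' pooled).  A subject is a carrier of a row when its assigned haplogroup
#' is one of the row's members.
#'
#' @param flavor `"risk"` for the full risk-analysis layout, `"tau"` for
#'   the reduced layout used in case-only analyses.
#' @return Named list mapping row label to member haplogroup names.
#' @export
default_analysis_rows <- function(flavor = c("risk", "tau")) {
  flavor <- match.arg(flavor)
  singles <- function(x) stats::setNames(as.list(x), x)
  if (flavor == "risk") {
    c(singles(c("N", "N1", "I", "W", "X")),
      list("R and R0" = c("R", "R0"),
           "HV and HV0a" = c("HV", "HV0a"),
           "H, H1, H2, H3, and H4" = c("H", "H1", "H2", "H3", "H4")),
      singles(c("H", "H1", "H2", "H3", "H4", "V", "JT")),
      list("J1, J1d, J2a, and J2b" = c("J1", "J1d", "J2a", "J2b")),
      singles(c("J1", "J1d", "J2a", "J2b")),
      list("T, T1, and T2" = c("T", "T1", "T2")),
      singles(c("T", "T1", "T2")),
      list("U, U1, U3, U5, and U6" = c("U", "U1", "U3", "U5", "U6")),
      singles(c("U", "U1", "U3", "U5", "U6", "K")))
  } else {
    c(singles(c("I", "W", "X")),
      list("R and R0" = c("R", "R0"),
           "HV and HV0a" = c("HV", "HV0a"),
           "H, H1, H2, H3 and H4" = c("H", "H1", "H2", "H3", "H4")),
      singles(c("H", "H1", "H2", "H3", "H4", "V")),
      list("J1 and J2a" = c("J1", "J2a")),
      singles(c("J1", "J2a")),
      list("T, T1 and T2" = c("T", "T1", "T2")),
      singles(c("T", "T1", "T2")),
      list("U and U5" = c("U", "U5")),
      singles(c("U", "U5", "K")))
  }
}

#' Super-haplogroup analysis rows for the secondary analyses
#'
#' One row per distinct super-haplogroup label in the tree's map that
#' pools more than one haplogroup.
#'
#' @param tree A `haplo_tree`.
#' @return Named list mapping super-haplogroup label to member nodes.
#' @export
super_analysis_rows <- function(tree) {
  labs <- table(unlist(tree$super_map))
  pooled <- names(labs)[labs > 1L]
  stats::setNames(lapply(pooled, function(lab)
    names(tree$super_map)[tree$super_map == lab]), pooled)
}

#' Minimum-carrier rule for one analysis
#'
#' A haplogroup row is tested only when it has at least `min_count`
#' carriers among the subjects entering the analysis; rows on the
#' `force_test` override list are tested regardless.
#'
#' @param n_carriers Total carriers across the analysed groups.
#' @param min_count Minimum carriers (default 10).
#' @param label Row label (used for the override check).
#' @param force_test Character vector of row labels exempt from the rule.
#' @return Logical: tested or not.
#' @export
min_count_filter <- function(n_carriers, min_count = 10, label = NULL,
                             force_test = character(0)) {
  n_carriers >= min_count || (!is.null(label) && label %in% force_test)
}

untested_result <- function(label, comparison, counts, reason) {
  data.frame(haplogroup = label, comparison = comparison,
             n_exposed = sum(counts), estimate = NA_real_,
             ci_low = NA_real_, ci_high = NA_real_, p_value = NA_real_,
             tested = FALSE, unstable = FALSE, exclusion_reason = reason,
             significant = FALSE, stringsAsFactors = FALSE)
}

drop_constant <- function(covars, data) {
  keep <- vapply(covars, function(v) {
    x <- data[[v]]
    length(unique(x[!is.na(x)])) > 1L
  }, logical(1))
  covars[keep]
}

#' Case-control logistic risk model for one haplogroup row
#'
#' Maximum-likelihood logistic regression of case status on a one-vs-rest
#' haplogroup indicator, adjusted for the given covariates (age and sex by
#' default).  The estimate is the exponentiated indicator coefficient
#' (odds ratio) with a Wald 95% CI and two-sided Wald p-value.  Constant
#' covariates are dropped with a message.  Apparent non-convergence or
#' separation flags the result `unstable` rather than dropping it.
#'
#' @param data Data frame of cases and controls with a logical/0-1 `case`
#'   column, an `exposed` indicator column and the covariate columns.
#' @param label Row label for reporting.
#' @param comparison Family label (e.g. `"PSP_risk"`).
#' @param covariates Covariate column names (default `c("age", "sex")`).
#' @return One-row data frame (`AssociationResult` layout): `haplogroup`,
#'   `comparison`, `n_exposed`, `estimate` (OR), `ci_low`, `ci_high`,
#'   `p_value`, `tested`, `unstable`, `exclusion_reason`, `significant`
#'   (filled later by [bonferroni_family()]).
#' @export
fit_risk_model <- function(data, label = "haplogroup",
                           comparison = "risk",
                           covariates = c("age", "sex")) {
  covariates <- drop_constant(covariates, data)
  fml <- stats::reformulate(c("exposed", covariates), response = "case")
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = data, family = stats::binomial()),
    warning = function(w) { warned <<- TRUE; invokeRestart("muffleWarning") })
  sm <- summary(fit)$coefficients
  row <- sm[grep("^exposed", rownames(sm))[1L], ]
  beta <- row[["Estimate"]]; se <- row[["Std. Error"]]
  z <- stats::qnorm(0.975)
  unstable <- warned || !fit$converged || abs(beta) > 10 || se > 10
  data.frame(haplogroup = label, comparison = comparison,
             n_exposed = sum(data$exposed),
             estimate = exp(beta), ci_low = exp(beta - z * se),
             ci_high = exp(beta + z * se),
             p_value = 2 * stats::pnorm(-abs(beta / se)),
             tested = TRUE, unstable = unstable,
             exclusion_reason = NA_character_, significant = FALSE,
             stringsAsFactors = FALSE)
}

#' Linear model of tau burden (or another continuous outcome)
#'
#' Ordinary least squares of a continuous outcome on the one-vs-rest
#' haplogroup indicator plus covariates (age at death, sex, Braak stage
#' and Thal phase for tau outcomes).  The estimate is the indicator
#' coefficient in outcome units with a Wald 95% CI and two-sided p.  A
#' constant covariate makes the design rank deficient and raises an error
#' naming the covariate.
#'
#' @param data Data frame with `outcome` and `exposed` columns and the
#'   covariates.
#' @inheritParams fit_risk_model
#' @param covariates Covariate column names (default
#'   `c("age", "sex", "braak", "thal")`).
#' @return One-row data frame in the `AssociationResult` layout; the
#'   estimate is a regression coefficient, not an OR.
#' @export
fit_tau_model <- function(data, label = "haplogroup", comparison = "tau",
                          covariates = c("age", "sex", "braak", "thal")) {
  constant <- setdiff(covariates, drop_constant(covariates, data))
  if (length(constant))
    stop("constant covariate(s) make the design rank deficient: ",
         paste(constant, collapse = ", "), call. = FALSE)
  fml <- stats::reformulate(c("exposed", covariates), response = "outcome")
  fit <- stats::lm(fml, data = data)
  sm <- summary(fit)$coefficients
  row <- sm[grep("^exposed", rownames(sm))[1L], ]
  beta <- row[["Estimate"]]; se <- row[["Std. Error"]]
  tq <- stats::qt(0.975, df = fit$df.residual)
  data.frame(haplogroup = label, comparison = comparison,
             n_exposed = sum(data$exposed), estimate = beta,
             ci_low = beta - tq * se, ci_high = beta + tq * se,
             p_value = row[["Pr(>|t|)"]], tested = TRUE, unstable = FALSE,
             exclusion_reason = NA_character_, significant = FALSE,
             stringsAsFactors = FALSE)
}

#' Bonferroni correction for a family of similar tests
#'
#' Counts the distinct tested haplogroup rows in the family, sets the
#' family threshold to `alpha / m` rounded to 4 decimal places (primary
#' families) or to `alpha` unrounded (secondary, super-haplogroup
#' families), and flags results with p-value less than or equal to the
#' threshold as significant.
#'
#' @param results Data frame of `AssociationResult` rows from one family.
#' @param alpha Family-wise error target (default 0.05).
#' @param secondary When `TRUE`, no multiplicity adjustment is applied.
#' @return List with `results` (significance flags filled), `label`,
#'   `m_tests` and `threshold`.
#' @export
bonferroni_family <- function(results, alpha = 0.05, secondary = FALSE) {
  m <- length(unique(results$haplogroup[results$tested]))
  if (m == 0L)
    stop("empty family: no tested haplogroups", call. = FALSE)
  threshold <- if (secondary) alpha else round(alpha / m, 4)
  results$significant <- results$tested & !is.na(results$p_value) &
    results$p_value <= threshold
  list(results = results,
       label = unique(results$comparison)[1L],
       m_tests = m, threshold = threshold)
}

#' Run a full case-control risk family
#'
#' One logistic fit per analysis row over the cases of one disease plus
#' the controls, with the minimum-carrier rule and the family Bonferroni
#' threshold applied.
#'
#' @param subjects Subject table with columns `group`, `age`, `sex` and
#'   `haplogroup` (assigned node; `NA` rows are dropped from the
#'   analysis).
#' @param disease `"PSP"` or `"CBD"`.
#' @param rows Analysis rows (default [default_analysis_rows]`("risk")`);
#'   for secondary super-haplogroup analyses pass [super_analysis_rows()]
#'   and `secondary = TRUE`.
#' @param min_count Minimum carriers per row (default 10).
#' @param alpha Family alpha (default 0.05).
#' @param secondary Passed to [bonferroni_family()].
#' @param force_test Row labels exempt from the minimum-carrier rule.
#' @return A family list as from [bonferroni_family()].
#' @export
run_risk_family <- function(subjects, disease = c("PSP", "CBD"),
                            rows = default_analysis_rows("risk"),
                            min_count = 10, alpha = 0.05,
                            secondary = FALSE,
                            force_test = character(0)) {
  disease <- match.arg(disease)
  dat <- subjects[subjects$group %in% c(disease, "control") &
                    !is.na(subjects$haplogroup), , drop = FALSE]
  dat$case <- as.integer(dat$group == disease)
  comparison <- paste0(disease, "_risk", if (secondary) "_super" else "")
  res <- lapply(names(rows), function(label) {
    dat$exposed <- as.integer(dat$haplogroup %in% rows[[label]])
    counts <- c(cases = sum(dat$exposed[dat$case == 1L]),
                controls = sum(dat$exposed[dat$case == 0L]))
    if (!min_count_filter(sum(counts), min_count, label, force_test))
      return(untested_result(label, comparison, counts,
                             sprintf("< %d carriers", min_count)))
    fit_risk_model(dat, label, comparison)
  })
  finish_family(do.call(rbind, res), comparison, alpha, secondary)
}

# families where nothing reached the carrier minimum are reported as
# empty (m = 0) rather than raising bonferroni_family's error
finish_family <- function(results, label, alpha, secondary) {
  if (!any(results$tested))
    return(list(results = results, label = label, m_tests = 0L,
                threshold = NA_real_))
  bonferroni_family(results, alpha, secondary)
}

#' Run a tau-burden family for one disease
#'
#' One OLS fit per (analysis row, tau measure) over the cases of one
#' disease that have an included tau summary for the measure, adjusted
#' for age at death, sex, Braak stage and Thal phase.  The family
#' Bonferroni threshold counts distinct haplogroup rows, not
#' (row x measure) pairs.
#'
#' @param subjects Subject table (cases and controls; only the disease's
#'   cases are used) with `haplogroup`, `age`, `sex`, `braak`, `thal`.
#' @param tau_summary Output of [summarize_tau()].
#' @param disease `"PSP"` or `"CBD"`.
#' @param measures Tau measures to analyse (default: CB, NFT, AP and NT
#'   for PSP; CB, NFT, TA and NT for CBD).
#' @inheritParams run_risk_family
#' @return A family list as from [bonferroni_family()].
#' @export
run_tau_family <- function(subjects, tau_summary,
                           disease = c("PSP", "CBD"),
                           measures = NULL,
                           rows = default_analysis_rows("tau"),
                           min_count = 10, alpha = 0.05,
                           secondary = FALSE,
                           force_test = character(0)) {
  disease <- match.arg(disease)
  if (is.null(measures))
    measures <- if (disease == "PSP") c("CB", "NFT", "AP", "NT")
                else c("CB", "NFT", "TA", "NT")
  comparison <- paste0(disease, "_tau", if (secondary) "_super" else "")
  cases <- subjects[subjects$group == disease &
                      !is.na(subjects$haplogroup), , drop = FALSE]
  res <- lapply(measures, function(msr) {
    ts <- tau_summary[tau_summary$measure == msr & tau_summary$included &
                        tau_summary$group == disease, , drop = FALSE]
    dat <- merge(cases, ts[, c("subject_id", "mean_score")],
                 by = "subject_id")
    dat <- dat[stats::complete.cases(dat[, c("age", "sex", "braak",
                                             "thal")]), , drop = FALSE]
    dat$outcome <- dat$mean_score
    do.call(rbind, lapply(names(rows), function(label) {
      dat$exposed <- as.integer(dat$haplogroup %in% rows[[label]])
      n_exp <- sum(dat$exposed)
      out <- if (!min_count_filter(n_exp, min_count, label, force_test))
        untested_result(label, comparison, n_exp,
                        sprintf("< %d carriers", min_count))
      else fit_tau_model(dat, label, comparison)
      out$measure <- msr
      out
    }))
  })
  finish_family(do.call(rbind, res), comparison, alpha, secondary)
}

#' Run the PSP onset and duration family
#'
#' OLS models over PSP cases with a non-missing outcome: disease duration
#' adjusted for age of onset and sex; age of onset adjusted for sex.
#' Both outcomes form a single test family.
#'
#' @param subjects Subject table with `age_of_onset`, `disease_duration`,
#'   `sex`, `haplogroup`.
#' @inheritParams run_risk_family
#' @return A family list as from [bonferroni_family()].
#' @export
run_onset_duration_family <- function(subjects,
                                      rows = default_analysis_rows("tau"),
                                      min_count = 10, alpha = 0.05) {
  cases <- subjects[subjects$group == "PSP" &
                      !is.na(subjects$haplogroup), , drop = FALSE]
  specs <- list(
    duration = list(outcome = "disease_duration",
                    covariates = c("age_of_onset", "sex")),
    onset = list(outcome = "age_of_onset", covariates = "sex"))
  res <- lapply(names(specs), function(what) {
    spec <- specs[[what]]
    dat <- cases[!is.na(cases[[spec$outcome]]), , drop = FALSE]
    dat <- dat[stats::complete.cases(dat[, spec$covariates, drop = FALSE]), ,
               drop = FALSE]
    dat$outcome <- dat[[spec$outcome]]
    do.call(rbind, lapply(names(rows), function(label) {
      dat$exposed <- as.integer(dat$haplogroup %in% rows[[label]])
      n_exp <- sum(dat$exposed)
      out <- if (!min_count_filter(n_exp, min_count))
        untested_result(label, "PSP_duration_onset", n_exp,
                        sprintf("< %d carriers", min_count))
      else fit_tau_model(dat, label, "PSP_duration_onset",
                         covariates = spec$covariates)
      out$outcome_name <- what
      out
    }))
  })
  finish_family(do.call(rbind, res), "PSP_duration_onset", alpha, FALSE)
}
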