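# -- Tau lesion score aggregation ----------------------------------------
#
# Each subject is scored 0-3 (none/mild/moderate/severe) per brain region
# for each lesion measure (CB, NFT, TA, AP, NT).  A subject's burden for a
# measure is the mean score over all regions, after imputing any missing
# region with the mean of the observed scores for that (disease group,
# measure, region) cell.  Subjects missing more than half of the regions
# for a measure are excluded from analyses of that measure.

TAU_MEASURES <- c("CB", "NFT", "TA", "AP", "NT")

#' Default neuroanatomical region lists
#'
#' Region panels for the two diseases: 20 regions scored in PSP and 17 in
#' CBD.  The published region names are supplementary material that is not
#' reproduced here, so these lists are documented placeholders matching
#' the published counts; they are configuration, not biology, and can be
#' replaced by the user.
#'
#' @param group `"PSP"` or `"CBD"`.
#' @return Character vector of region names.
#' @export
default_region_list <- function(group = c("PSP", "CBD")) {
  group <- match.arg(group)
  base <- c("globus pallidus", "subthalamic nucleus", "substantia nigra",
            "red nucleus", "locus coeruleus", "pontine base",
            "pontine tegmentum", "medulla", "dentate nucleus",
            "cerebellar white matter", "caudate nucleus", "putamen",
            "thalamus", "motor cortex", "premotor cortex",
            "superior frontal cortex", "inferior parietal cortex")
  if (group == "PSP")
    c(base, "oculomotor nucleus", "inferior olive", "midbrain tectum")
  else base
}

validate_scores <- function(scores) {
  need <- c("subject_id", "group", "measure", "region", "score")
  missing <- setdiff(need, names(scores))
  if (length(missing))
    stop("score table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  s <- scores$score
  bad <- !is.na(s) & !(s %in% 0:3)
  if (any(bad))
    stop("scores outside the 0-3 ordinal scale: ",
         paste(unique(s[bad]), collapse = ", "), call. = FALSE)
  invisible(scores)
}

#' Per-cell mean observed scores for imputation
#'
#' Means of the observed (non-missing) scores per (disease group, measure,
#' region) cell, computed from all subjects of the group with an observed
#' value regardless of their own inclusion status.  Cells with no observed
#' scores have no entry.
#'
#' @param scores Long-format data frame with columns `subject_id`,
#'   `group`, `measure`, `region`, `score` (`NA` = missing).
#' @return Data frame `group`, `measure`, `region`, `mean_score`,
#'   `n_observed`.
#' @export
region_group_means <- function(scores) {
  validate_scores(scores)
  obs <- scores[!is.na(scores$score), , drop = FALSE]
  if (!nrow(obs))
    return(data.frame(group = character(0), measure = character(0),
                      region = character(0), mean_score = numeric(0),
                      n_observed = integer(0), stringsAsFactors = FALSE))
  agg <- stats::aggregate(score ~ group + measure + region, data = obs,
                          FUN = mean)
  cnt <- stats::aggregate(score ~ group + measure + region, data = obs,
                          FUN = length)
  out <- data.frame(group = agg$group, measure = agg$measure,
                    region = agg$region, mean_score = agg$score,
                    n_observed = cnt$score, stringsAsFactors = FALSE)
  out[order(out$group, out$measure, out$region), , drop = FALSE]
}

#' Summarise one subject's burden for one measure
#'
#' Applies the exclusion and imputation rules: if the subject is missing
#' strictly more than 50% of the regions, the subject is excluded for this
#' measure (no mean is computed); otherwise each missing region is imputed
#' with its group mean and the mean over the full region list is returned.
#'
#' @param scores Data frame of this subject's rows for one measure
#'   (columns `region`, `score`; regions absent from the table count as
#'   missing).
#' @param region_list Full region panel for the disease group.
#' @param group_means Data frame from [region_group_means()], already
#'   restricted (or restrictable) to the subject's group and measure.
#' @return One-row data frame: `mean_score`, `n_observed`, `n_imputed`,
#'   `included`, `exclusion_reason`.
#' @export
summarize_subject <- function(scores, region_list, group_means) {
  if (!length(region_list)) stop("empty region list", call. = FALSE)
  unknown <- setdiff(scores$region, region_list)
  if (length(unknown))
    stop("region not in region list: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  obs <- scores$score[match(region_list, scores$region)]
  n_missing <- sum(is.na(obs))
  n_regions <- length(region_list)
  if (n_missing / n_regions > 0.5)
    return(data.frame(mean_score = NA_real_,
                      n_observed = n_regions - n_missing, n_imputed = 0L,
                      included = FALSE,
                      exclusion_reason = sprintf(
                        "missing %d of %d regions (> 50%%)", n_missing,
                        n_regions),
                      stringsAsFactors = FALSE))
  filled <- obs
  if (n_missing) {
    imput <- group_means$mean_score[match(region_list[is.na(obs)],
                                          group_means$region)]
    if (anyNA(imput))
      stop("no group mean available for region(s): ",
           paste(region_list[is.na(obs)][is.na(imput)], collapse = ", "),
           call. = FALSE)
    filled[is.na(obs)] <- imput
  }
  data.frame(mean_score = mean(filled),
             n_observed = n_regions - n_missing,
             n_imputed = n_missing, included = TRUE,
             exclusion_reason = NA_character_, stringsAsFactors = FALSE)
}

#' Summarise tau burden for a whole cohort
#'
#' Runs [region_group_means()] once (single pass: means are not
#' recomputed after exclusions) and then [summarize_subject()] for every
#' (subject, measure) pair present in the table.
#'
#' @param scores Long-format score table (see [region_group_means()]).
#' @param region_lists Named list of region panels per group; defaults to
#'   [default_region_list()] for PSP and CBD.
#' @return Data frame with one row per (subject, measure): `subject_id`,
#'   `group`, `measure`, `mean_score`, `n_observed`, `n_imputed`,
#'   `included`, `exclusion_reason`.
#' @export
summarize_tau <- function(scores,
                          region_lists = list(PSP = default_region_list("PSP"),
                                              CBD = default_region_list("CBD"))) {
  validate_scores(scores)
  pieces <- list()
  for (grp in unique(scores$group)) {
    regions <- region_lists[[grp]]
    if (is.null(regions))
      stop("no region list for group '", grp, "'", call. = FALSE)
    gsc <- scores[scores$group == grp, , drop = FALSE]
    unknown <- setdiff(gsc$region, regions)
    if (length(unknown))
      stop("region not in region list: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    for (msr in unique(gsc$measure)) {
      m <- gsc[gsc$measure == msr, , drop = FALSE]
      subjects <- unique(m$subject_id)
      # subjects x full-region-panel score matrix; absent rows = missing
      mat <- matrix(NA_real_, nrow = length(subjects), ncol = length(regions),
                    dimnames = list(subjects, regions))
      mat[cbind(m$subject_id, m$region)] <- m$score
      cell_means <- colMeans(mat, na.rm = TRUE)   # per-region group means
      n_missing <- rowSums(is.na(mat))
      included <- n_missing / length(regions) <= 0.5
      filled <- mat
      idx <- which(is.na(mat), arr.ind = TRUE)
      if (nrow(idx)) {
        bad <- is.nan(cell_means[idx[, 2L]]) & included[idx[, 1L]]
        if (any(bad))
          stop("no group mean available for region(s): ",
               paste(unique(colnames(mat)[idx[bad, 2L]]), collapse = ", "),
               call. = FALSE)
        filled[idx] <- cell_means[idx[, 2L]]
      }
      mean_score <- rowMeans(filled)
      mean_score[!included] <- NA_real_
      pieces[[length(pieces) + 1L]] <- data.frame(
        subject_id = subjects, group = grp, measure = msr,
        mean_score = unname(mean_score),
        n_observed = length(regions) - unname(n_missing),
        n_imputed = ifelse(included, unname(n_missing), 0L),
        included = unname(included),
        exclusion_reason = ifelse(included, NA_character_, sprintf(
          "missing %d of %d regions (> 50%%)", n_missing, length(regions))),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
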