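mk_scores <- function(subject_id, group, measure, region, score)
  data.frame(subject_id = subject_id, group = group, measure = measure,
             region = region, score = score, stringsAsFactors = FALSE)

test_that("group means average only observed scores per cell", {
  sc <- mk_scores(paste0("p", 1:5), "PSP", "NFT", "substantia nigra",
                  c(2, 3, 3, 2, NA))
  gm <- region_group_means(sc)
  expect_equal(gm$mean_score, 2.5)
  expect_equal(gm$n_observed, 4L)

  single <- region_group_means(mk_scores("p1", "CBD", "CB", "putamen", 1))
  expect_equal(single$mean_score, 1.0)

  empty_cell <- region_group_means(
    mk_scores("p1", "PSP", "TA", "putamen", NA))
  expect_equal(nrow(empty_cell), 0L)

  expect_error(region_group_means(
    mk_scores("p1", "PSP", "TA", "putamen", 5)), "0-3 ordinal")
})

test_that("the >50% missing exclusion is strict and per measure", {
  regions <- sprintf("r%02d", 1:20)
  gm <- data.frame(group = "PSP", measure = "NFT", region = regions,
                   mean_score = 1.0, n_observed = 5L,
                   stringsAsFactors = FALSE)
  mk <- function(n_missing) {
    sc <- data.frame(region = regions,
                     score = c(rep(2, 20 - n_missing), rep(NA, n_missing)))
    summarize_subject(sc, regions, gm)
  }
  expect_false(mk(11)$included)                 # 55% missing: out
  expect_match(mk(11)$exclusion_reason, "> 50%")
  expect_true(mk(10)$included)                  # exactly 50%: in
  expect_equal(mk(10)$n_imputed, 10L)
})

test_that("imputation fills missing regions with the group mean", {
  regions <- c("a", "b", "c", "d")
  gm <- data.frame(group = "PSP", measure = "CB", region = regions,
                   mean_score = c(9, 9, 9, 1.0), n_observed = 3L,
                   stringsAsFactors = FALSE)
  sc <- data.frame(region = c("a", "b", "c", "d"), score = c(3, 3, 1, NA))
  res <- summarize_subject(sc, regions, gm)
  expect_equal(res$mean_score, 2.0)             # (3+3+1+1)/4
  expect_equal(res$n_observed, 3L)
  expect_equal(res$n_imputed, 1L)

  # complete data: plain arithmetic mean, no imputation
  full <- summarize_subject(
    data.frame(region = regions, score = c(0, 1, 2, 3)), regions, gm)
  expect_equal(full$mean_score, 1.5)
  expect_equal(full$n_imputed, 0L)

  expect_error(summarize_subject(
    data.frame(region = "z", score = 1), regions, gm), "not in region list")
  expect_error(summarize_subject(sc, character(0), gm), "empty region list")
})

test_that("cohort summaries agree with the per-subject contract", {
  set.seed(71)
  regions <- default_region_list("CBD")
  n <- 25
  sc <- expand.grid(subject_id = sprintf("c%02d", 1:n), region = regions,
                    stringsAsFactors = FALSE)
  sc$group <- "CBD"; sc$measure <- "NT"
  sc$score <- sample(0:3, nrow(sc), replace = TRUE)
  sc$score[sample(nrow(sc), 60)] <- NA
  summ <- summarize_tau(sc, list(CBD = regions))
  gm <- region_group_means(sc)
  for (sid in sample(unique(sc$subject_id), 8)) {
    ref <- summarize_subject(sc[sc$subject_id == sid, c("region", "score")],
                             regions, gm[gm$measure == "NT", ])
    row <- summ[summ$subject_id == sid, ]
    expect_equal(row$mean_score, ref$mean_score)
    expect_identical(row$included, ref$included)
    expect_equal(row$n_imputed, ref$n_imputed)
  }
  # bounds hold for every included subject
  expect_true(all(summ$mean_score[summ$included] >= 0 &
                    summ$mean_score[summ$included] <= 3))
})

test_that("group-mean imputation is a fixed point of the cell means", {
  sim <- simulate_cohort(sim_config(n_psp = 60, n_cbd = 0, n_control = 0,
                                    missing_region_rate = 0.15, seed = 3))
  sc <- sim$tau_scores
  gm <- region_group_means(sc)
  # impute every missing score with its cell mean, recompute cell means
  key <- paste(sc$group, sc$measure, sc$region)
  gkey <- paste(gm$group, gm$measure, gm$region)
  filled <- sc
  miss <- is.na(filled$score)
  filled$score[miss] <- gm$mean_score[match(key[miss], gkey)]
  gm2 <- stats::aggregate(score ~ group + measure + region, data = filled,
                          FUN = mean)
  m <- match(paste(gm2$group, gm2$measure, gm2$region), gkey)
  expect_equal(gm2$score, gm$mean_score[m], tolerance = 1e-12)
})

test_that("cohort medians on a calibrated synthetic cohort stay inside the published envelopes", {
  sim <- simulate_cohort(sim_config(n_psp = 400, n_cbd = 80, n_control = 0,
                                    seed = 12))
  summ <- summarize_tau(sim$tau_scores)
  env <- list(  # published (min, max) envelopes per group and measure
    PSP = list(CB = c(0.25, 2.36), NFT = c(0.83, 2.89), NT = c(0.35, 2.90)),
    CBD = list(CB = c(0.23, 1.75), NFT = c(0.99, 2.67), NT = c(1.23, 2.95)))
  for (grp in names(env)) for (msr in names(env[[grp]])) {
    x <- summ$mean_score[summ$group == grp & summ$measure == msr &
                           summ$included]
    med <- median(x)
    expect_gt(med, env[[grp]][[msr]][1])
    expect_lt(med, env[[grp]][[msr]][2])
  }
})
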