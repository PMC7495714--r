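# builds a bare-bones subject table for model fitting
mk_subjects <- function(n, p_exposed = 0.2, seed = 1) {
  set.seed(seed)
  data.frame(subject_id = sprintf("m%04d", 1:n),
             exposed = as.integer(runif(n) < p_exposed),
             age = round(rnorm(n, 75, 8)),
             sex = sample(c("male", "female"), n, replace = TRUE),
             braak = sample(0:6, n, replace = TRUE),
             thal = sample(0:5, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

test_that("the minimum-carrier rule follows the published examples", {
  # "R and R0": 6 controls + 10 PSP cases = 16 carriers -> tested
  expect_true(min_count_filter(6 + 10))
  # CBD comparison: 6 + 2 = 8 -> not tested
  expect_false(min_count_filter(6 + 2))
  # H4 in the CBD tau analysis: 8 carriers but explicitly force-tested
  expect_false(min_count_filter(8))
  expect_true(min_count_filter(8, label = "H4", force_test = "H4"))
  expect_true(min_count_filter(10))  # boundary: exactly 10 is tested
})

test_that("a null logistic model estimates OR near 1", {
  d <- mk_subjects(4000, seed = 2)
  d$case <- as.integer(runif(4000) < 0.5)
  res <- fit_risk_model(d, "null")
  expect_true(res$tested)
  expect_gt(res$p_value, 0.01)
  expect_lt(abs(log(res$estimate)), 0.3)
  expect_true(res$ci_low <= res$estimate && res$estimate <= res$ci_high)
})

test_that("with constant covariates the logistic OR equals the crude cross-product", {
  set.seed(9)
  n <- 800
  d <- data.frame(case = rep(c(1, 0), c(300, 500)),
                  exposed = c(rbinom(300, 1, 0.3), rbinom(500, 1, 0.15)),
                  age = 70, sex = "male", stringsAsFactors = FALSE)
  res <- suppressMessages(fit_risk_model(d, "crude"))
  tab <- table(d$case, d$exposed)
  crude <- (tab["1", "1"] / tab["1", "0"]) / (tab["0", "1"] / tab["0", "0"])
  expect_equal(res$estimate, unname(crude), tolerance = 1e-6)
})

test_that("an injected log-OR is recovered inside the Wald CI in most replicates", {
  hits <- 0; reps <- 60
  for (r in seq_len(reps)) {
    set.seed(1000 + r)
    n <- 2000
    expo <- rbinom(n, 1, 0.15)
    age <- rnorm(n, 70, 8)
    lp <- -0.5 + log(2) * expo + 0.01 * (age - 70)
    d <- data.frame(case = rbinom(n, 1, plogis(lp)), exposed = expo,
                    age = age,
                    sex = sample(c("male", "female"), n, replace = TRUE),
                    stringsAsFactors = FALSE)
    res <- fit_risk_model(d, "inj")
    hits <- hits + (res$ci_low <= 2 && 2 <= res$ci_high)
  }
  expect_gte(hits / reps, 0.9)
})

test_that("tau models recover null and injected shifts and reject bad designs", {
  d <- mk_subjects(600, seed = 3)
  d$outcome <- rnorm(600, 2, 0.3)                    # orthogonal noise
  res <- fit_tau_model(d, "null")
  expect_lt(abs(res$estimate), 0.1)
  expect_gt(res$p_value, 0.001)

  d2 <- d
  d2$outcome <- d2$outcome - 0.35 * d2$exposed       # injected shift
  res2 <- fit_tau_model(d2, "shift")
  expect_true(res2$ci_low <= -0.35 && -0.35 <= res2$ci_high)
  expect_lt(res2$estimate, 0)

  # duplicating every row keeps the estimate, narrows the CI
  res_dup <- fit_tau_model(rbind(d2, d2), "dup")
  expect_equal(res_dup$estimate, res2$estimate, tolerance = 1e-10)
  expect_lt(res_dup$ci_high - res_dup$ci_low,
            res2$ci_high - res2$ci_low)

  d3 <- d; d3$braak <- 2
  expect_error(fit_tau_model(d3, "bad"), "braak")
})

test_that("family thresholds are alpha over the tested-haplogroup count, 4 dp", {
  mk_res <- function(m_tested, m_untested = 0) {
    data.frame(haplogroup = paste0("h", seq_len(m_tested + m_untested)),
               comparison = "fam", n_exposed = 20, estimate = 1,
               ci_low = 0.5, ci_high = 2, p_value = 0.5,
               tested = rep(c(TRUE, FALSE), c(m_tested, m_untested)),
               unstable = FALSE, exclusion_reason = NA_character_,
               significant = FALSE, stringsAsFactors = FALSE)
  }
  expect_equal(bonferroni_family(mk_res(24))$threshold, 0.0021)
  expect_equal(bonferroni_family(mk_res(21))$threshold, 0.0024)
  expect_equal(bonferroni_family(mk_res(11))$threshold, 0.0045)
  expect_equal(bonferroni_family(mk_res(19))$threshold, 0.0026)
  expect_equal(bonferroni_family(mk_res(1))$threshold, 0.05)
  # untested rows do not count toward m
  expect_equal(bonferroni_family(mk_res(24, 7))$m_tests, 24L)
  # secondary families skip the correction
  expect_equal(bonferroni_family(mk_res(5), secondary = TRUE)$threshold, 0.05)
  expect_error(bonferroni_family(mk_res(0, 3)), "empty family")

  # significance uses <= against the rounded threshold
  res <- mk_res(24); res$p_value[1] <- 0.0021
  expect_true(bonferroni_family(res)$results$significant[1])
  res$p_value[1] <- 0.00215
  expect_false(bonferroni_family(res)$results$significant[1])
})

test_that("tau families count haplogroups once across measures", {
  sim <- simulate_cohort(sim_config(n_psp = 400, n_cbd = 0, n_control = 0,
                                    seed = 8))
  subj <- sim$subjects
  subj$haplogroup <- sim$truth$haplogroup[subj$subject_id]
  ts <- summarize_tau(sim$tau_scores)
  fam <- run_tau_family(subj, ts, "PSP")
  per_row <- table(fam$results$haplogroup[fam$results$tested])
  expect_true(all(per_row == 4))     # each tested row fitted for 4 measures
  expect_equal(fam$m_tests, length(per_row))
  expect_equal(fam$threshold, round(0.05 / fam$m_tests, 4))
})

test_that("onset and duration models handle missing outcomes", {
  sim <- simulate_cohort(sim_config(n_psp = 500, n_cbd = 0, n_control = 0,
                                    seed = 13))
  subj <- sim$subjects
  subj$haplogroup <- sim$truth$haplogroup[subj$subject_id]
  fam <- run_onset_duration_family(subj)
  expect_true(any(fam$results$tested))
  expect_true(all(c("duration", "onset") %in% fam$results$outcome_name))
  # null simulation: coefficients hover near zero for the common rows
  big <- fam$results[fam$results$tested & fam$results$n_exposed > 50, ]
  expect_true(all(abs(big$estimate[big$outcome_name == "onset"]) < 5))

  subj$age_of_onset <- NA_real_
  subj$disease_duration <- NA_real_
  empty <- run_onset_duration_family(subj)
  expect_false(any(empty$results$tested))
  expect_equal(empty$m_tests, 0L)
})
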