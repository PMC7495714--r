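# -- Synthetic cohort generator ------------------------------------------
#
# Generates complete synthetic studies -- panel genotype calls, subject
# tables and regional tau lesion scores -- with known ground truth, so
# the whole chain from raw calls to association families can be exercised
# and its parameter recovery measured without any external data.
#
# Cases and controls are drawn with fixed group sizes; injected disease
# odds ratios are realised through the case-control sampling identity:
# controls draw haplogroups from the base frequencies f, cases of a
# disease from f * exp(log OR) renormalised, which is exactly the
# distribution induced by a prospective logistic model with those log
# odds once sampling is conditioned on case status (covariates being
# independent of haplogroup).  Tau scores are generated on a latent
# continuous scale and rounded/clamped to the 0-3 ordinal grid.
#
# Randomness uses one seeded stream split per subject by counter, so
# changing the cohort size never reshuffles earlier subjects.

#' Simulation configuration
#'
#' Builds and validates the configuration of a synthetic study.  The
#' defaults are the study conditions: group sizes of the published
#' cohort, haplogroup frequencies of its control column, covariate
#' distributions calibrated to its characteristics table, two-assay-style
#' intensity noise and small no-call and missing-region rates.
#'
#' @param n_psp,n_cbd,n_control Group sizes (defaults 1042 / 171 / 910).
#' @param haplogroup_freqs Named per-node sampling frequencies (default
#'   [control_haplogroup_freqs()]).
#' @param risk_log_odds Named list per disease (`PSP`, `CBD`) of named
#'   log-OR vectors over haplogroups (default: all zero).
#' @param tau_shifts Data frame with columns `haplogroup`, `measure`,
#'   `shift` giving latent-scale tau score shifts for carriers (default:
#'   none).
#' @param nocall_rate Per-locus probability of a no-call (default 0.005).
#' @param intensity_mean,baseline_mean,intensity_sd Signal model for raw
#'   calls (arbitrary units; defaults 12, 3, 1): accepted calls exceed
#'   baseline by > 5 in expectation.
#' @param missing_region_rate Probability a regional tau score is missing
#'   (default 0.03).
#' @param tau_scored_fraction Named fractions of cases with tau scoring
#'   (defaults 764/1042 for PSP, 150/171 for CBD, as published).
#' @param onset_missing_rate Fraction of PSP cases lacking onset/duration
#'   (default 606/1042, as published).
#' @param tau_measure_means Named list per group of latent means per
#'   measure (defaults calibrated to the published medians).
#' @param tau_noise_sd Latent-scale residual SD (default 0.8).
#' @param seed Integer seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_psp = 1042, n_cbd = 171, n_control = 910,
                       haplogroup_freqs = NULL,
                       risk_log_odds = list(),
                       tau_shifts = NULL,
                       nocall_rate = 0.005,
                       intensity_mean = 12, baseline_mean = 3,
                       intensity_sd = 1,
                       missing_region_rate = 0.03,
                       tau_scored_fraction = c(PSP = 764 / 1042,
                                               CBD = 150 / 171),
                       onset_missing_rate = 606 / 1042,
                       tau_measure_means = NULL,
                       tau_noise_sd = 0.8,
                       seed = 1L) {
  if (is.null(haplogroup_freqs))
    haplogroup_freqs <- control_haplogroup_freqs()
  if (is.null(tau_measure_means))
    tau_measure_means <- list(
      PSP = c(CB = 1.50, NFT = 2.23, TA = 1.00, AP = 1.00, NT = 2.15),
      CBD = c(CB = 0.76, NFT = 2.19, TA = 0.52, AP = 0.52, NT = 2.52))
  if (is.null(tau_shifts))
    tau_shifts <- data.frame(haplogroup = character(0),
                             measure = character(0), shift = numeric(0),
                             stringsAsFactors = FALSE)
  cfg <- list(n_psp = as.integer(n_psp), n_cbd = as.integer(n_cbd),
              n_control = as.integer(n_control),
              haplogroup_freqs = haplogroup_freqs,
              risk_log_odds = risk_log_odds, tau_shifts = tau_shifts,
              nocall_rate = nocall_rate,
              intensity_mean = intensity_mean,
              baseline_mean = baseline_mean, intensity_sd = intensity_sd,
              missing_region_rate = missing_region_rate,
              tau_scored_fraction = tau_scored_fraction,
              onset_missing_rate = onset_missing_rate,
              tau_measure_means = tau_measure_means,
              tau_noise_sd = tau_noise_sd, seed = as.integer(seed))
  problems <- character(0)
  probs <- c(nocall_rate, missing_region_rate, onset_missing_rate,
             tau_scored_fraction)
  if (any(probs < 0 | probs > 1))
    problems <- c(problems, "rates must lie in [0, 1]")
  if (any(haplogroup_freqs < 0))
    problems <- c(problems, "haplogroup_freqs must be non-negative")
  if (abs(sum(haplogroup_freqs) - 1) > 1e-8)
    problems <- c(problems, "haplogroup_freqs must sum to 1")
  if (any(c(cfg$n_psp, cfg$n_cbd, cfg$n_control) < 0))
    problems <- c(problems, "group sizes must be non-negative")
  if (length(problems))
    stop("invalid simulation config:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  structure(cfg, class = "sim_config")
}

# counter-split substreams: per-subject seeds must be decorrelated, not
# merely distinct -- affinely related seeds give correlated Mersenne
# Twister streams, which would leak spurious genotype-phenotype
# association into null simulations.  A splitmix-style 32-bit avalanche
# hash of (seed, counter) breaks that structure.  Arithmetic is done in
# doubles (exact below 2^53) with 16-bit split multiplies.
xor32 <- function(a, b)
  bitwXor(a %% 65536, b %% 65536) +
  65536 * bitwXor(a %/% 65536, b %/% 65536)

mul32 <- function(a, b)
  ((a %% 65536) * b + ((a %/% 65536) * b %% 65536) * 65536) %% 4294967296

mix32 <- function(x) {
  x <- x %% 4294967296
  x <- xor32(x, x %/% 65536)
  x <- mul32(x, 2246822507)        # 0x85ebca6b
  x <- xor32(x, x %/% 8192)
  x <- mul32(x, 3266489909)        # 0xc2b2ae35
  xor32(x, x %/% 65536)
}

subject_seed <- function(seed, counter) {
  h <- mix32((as.numeric(seed) * 65537 + 1) %% 4294967296)
  h <- mix32(xor32(h, mul32(counter, 2654435761)))
  as.integer(h %% 2147483647)
}

#' Simulate the raw panel calls of one sample
#'
#' The sample carries the derived allele at every locus on the defining
#' path of its haplogroup and the ancestral allele elsewhere.  Each call
#' is independently replaced by a no-call with probability `nocall_rate`;
#' intensities and baselines are drawn from the configured signal model,
#' so accepted calls exceed the baseline by more than the acceptance
#' delta in expectation but a small fraction fall below and are rejected
#' downstream.
#'
#' @param haplogroup True haplogroup of the sample.
#' @param tree A `haplo_tree`.
#' @param config A [sim_config()].
#' @param seed Integer seed for this sample's stream.
#' @param sample_id Identifier to attach.
#' @return Data frame of raw calls (one row per panel locus).
#' @export
simulate_genotypes <- function(haplogroup, tree, config,
                               seed = config$seed,
                               sample_id = "sim") {
  stop_unknown_node(tree, haplogroup)
  set.seed(seed)
  info <- panel_alleles(tree)
  path <- defining_path(tree, haplogroup)
  allele <- ifelse(info$position %in% path$position, info$derived,
                   info$ancestral)
  nocall <- stats::runif(nrow(info)) < config$nocall_rate
  allele[nocall] <- NO_CALL
  data.frame(sample_id = sample_id, position = info$position,
             allele = allele,
             intensity = stats::rnorm(nrow(info), config$intensity_mean,
                                      config$intensity_sd),
             baseline = stats::rnorm(nrow(info), config$baseline_mean,
                                     config$intensity_sd),
             stringsAsFactors = FALSE)
}

# case haplogroup distribution under injected log odds
tilted_freqs <- function(freqs, log_odds) {
  lo <- rep(0, length(freqs)); names(lo) <- names(freqs)
  if (length(log_odds)) lo[names(log_odds)] <- unlist(log_odds)
  w <- freqs * exp(lo)
  w / sum(w)
}

# per-group covariate models, calibrated to the published
# characteristics table (medians / ranges, category frequencies)
covariate_defaults <- list(
  PSP = list(age_mean = 75, age_sd = 8, age_range = c(45, 98),
             p_male = 0.541, onset_mean = 68, onset_sd = 8,
             onset_range = c(41, 90),
             braak_probs = c(113, 127, 223, 234, 50, 11, 6) / 764,
             thal_probs = c(336, 125, 52, 188, 43, 20) / 764),
  CBD = list(age_mean = 70, age_sd = 9, age_range = c(46, 96),
             p_male = 0.520, onset_mean = NA, onset_sd = NA,
             onset_range = c(NA, NA),
             braak_probs = c(20, 32, 50, 39, 7, 1, 1) / 150,
             thal_probs = c(82, 30, 14, 19, 3, 2) / 150),
  control = list(age_mean = 79, age_sd = 9, age_range = c(41, 102),
                 p_male = 0.426, onset_mean = NA, onset_sd = NA,
                 onset_range = c(NA, NA),
                 braak_probs = NULL, thal_probs = NULL))

rnorm_clamped <- function(n, mean, sd, range)
  pmin(pmax(stats::rnorm(n, mean, sd), range[1]), range[2])

#' Simulate a complete synthetic study
#'
#' Draws subjects with fixed group sizes, true haplogroups (controls from
#' the base frequencies, cases from frequencies tilted by the injected
#' log odds ratios), covariates from the calibrated per-group models, raw
#' panel calls per subject and regional tau lesion scores for the scored
#' case subsets, together with a ground-truth record of every injected
#' parameter.  Fully reproducible from the seed; each subject has its own
#' counter-derived substream.
#'
#' @param config A [sim_config()].
#' @param tree A `haplo_tree` (default [default_tree()]).
#' @return List with `subjects` (no haplogroup columns: those are for the
#'   caller to reconstruct), `raw_calls`, `tau_scores` (long format) and
#'   `truth` (true haplogroup per subject plus all injected parameters
#'   and the config).
#' @export
simulate_cohort <- function(config = sim_config(), tree = default_tree()) {
  stopifnot(inherits(config, "sim_config"))
  freqs <- config$haplogroup_freqs
  if (!all(names(freqs) %in% names(tree$nodes)))
    stop("haplogroup_freqs refers to nodes absent from the tree",
         call. = FALSE)
  groups <- rep(c("PSP", "CBD", "control"),
                c(config$n_psp, config$n_cbd, config$n_control))
  n <- length(groups)
  ids <- sprintf("S%05d", seq_len(n))

  group_freqs <- list(
    PSP = tilted_freqs(freqs, config$risk_log_odds$PSP),
    CBD = tilted_freqs(freqs, config$risk_log_odds$CBD),
    control = freqs)

  info <- panel_alleles(tree)
  path_pos <- lapply(names(tree$nodes), function(nm)
    defining_path(tree, nm)$position)
  names(path_pos) <- names(tree$nodes)

  hap <- character(n)
  age <- numeric(n); sex <- character(n)
  onset <- rep(NA_real_, n); duration <- rep(NA_real_, n)
  braak <- rep(NA_integer_, n); thal <- rep(NA_integer_, n)
  tau_scored <- rep(FALSE, n)
  allele_mat <- matrix(NA_character_, nrow = n, ncol = nrow(info))
  inten_mat <- matrix(NA_real_, nrow = n, ncol = nrow(info))
  base_mat <- matrix(NA_real_, nrow = n, ncol = nrow(info))

  for (i in seq_len(n)) {
    set.seed(subject_seed(config$seed, i))
    g <- groups[i]
    cov <- covariate_defaults[[g]]
    hap[i] <- sample(names(freqs), 1L, prob = group_freqs[[g]])
    age[i] <- round(rnorm_clamped(1L, cov$age_mean, cov$age_sd,
                                  cov$age_range))
    sex[i] <- if (stats::runif(1L) < cov$p_male) "male" else "female"
    if (g == "PSP" && stats::runif(1L) >= config$onset_missing_rate) {
      onset[i] <- round(rnorm_clamped(1L, cov$onset_mean, cov$onset_sd,
                                      cov$onset_range))
      duration[i] <- max(1, round(age[i] - onset[i] +
                                    stats::rnorm(1L, 0, 1)))
    }
    if (g != "control") {
      tau_scored[i] <- stats::runif(1L) < config$tau_scored_fraction[[g]]
      if (tau_scored[i]) {
        braak[i] <- sample(0:6, 1L, prob = cov$braak_probs)
        thal[i] <- sample(0:5, 1L, prob = cov$thal_probs)
      }
    }
    # genotypes: derived on the defining path, ancestral elsewhere
    on_path <- info$position %in% path_pos[[hap[i]]]
    a <- ifelse(on_path, info$derived, info$ancestral)
    a[stats::runif(nrow(info)) < config$nocall_rate] <- NO_CALL
    allele_mat[i, ] <- a
    inten_mat[i, ] <- stats::rnorm(nrow(info), config$intensity_mean,
                                   config$intensity_sd)
    base_mat[i, ] <- stats::rnorm(nrow(info), config$baseline_mean,
                                  config$intensity_sd)
  }

  subjects <- data.frame(
    subject_id = ids, group = groups, age = age, sex = sex,
    age_of_onset = onset, disease_duration = duration,
    braak = braak, thal = thal, stringsAsFactors = FALSE)

  raw_calls <- data.frame(
    sample_id = rep(ids, each = nrow(info)),
    position = rep(info$position, n),
    allele = as.vector(t(allele_mat)),
    intensity = as.vector(t(inten_mat)),
    baseline = as.vector(t(base_mat)), stringsAsFactors = FALSE)

  tau_scores <- simulate_tau_scores(subjects, hap, tau_scored, config)

  list(subjects = subjects, raw_calls = raw_calls, tau_scores = tau_scores,
       truth = list(haplogroup = stats::setNames(hap, ids),
                    tau_scored = stats::setNames(tau_scored, ids),
                    risk_log_odds = config$risk_log_odds,
                    tau_shifts = config$tau_shifts, config = config))
}

# latent-scale tau generation: per-region baseline around the measure
# mean, haplogroup shift for carriers, mild Braak/Thal/age covariate
# effects, Gaussian noise; rounded and clamped to the 0-3 grid.
simulate_tau_scores <- function(subjects, hap, tau_scored, config) {
  pieces <- list()
  for (grp in c("PSP", "CBD")) {
    idx <- which(subjects$group == grp & tau_scored)
    if (!length(idx)) next
    regions <- default_region_list(grp)
    nr <- length(regions)
    offsets <- seq(-0.5, 0.5, length.out = nr)   # fixed per-region spread
    mm <- config$tau_measure_means[[grp]]
    ncell <- length(TAU_MEASURES) * nr
    meas_vec <- rep(TAU_MEASURES, each = nr)
    base_vec <- rep(unlist(mm[TAU_MEASURES]), each = nr) + rep(offsets,
                                                              length(TAU_MEASURES))
    score_mat <- matrix(NA_integer_, nrow = length(idx), ncol = ncell)
    for (k in seq_along(idx)) {
      i <- idx[k]
      set.seed(subject_seed(config$seed, 1000000 + i))
      covar <- 0.05 * (subjects$braak[i] - 2) + 0.03 * (subjects$thal[i] - 1) +
        0.005 * (subjects$age[i] - covariate_defaults[[grp]]$age_mean)
      shift_vec <- numeric(length(TAU_MEASURES))
      names(shift_vec) <- TAU_MEASURES
      sel <- config$tau_shifts$haplogroup == hap[i]
      if (any(sel))
        for (msr in config$tau_shifts$measure[sel])
          shift_vec[msr] <- shift_vec[msr] +
            sum(config$tau_shifts$shift[sel & config$tau_shifts$measure == msr])
      latent <- base_vec + rep(shift_vec, each = nr) + covar +
        stats::rnorm(ncell, 0, config$tau_noise_sd)
      score <- pmin(pmax(round(latent), 0), 3)
      score[stats::runif(ncell) < config$missing_region_rate] <- NA
      score_mat[k, ] <- score
    }
    pieces[[length(pieces) + 1L]] <- data.frame(
      subject_id = rep(subjects$subject_id[idx], each = ncell),
      group = grp,
      measure = rep(meas_vec, length(idx)),
      region = rep(rep(regions, length(TAU_MEASURES)), length(idx)),
      score = as.vector(t(score_mat)), stringsAsFactors = FALSE)
  }
  if (!length(pieces))
    return(data.frame(subject_id = character(0), group = character(0),
                      measure = character(0), region = character(0),
                      score = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
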