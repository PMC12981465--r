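# run code under a local, restorable RNG state
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Configure a synthetic screening registry
#'
#' Describes the statistical structure of a simulated screening round:
#' total attendance, the age-group mix, a per-group probability that a
#' screen detects a cancer, the stage mix of detected cancers and the
#' BI-RADS triage rates for disease-free women. Defaults mirror the
#' packaged registry's structure ([shenzhen_registry_counts()]): group
#' weights proportional to the printed screening populations,
#' per-group detection probabilities equal to the printed cases /
#' screened ratios, the overall printed stage mix, and the programme
#' triage rates (22.9\% BI-RADS 0/III, 2.3\% BI-RADS IV+).
#'
#' @param n_total number of records to generate.
#' @param age_groups data frame with \code{group}, \code{age_lower},
#'   \code{age_upper}.
#' @param group_weights attendance fractions per group (sum to 1).
#' @param detection_prob per-group probability that a screened woman
#'   has a detected cancer.
#' @param stage_mix named shares over DCIS, I, II, III, IV (sum to 1).
#' @param f_mam fraction of disease-free women triaged BI-RADS 0/III.
#' @param f_referral_pos fraction of disease-free women BI-RADS IV+.
#' @param seed generator seed.
#' @return A \code{bc_registry_config} list.
#' @export
registry_config <- function(n_total = 699600,
                            age_groups = default_age_groups(),
                            group_weights = NULL,
                            detection_prob = NULL,
                            stage_mix = NULL,
                            f_mam = 0.229,
                            f_referral_pos = 0.023,
                            seed = 1L) {
  printed <- shenzhen_registry_counts()
  printed <- printed[printed$group != "total", ]
  if (is.null(group_weights))
    group_weights <- printed$n_screened / sum(printed$n_screened)
  if (is.null(detection_prob))
    detection_prob <- rowSums(printed[, STAGES]) / printed$n_screened
  if (is.null(stage_mix)) {
    tot <- colSums(printed[, STAGES])
    stage_mix <- tot / sum(tot)
  }
  stopifnot(nrow(age_groups) == length(group_weights),
            nrow(age_groups) == length(detection_prob),
            abs(sum(group_weights) - 1) < 1e-9,
            all(detection_prob >= 0 & detection_prob <= 1),
            abs(sum(stage_mix) - 1) < 1e-9,
            f_mam >= 0, f_referral_pos >= 0,
            f_mam + f_referral_pos <= 1)
  structure(list(n_total = n_total, age_groups = age_groups,
                 group_weights = group_weights,
                 detection_prob = detection_prob,
                 stage_mix = stage_mix, f_mam = f_mam,
                 f_referral_pos = f_referral_pos, seed = seed),
            class = "bc_registry_config")
}

#' Generate a synthetic screening registry
#'
#' Draws individual screening records with the structure given by
#' [registry_config()]: ages from the group weights (uniform within a
#' group), cancer status per the group's detection probability, stages
#' of detected cancers from the stage mix (these records have
#' \code{biopsy_done = TRUE} and BI-RADS IV+ triage), and BI-RADS
#' triage categories for disease-free records at the configured rates
#' (false-positive BI-RADS IV+ referrals also get a biopsy). Fully
#' reproducible from the seed; the generator's own draws never touch
#' the caller's RNG state.
#'
#' @param config a \code{bc_registry_config}.
#' @return Data frame of screening records: \code{age},
#'   \code{birads_triage} (\code{negative}, \code{triage_0_III},
#'   \code{positive_IV_plus}), \code{biopsy_done}, \code{diagnosis}
#'   (\code{none} or a stage).
#' @export
generate_registry <- function(config) {
  stopifnot(inherits(config, "bc_registry_config"))
  n <- config$n_total
  empty <- data.frame(age = integer(), birads_triage = character(),
                      biopsy_done = logical(), diagnosis = character())
  if (n == 0) return(empty)
  with_local_seed(config$seed, {
    g <- sample.int(nrow(config$age_groups), n, replace = TRUE,
                    prob = config$group_weights)
    lo <- config$age_groups$age_lower[g]
    hi <- config$age_groups$age_upper[g]
    age <- lo + floor(stats::runif(n) * (hi - lo + 1))
    cancer <- stats::runif(n) < config$detection_prob[g]
    diagnosis <- rep("none", n)
    k <- sum(cancer)
    if (k > 0)
      diagnosis[cancer] <- sample(STAGES, k, replace = TRUE,
                                  prob = config$stage_mix)
    triage <- rep("negative", n)
    u <- stats::runif(n)
    triage[!cancer & u < config$f_mam] <- "triage_0_III"
    triage[!cancer & u >= config$f_mam &
             u < config$f_mam + config$f_referral_pos] <- "positive_IV_plus"
    triage[cancer] <- "positive_IV_plus"
    biopsy <- cancer | triage == "positive_IV_plus"
    data.frame(age = as.integer(age), birads_triage = triage,
               biopsy_done = biopsy, diagnosis = diagnosis)
  })
}
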