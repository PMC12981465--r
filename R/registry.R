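#' Packaged screening-registry counts
#'
#' The aggregate outcome table of one screening round of the urban
#' programme the model parameterises: screened women and detected
#' cancers by stage for six age groups, plus the programme's printed
#' totals row. Shipped exactly as printed; note the printed group rows
#' do not add up to the printed totals (cases 713 vs 724, screened
#' 697,384 vs 699,600) - [summarize_registry()] therefore uses the
#' explicit totals row for overall statistics and reports the mismatch
#' in its \code{consistency} field.
#'
#' @return Data frame with columns \code{group}, \code{age_lower},
#'   \code{age_upper}, \code{n_screened}, \code{DCIS}, \code{I},
#'   \code{II}, \code{III}, \code{IV}; the last row is the printed
#'   totals row (\code{group == "total"}).
#' @export
shenzhen_registry_counts <- function() {
  data.frame(
    group = c("35-39", "40-44", "45-49", "50-54", "55-59", "60-65",
              "total"),
    age_lower = c(35, 40, 45, 50, 55, 60, NA),
    age_upper = c(39, 44, 49, 54, 59, 65, NA),
    n_screened = c(229772, 169872, 128706, 93348, 55079, 20607, 699600),
    DCIS = c(13, 18, 26, 12, 5, 5, 81),
    I = c(36, 64, 55, 57, 42, 18, 274),
    II = c(37, 75, 56, 59, 38, 13, 281),
    III = c(5, 17, 20, 19, 5, 5, 73),
    IV = c(3, 0, 4, 4, 2, 0, 15)
  )
}

default_age_groups <- function() {
  data.frame(
    group = c("35-39", "40-44", "45-49", "50-54", "55-59", "60-65"),
    age_lower = c(35, 40, 45, 50, 55, 60),
    age_upper = c(39, 44, 49, 54, 59, 65)
  )
}

records_to_counts <- function(records, age_groups) {
  stopifnot(all(c("age", "diagnosis") %in% names(records)))
  uncovered <- !vapply(records$age, function(a)
    any(age_groups$age_lower <= a & a <= age_groups$age_upper),
    logical(1))
  if (any(uncovered))
    stop("ages not covered by the given groups: ",
         paste(unique(records$age[uncovered]), collapse = ", "),
         call. = FALSE)
  rows <- lapply(seq_len(nrow(age_groups)), function(i) {
    g <- age_groups[i, ]
    in_g <- records$age >= g$age_lower & records$age <= g$age_upper
    counts <- vapply(STAGES, function(s)
      sum(records$diagnosis[in_g] == s), integer(1))
    cbind(data.frame(group = g$group, age_lower = g$age_lower,
                     age_upper = g$age_upper, n_screened = sum(in_g)),
          as.data.frame(as.list(counts)))
  })
  do.call(rbind, rows)
}

#' Summarise a screening registry
#'
#' Computes the descriptive statistics of a screening round: per
#' age-group and overall case counts by stage, each group's share of
#' all cases, detection rates per 100,000 screened women, the overall
#' early-diagnosis rate (DCIS + stage I + stage II as a percentage of
#' all cases) and, for individual-level input, BI-RADS triage
#' fractions.
#'
#' Rounding follows the registry reporting convention: the overall
#' detection rate to 2 decimals, per-group rates to the nearest
#' integer, case shares to 2 decimals, the early-diagnosis rate to the
#' nearest integer. Unrounded values are kept in \code{*_raw} columns.
#'
#' @param x either individual records (data frame with columns
#'   \code{age}, \code{birads_triage}, \code{biopsy_done},
#'   \code{diagnosis} in \{none, DCIS, I, II, III, IV\}) or
#'   pre-aggregated per-group counts (columns \code{group},
#'   \code{age_lower}, \code{age_upper}, \code{n_screened},
#'   \code{DCIS}, \code{I}, \code{II}, \code{III}, \code{IV}),
#'   optionally including a \code{group == "total"} row whose values
#'   take precedence for the overall statistics.
#' @param age_groups age-group definition used to aggregate individual
#'   records (data frame with \code{group}, \code{age_lower},
#'   \code{age_upper}).
#' @return A \code{bc_registry_summary}: list with \code{by_group}
#'   (counts, \code{share_pct}, \code{rate_per_1e5} and raw columns),
#'   \code{overall} (n_screened, n_cases, stage counts, detection
#'   rate, early-diagnosis rate), \code{triage} (fractions, or
#'   \code{NULL} for grouped input) and \code{consistency} (character
#'   vector of internal inconsistencies, empty when clean).
#' @examples
#' s <- summarize_registry(shenzhen_registry_counts())
#' s$overall$detection_rate_per_1e5  # 103.49
#' s$overall$early_diagnosis_pct    # 88
#' @export
summarize_registry <- function(x, age_groups = default_age_groups()) {
  triage <- NULL
  total_row <- NULL
  if (all(c("age", "diagnosis") %in% names(x))) {
    records <- x
    counts <- records_to_counts(records, age_groups)
    if ("birads_triage" %in% names(records) && nrow(records)) {
      triage <- list(
        f_mam = mean(records$birads_triage == "triage_0_III"),
        f_referral_pos = mean(records$birads_triage == "positive_IV_plus"))
    }
    if (!is.null(records$biopsy_done) &&
        any(records$diagnosis != "none" & !records$biopsy_done))
      stop("malformed records: diagnosis without biopsy_done",
           call. = FALSE)
  } else if (all(c("n_screened", STAGES) %in% names(x))) {
    counts <- x
    if ("group" %in% names(counts) && any(counts$group == "total")) {
      total_row <- counts[counts$group == "total", ][1, ]
      counts <- counts[counts$group != "total", ]
    }
  } else {
    stop("x must be individual records or per-group stage counts",
         call. = FALSE)
  }

  counts$n_cases <- rowSums(counts[, STAGES, drop = FALSE])
  tot_screened <- if (!is.null(total_row)) total_row$n_screened
                  else sum(counts$n_screened)
  tot_stage <- if (!is.null(total_row)) unlist(total_row[STAGES])
               else colSums(counts[, STAGES, drop = FALSE])
  tot_cases <- sum(tot_stage)

  consistency <- character()
  if (!is.null(total_row)) {
    if (sum(counts$n_cases) != tot_cases)
      consistency <- c(consistency, sprintf(
        "group case counts sum to %d but the total row says %d",
        sum(counts$n_cases), tot_cases))
    if (sum(counts$n_screened) != tot_screened)
      consistency <- c(consistency, sprintf(
        "group screening populations sum to %d but the total row says %d",
        sum(counts$n_screened), tot_screened))
  }

  by_group <- counts
  by_group$share_raw <- if (tot_cases > 0)
    by_group$n_cases / tot_cases * 100 else NA_real_
  by_group$share_pct <- round(by_group$share_raw, 2)
  by_group$rate_raw <- ifelse(by_group$n_screened > 0,
                              by_group$n_cases / by_group$n_screened * 1e5,
                              NA_real_)
  by_group$rate_per_1e5 <- round(by_group$rate_raw)
  if (any(by_group$n_screened == 0))
    consistency <- c(consistency, sprintf(
      "detection rate undefined for group(s) with nobody screened: %s",
      paste(by_group$group[by_group$n_screened == 0], collapse = ", ")))

  early <- sum(tot_stage[c("DCIS", "I", "II")])
  overall <- list(
    n_screened = tot_screened,
    n_cases = tot_cases,
    stage_counts = tot_stage,
    detection_rate_raw = if (tot_screened > 0)
      tot_cases / tot_screened * 1e5 else NA_real_,
    detection_rate_per_1e5 = if (tot_screened > 0)
      round(tot_cases / tot_screened * 1e5, 2) else NA_real_,
    early_diagnosis_raw = if (tot_cases > 0)
      early / tot_cases * 100 else NA_real_,
    early_diagnosis_pct = if (tot_cases > 0)
      round(early / tot_cases * 100) else NA_real_
  )
  if (tot_cases == 0)
    consistency <- c(consistency,
                     "no cases: shares and early-diagnosis rate undefined")
  if (tot_screened == 0)
    consistency <- c(consistency,
                     "empty registry: detection rate undefined")

  structure(list(by_group = by_group, overall = overall,
                 triage = triage, consistency = consistency),
            class = "bc_registry_summary")
}

#' Age-group shares and detection rates
#'
#' @param summary a \code{bc_registry_summary}.
#' @return Data frame with \code{group}, \code{share_pct} (percentage
#'   of all cases, 2 decimals) and \code{rate_per_1e5} (detections per
#'   100,000 screened, nearest integer).
#' @export
age_group_rates <- function(summary) {
  stopifnot(inherits(summary, "bc_registry_summary"))
  summary$by_group[, c("group", "share_pct", "rate_per_1e5")]
}

#' @export
print.bc_registry_summary <- function(x, ...) {
  o <- x$overall
  cat("<bc_registry_summary>\n")
  cat(sprintf("  %s screened, %d cases (%.2f per 100,000), early diagnosis %s%%\n",
              format(o$n_screened, big.mark = ","), o$n_cases,
              o$detection_rate_raw, o$early_diagnosis_pct))
  print(x$by_group[, c("group", "n_screened", "n_cases", "share_pct",
                       "rate_per_1e5")], row.names = FALSE)
  if (length(x$consistency))
    cat("  consistency:", paste(x$consistency, collapse = "; "), "\n")
  invisible(x)
}
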