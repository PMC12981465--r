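#' Cohort engine options
#'
#' Structural switches for the cohort engine. Defaults reproduce the
#' reference model structure: no half-cycle correction (utilities and
#' recurring costs accrue for the full cycle in the start-of-cycle
#' state) and same-cycle clinical diagnosis of screen-missed cases.
#'
#' @param half_cycle if \code{TRUE}, utility and recurring outpatient
#'   cost accruals use the average of start- and end-of-cycle
#'   occupancy (half-cycle correction); one-off event costs
#'   (screening, diagnosis) are unaffected.
#' @param missed_carryover if \code{TRUE}, cases missed by a screen
#'   wait in an undiagnosed pool (healthy utility) and present at the
#'   next cycle - detected with probability equal to the sensitivity
#'   if that cycle has a screen, otherwise clinically. If \code{FALSE}
#'   (reference), missed cases are clinically diagnosed in the same
#'   cycle.
#' @return A list of engine options.
#' @export
cohort_options <- function(half_cycle = FALSE, missed_carryover = FALSE) {
  list(half_cycle = isTRUE(half_cycle),
       missed_carryover = isTRUE(missed_carryover))
}

#' Screening-round cost and detections for one cycle
#'
#' Implements the (CBE+BUS)+MAM triage pathway costing for a screening
#' round: every attending woman receives CBE and ultrasound; a fraction
#' \code{f_mam} is triaged to supplementary mammography; biopsies go to
#' true positives (diseased x sensitivity) and false positives
#' (disease-free x (1 - specificity)).
#'
#' @param params a \code{bc_params} object.
#' @param eligible_fraction fraction of the cohort attending the screen
#'   (never-diagnosed, alive).
#' @param diseased_fraction fraction of the cohort attending with
#'   as-yet-undiagnosed disease (subset of \code{eligible_fraction}).
#' @return List with \code{cost} (CNY per cohort member) and
#'   \code{detected} (fraction of the cohort screen-detected).
#' @examples
#' screening_cycle_cost(default_parameters(), 1, 0)$cost  # about 216.17
#' @export
screening_cycle_cost <- function(params, eligible_fraction,
                                 diseased_fraction) {
  stopifnot(eligible_fraction >= 0, eligible_fraction <= 1,
            diseased_fraction >= 0,
            diseased_fraction <= eligible_fraction + 1e-12)
  sc <- params$screening_costs
  se <- params$test$sensitivity[["base"]]
  sp <- params$test$specificity[["base"]]
  detected <- diseased_fraction * se
  n_biopsy <- detected + (eligible_fraction - diseased_fraction) * (1 - sp)
  cost <- eligible_fraction * (sc$c_cbe + sc$c_us) +
    eligible_fraction * sc$f_mam * sc$c_mam +
    n_biopsy * sc$c_biopsy
  list(cost = cost, detected = detected)
}

# Expected one-off diagnosis cost (treatment + direct non-medical) and
# per-cycle outpatient cost for a diagnosed case, averaged over a stage
# mix. mode selects the treatment-cost column.
stage_mix_costs <- function(params, mix, mode = c("screen", "noscreen")) {
  mode <- match.arg(mode)
  col <- if (mode == "screen") "c_treat_screen" else "c_treat_noscreen"
  diag_cost <- sum(vapply(STAGES, function(s)
    mix[[s]] * (params$stage_costs[[s]][[col]][["base"]] +
                params$stage_costs[[s]][["c_nonmedical"]][["base"]]),
    numeric(1)))
  outp_cost <- sum(vapply(STAGES, function(s)
    mix[[s]] * params$stage_costs[[s]][["c_outpatient"]][["base"]],
    numeric(1)))
  list(diagnosis = diag_cost, outpatient = outp_cost)
}

#' Run the Markov cohort model for one strategy
#'
#' Advances a closed cohort (fractions of it, deterministically) through
#' the health states Healthy, DCIS, invasive stages I-IV and death
#' (breast-cancer vs other-cause) over \code{params$econ$n_cycles}
#' annual cycles, starting 100\% healthy at
#' \code{params$econ$start_age}. Per cycle, in order:
#' \enumerate{
#'   \item if the strategy screens at this age, the never-diagnosed pool
#'     attends: screening costs accrue per [screening_cycle_cost()] and
#'     incident cases are screen-detected with probability equal to the
#'     test sensitivity;
#'   \item incidence moves healthy women to a diagnosed stage - the
#'     screen-detected stage mix for detections, the clinically detected
#'     mix otherwise;
#'   \item diagnosed DCIS progresses to diagnosed stage I with annual
#'     probability \code{rr_dcis * lambda(age)}; invasive stages
#'     progress and die of breast cancer per the progression parameters;
#'     all alive states face other-cause mortality \code{mu_other(age)};
#'   \item utilities accrue by health state (death = 0); costs accrue as
#'     screening costs, one-off diagnosis costs (stage-mix treatment by
#'     detection mode plus direct non-medical costs) and recurring
#'     outpatient costs for every cycle spent diagnosed, including the
#'     diagnosis cycle;
#'   \item cycle totals are discounted by \code{(1 + r)^(-t)} with
#'     \code{t = 0} at the start age.
#' }
#'
#' @param params a valid \code{bc_params} object.
#' @param strategy a \code{bc_strategy}.
#' @param options engine options from [cohort_options()].
#' @return A \code{bc_trace}: list with \code{cycles} (one row per
#'   cycle: age, state occupancy, cost components, QALY and discounted
#'   increments), per-person totals \code{discounted_cost},
#'   \code{discounted_qaly}, \code{undiscounted_cost},
#'   \code{undiscounted_qaly}, and the \code{strategy}.
#' @export
run_cohort <- function(params, strategy, options = cohort_options()) {
  assert_valid_parameters(params)
  ec <- params$econ
  pr <- params$progression
  u <- params$utilities
  r <- ec$discount_rate
  n <- ec$n_cycles

  healthy <- 1
  pool <- 0  # undiagnosed carryover (missed_carryover mode only)
  dx <- stats::setNames(numeric(5), STAGES)
  death_bc <- 0
  death_other <- 0

  # stage-mix cost constants (independent of cycle)
  mix_s <- params$stage_screen
  mix_c <- params$stage_clinical
  cc_screen <- stage_mix_costs(params, mix_s, "screen")
  cc_clin <- stage_mix_costs(params, mix_c, "noscreen")
  outp_base <- vapply(STAGES, function(s)
    params$stage_costs[[s]][["c_outpatient"]][["base"]], numeric(1))
  u_stage <- u[STAGES]

  trace_mat <- matrix(0, nrow = n, ncol = 17)
  tot <- c(cost = 0, qaly = 0, dcost = 0, dqaly = 0)

  for (t in seq_len(n) - 1L) {
    age <- ec$start_age + t
    lam <- age_lookup(params$incidence, age, "lambda")
    mu_o <- age_lookup(params$mortality, age, "mu_other")
    screen_now <- is_screening_cycle(strategy, age)

    incident <- healthy * lam
    out_healthy <- lam + mu_o
    if (out_healthy > 1)
      stop(sprintf(
        "probability mass leaving state Healthy exceeds 1 (%.4f) at age %d",
        out_healthy, age), call. = FALSE)

    cost_screen <- 0
    new_screen <- 0  # screen-detected diagnoses this cycle
    new_clin <- 0    # clinically detected diagnoses this cycle
    pool_next <- 0
    if (screen_now) {
      eligible <- healthy + pool
      diseased <- incident + pool
      scr <- screening_cycle_cost(params, eligible, diseased)
      cost_screen <- scr$cost
      new_screen <- scr$detected
      missed <- diseased - scr$detected
      if (options$missed_carryover) pool_next <- missed
      else new_clin <- missed
    } else {
      new_clin <- incident + pool
    }

    # progression / death flows from start-of-cycle diagnosed occupancy
    p_dcis_I <- min(1, pr$rr_dcis * lam)
    outgoing <- c(
      DCIS = p_dcis_I + mu_o,
      I = pr$p_I_II + pr$p_I_IV + pr$mort[["I"]] + mu_o,
      II = pr$p_II_III + pr$p_II_IV + pr$mort[["II"]] + mu_o,
      III = pr$p_III_IV + pr$mort[["III"]] + mu_o,
      IV = pr$mort[["IV"]] + mu_o
    )
    over <- outgoing > 1 + 1e-12
    if (any(over))
      stop(sprintf(
        "probability mass leaving state %s exceeds 1 (%.4f) at age %d",
        names(outgoing)[over][1], outgoing[over][1], age), call. = FALSE)

    dx_next <- c(
      DCIS = dx[["DCIS"]] * (1 - p_dcis_I - mu_o),
      I = dx[["I"]] * (1 - pr$p_I_II - pr$p_I_IV - pr$mort[["I"]] - mu_o) +
        dx[["DCIS"]] * p_dcis_I,
      II = dx[["II"]] * (1 - pr$p_II_III - pr$p_II_IV - pr$mort[["II"]] -
                           mu_o) + dx[["I"]] * pr$p_I_II,
      III = dx[["III"]] * (1 - pr$p_III_IV - pr$mort[["III"]] - mu_o) +
        dx[["II"]] * pr$p_II_III,
      IV = dx[["IV"]] * (1 - pr$mort[["IV"]] - mu_o) +
        dx[["I"]] * pr$p_I_IV + dx[["II"]] * pr$p_II_IV +
        dx[["III"]] * pr$p_III_IV
    ) + new_screen * mix_s + new_clin * mix_c

    death_bc_next <- death_bc +
      dx[["I"]] * pr$mort[["I"]] + dx[["II"]] * pr$mort[["II"]] +
      dx[["III"]] * pr$mort[["III"]] + dx[["IV"]] * pr$mort[["IV"]]
    # the pool exits wholly into diagnosis the cycle it presents, so
    # other-cause death applies to the healthy and diagnosed masses only
    death_other_next <- death_other + healthy * mu_o + sum(dx) * mu_o
    healthy_next <- healthy * (1 - lam - mu_o)

    # accruals for cycle t
    cost_diag <- new_screen * cc_screen$diagnosis + new_clin * cc_clin$diagnosis
    outp_start <- sum(dx * outp_base)
    outp_new <- new_screen * cc_screen$outpatient + new_clin * cc_clin$outpatient
    qaly_start <- (healthy + pool) * u[["Healthy"]] + sum(dx * u_stage)

    if (options$half_cycle) {
      qaly_end <- (healthy_next + pool_next) * u[["Healthy"]] +
        sum(dx_next * u_stage)
      outp_end <- sum(dx_next * outp_base)
      qaly_t <- (qaly_start + qaly_end) / 2
      cost_followup <- (outp_start + outp_end) / 2 + outp_new / 2
    } else {
      qaly_t <- qaly_start
      cost_followup <- outp_start + outp_new
    }
    cost_t <- cost_screen + cost_diag + cost_followup
    disc <- (1 + r)^(-t)

    trace_mat[t + 1L, ] <- c(
      t, age, healthy + pool, dx, death_bc, death_other,
      cost_screen, cost_diag, cost_followup, cost_t,
      qaly_t, cost_t * disc, qaly_t * disc)
    tot <- tot + c(cost_t, qaly_t, cost_t * disc, qaly_t * disc)

    healthy <- healthy_next
    pool <- pool_next
    dx <- dx_next
    death_bc <- death_bc_next
    death_other <- death_other_next

    total_mass <- healthy + pool + sum(dx) + death_bc + death_other
    if (abs(total_mass - 1) > 1e-9)
      stop(sprintf(
        "cohort mass not conserved at age %d: total %.12f", age, total_mass),
        call. = FALSE)
  }

  cycles <- as.data.frame(trace_mat)
  names(cycles) <- c("cycle", "age", "Healthy", "DCIS", "I", "II", "III",
                     "IV", "Death_BC", "Death_Other", "cost_screening",
                     "cost_diagnosis", "cost_followup", "cost_total",
                     "qaly", "disc_cost", "disc_qaly")
  structure(
    list(cycles = cycles,
         discounted_cost = tot[["dcost"]],
         discounted_qaly = tot[["dqaly"]],
         undiscounted_cost = tot[["cost"]],
         undiscounted_qaly = tot[["qaly"]],
         strategy = strategy,
         options = options),
    class = "bc_trace"
  )
}

#' Cost-effectiveness point of a cohort trace
#'
#' @param trace a \code{bc_trace} from [run_cohort()].
#' @return One-row data frame with \code{label}, \code{cost} (discounted
#'   CNY per person) and \code{effect} (discounted QALYs per person).
#' @export
ce_point <- function(trace) {
  stopifnot(inherits(trace, "bc_trace"))
  data.frame(label = trace$strategy$label,
             cost = trace$discounted_cost,
             effect = trace$discounted_qaly)
}

#' Cost-effectiveness points for a set of strategies
#'
#' Runs the cohort model for every strategy (plus, by default, the
#' no-screening comparator prepended) and collects the discounted CE
#' points.
#'
#' @param params a valid \code{bc_params} object.
#' @param strategies list of \code{bc_strategy} objects; defaults to the
#'   27-strategy design space from [enumerate_strategies()].
#' @param include_no_screening prepend the no-screening comparator.
#' @param options engine options from [cohort_options()].
#' @return Data frame of CE points (label, cost, effect), one row per
#'   strategy.
#' @export
run_strategy_set <- function(params,
                             strategies = enumerate_strategies(),
                             include_no_screening = TRUE,
                             options = cohort_options()) {
  if (include_no_screening)
    strategies <- c(list(no_screening()), strategies)
  do.call(rbind, lapply(strategies, function(s)
    ce_point(run_cohort(params, s, options))))
}

#' @export
print.bc_trace <- function(x, ...) {
  cat(sprintf("<bc_trace> %s: %d cycles\n", x$strategy$label,
              nrow(x$cycles)))
  cat(sprintf("  discounted per person: %.2f CNY, %.4f QALYs\n",
              x$discounted_cost, x$discounted_qaly))
  cat(sprintf("  undiscounted: %.2f CNY, %.4f QALYs\n",
              x$undiscounted_cost, x$undiscounted_qaly))
  invisible(x)
}
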