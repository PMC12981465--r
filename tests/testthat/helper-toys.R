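# Toy parameter sets and an independent hand-enumeration oracle for
# small cohort models. The oracle walks the per-cycle event tree state
# by state with explicit arithmetic; it shares no code with the engine.

# A degenerate parameter set: no incidence, no mortality, no
# progression. The cohort stays 100% healthy.
toy_inert_params <- function(n_cycles = 50, discount_rate = 0.03) {
  p <- default_parameters()
  p$incidence$lambda[] <- 0
  p$mortality$mu_all[] <- 0
  p$mortality$mu_bc[] <- 0
  p$mortality$mu_other[] <- 0
  p$progression[c("p_I_II", "p_II_III", "p_I_IV", "p_II_IV",
                  "p_III_IV")] <- 0
  p$progression$mort[] <- 0
  p$econ$n_cycles <- n_cycles
  p$econ$discount_rate <- discount_rate
  p
}

# Two-state toy: healthy women develop disease at rate lambda and are
# clinically diagnosed into a single stage (II, utility 0.8). No death,
# no discounting, optional costs.
toy_single_stage_params <- function(lambda = 0.1, n_cycles = 2,
                                    discount_rate = 0,
                                    mu_other = 0, mort_II = 0) {
  p <- toy_inert_params(n_cycles, discount_rate)
  p$incidence$lambda[] <- lambda
  p$mortality$mu_all[] <- mu_other
  p$mortality$mu_other[] <- mu_other
  p$progression$mort[["II"]] <- mort_II
  p$stage_clinical[] <- c(0, 0, 1, 0, 0)
  p$stage_screen[] <- c(0, 0, 1, 0, 0)
  p
}

# strip all costs so only the named components remain
zero_costs <- function(p) {
  for (s in names(p$stage_costs))
    for (nm in names(p$stage_costs[[s]]))
      p$stage_costs[[s]][[nm]][] <- 0
  p$screening_costs[c("c_cbe", "c_mam", "c_us", "c_biopsy")] <- 0
  p
}

# Independent oracle: expected discounted cost and QALY per person for
# the single-stage toy (states: healthy H, diagnosed D, dead X), by
# explicit forward bookkeeping of state masses. Screening (optional)
# detects incident cases with probability se in screen cycles; both
# detection modes land in the same stage here, but costs may differ.
oracle_single_stage <- function(p, screen_ages = integer(),
                                se = p$test$sensitivity[["base"]]) {
  lam <- p$incidence$lambda[1]
  mu <- p$mortality$mu_other[1]
  mort <- p$progression$mort[["II"]]
  u_D <- p$utilities[["II"]]
  r <- p$econ$discount_rate
  sc <- p$screening_costs
  sp <- p$test$specificity[["base"]]
  cost_diag_scr <- p$stage_costs$II$c_treat_screen[["base"]] +
    p$stage_costs$II$c_nonmedical[["base"]]
  cost_diag_clin <- p$stage_costs$II$c_treat_noscreen[["base"]] +
    p$stage_costs$II$c_nonmedical[["base"]]
  c_out <- p$stage_costs$II$c_outpatient[["base"]]

  H <- 1; D <- 0; X <- 0
  tot_cost <- 0; tot_qaly <- 0
  for (t in seq_len(p$econ$n_cycles) - 1) {
    age <- p$econ$start_age + t
    inc <- H * lam
    cost_t <- 0
    if (age %in% screen_ages) {
      det <- inc * se
      clin <- inc - det
      cost_t <- cost_t + H * (sc$c_cbe + sc$c_us) +
        H * sc$f_mam * sc$c_mam +
        (det + (H - inc) * (1 - sp)) * sc$c_biopsy
    } else {
      det <- 0
      clin <- inc
    }
    cost_t <- cost_t + det * cost_diag_scr + clin * cost_diag_clin
    cost_t <- cost_t + (D + det + clin) * c_out
    qaly_t <- H + D * u_D
    disc <- (1 + r)^(-t)
    tot_cost <- tot_cost + cost_t * disc
    tot_qaly <- tot_qaly + qaly_t * disc
    H_next <- H - inc - H * mu
    D_next <- D * (1 - mort - mu) + det + clin
    X <- X + H * mu + D * (mort + mu)
    H <- H_next; D <- D_next
  }
  list(cost = tot_cost, qaly = tot_qaly)
}

# Brute-force dominance oracle for small CE-point sets: a point is on
# the frontier iff it is not weakly dominated by any single point or by
# any convex combination of two other points.
oracle_frontier_members <- function(points) {
  n <- nrow(points)
  on <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (points$effect[j] >= points$effect[i] &&
          points$cost[j] <= points$cost[i] &&
          (points$effect[j] > points$effect[i] ||
           points$cost[j] < points$cost[i] ||
           points$label[j] < points$label[i] &&
           points$effect[j] == points$effect[i] &&
           points$cost[j] == points$cost[i])) {
        on[i] <- FALSE
      }
    }
    if (!on[i]) next
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (j == i || k == i || j == k) next
      ej <- points$effect[j]; ek <- points$effect[k]
      if (ej >= ek) next
      ei <- points$effect[i]
      if (ei <= ej || ei >= ek) next
      w <- (ei - ej) / (ek - ej)
      blend_cost <- (1 - w) * points$cost[j] + w * points$cost[k]
      if (blend_cost <= points$cost[i]) on[i] <- FALSE
    }
  }
  sort(points$label[on])
}

default_pair <- function()
  list(no_screening(), screening_strategy(35, 65, 2))
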