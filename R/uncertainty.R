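#' Default one-way sensitivity ranges
#'
#' The deterministic-sensitivity (tornado) ranges: printed (low, high)
#' ranges for stage costs and test sensitivity/specificity; documented
#' conventional ranges elsewhere - discount rate 0 to 5\%, screening
#' unit costs +/-20\%, health-state utilities +/-10\% capped at
#' \eqn{[0,1]} (healthy utility is fixed at 1 and not varied).
#'
#' @param params a \code{bc_params} object.
#' @return Data frame with columns \code{param} (dot-path identifier,
#'   see [param_get()]), \code{base}, \code{low}, \code{high}.
#' @export
default_dsa_ranges <- function(params) {
  rows <- list()
  add <- function(param, base, low, high)
    rows[[length(rows) + 1L]] <<- data.frame(
      param = param, base = base, low = low, high = high)

  add("econ.discount_rate", params$econ$discount_rate, 0, 0.05)
  for (nm in c("c_cbe", "c_mam", "c_us", "c_biopsy")) {
    b <- params$screening_costs[[nm]]
    add(paste0("screening_costs.", nm), b, 0.8 * b, 1.2 * b)
  }
  for (s in STAGES) {
    b <- params$utilities[[s]]
    add(paste0("utilities.", s), b, max(0, 0.9 * b), min(1, 1.1 * b))
  }
  for (s in STAGES)
    for (nm in names(params$stage_costs[[s]])) {
      rv <- params$stage_costs[[s]][[nm]]
      add(sprintf("stage_costs.%s.%s", s, nm),
          rv[["base"]], rv[["low"]], rv[["high"]])
    }
  for (nm in c("sensitivity", "specificity")) {
    rv <- params$test[[nm]]
    add(paste0("test.", nm), rv[["base"]], rv[["low"]], rv[["high"]])
  }
  out <- do.call(rbind, rows)
  stopifnot(all(out$low <= out$base), all(out$base <= out$high))
  out
}

pair_icur <- function(params, strategy_pair, options = cohort_options()) {
  ref <- ce_point(run_cohort(params, strategy_pair[[1]], options))
  alt <- ce_point(run_cohort(params, strategy_pair[[2]], options))
  icur(ref, alt)
}

#' One-way sensitivity of a pairwise ICUR to a single parameter
#'
#' Re-runs the cohort model for both strategies with the parameter at
#' its low and at its high value (everything else at base) and reports
#' the two ICURs and the swing between them.
#'
#' @param params a \code{bc_params} object.
#' @param range one-row data frame (or list) with \code{param},
#'   \code{base}, \code{low}, \code{high}.
#' @param strategy_pair list of two \code{bc_strategy} objects:
#'   (comparator, strategy of interest), e.g. no screening first.
#' @param options engine options.
#' @return One-row data frame: \code{param}, \code{icur_at_low},
#'   \code{icur_at_high}, \code{swing}.
#' @export
one_way <- function(params, range, strategy_pair,
                    options = cohort_options()) {
  lo <- pair_icur(param_set(params, range$param, range$low),
                  strategy_pair, options)
  hi <- pair_icur(param_set(params, range$param, range$high),
                  strategy_pair, options)
  data.frame(param = range$param, icur_at_low = lo, icur_at_high = hi,
             swing = abs(hi - lo))
}

#' Tornado table of one-way sensitivities
#'
#' One [one_way()] entry per range, sorted by decreasing swing
#' (deterministic ties broken by parameter identifier).
#'
#' @param params a \code{bc_params} object.
#' @param ranges data frame of ranges, e.g. [default_dsa_ranges()].
#' @param strategy_pair list of two \code{bc_strategy} objects
#'   (comparator first).
#' @param options engine options.
#' @return Data frame of tornado entries, widest swing first, with the
#'   base-case ICUR as attribute \code{"icur_base"}.
#' @export
tornado <- function(params, ranges = default_dsa_ranges(params),
                    strategy_pair, options = cohort_options()) {
  stopifnot(nrow(ranges) >= 1)
  entries <- do.call(rbind, lapply(seq_len(nrow(ranges)), function(i)
    one_way(params, ranges[i, ], strategy_pair, options)))
  entries <- entries[order(-entries$swing, entries$param), ]
  rownames(entries) <- NULL
  attr(entries, "icur_base") <- pair_icur(params, strategy_pair, options)
  entries
}

is_cost_param <- function(path) {
  grepl("^stage_costs\\.", path) ||
    grepl("^screening_costs\\.c_", path)
}

#' Assign probabilistic distributions to parameter ranges
#'
#' Method-of-moments construction used in place of unavailable
#' distribution tables: each (low, high) range is read as a 95\%
#' interval, so \code{sd = (high - low) / 3.92} with mean at the base
#' value. Probabilities, utilities and test performance get beta
#' distributions; costs get gamma distributions. A zero-width range
#' yields a flagged point mass.
#'
#' @param params a \code{bc_params} object.
#' @param ranges data frame of ranges (param, base, low, high).
#' @return Data frame with \code{param}, \code{family} (\code{"beta"},
#'   \code{"gamma"} or \code{"point"}), shape parameters
#'   (\code{shape1}, \code{shape2} for beta; \code{shape}, \code{scale}
#'   for gamma) and the \code{base} value.
#' @examples
#' r <- data.frame(param = "test.sensitivity", base = 0.851,
#'                 low = 0.758, high = 0.944)
#' assign_distributions(default_parameters(), r)  # beta(47.07, 8.24)
#' @export
assign_distributions <- function(params, ranges) {
  stopifnot(all(ranges$low <= ranges$base), all(ranges$base <= ranges$high))
  out <- lapply(seq_len(nrow(ranges)), function(i) {
    r <- ranges[i, ]
    m <- r$base
    sd <- (r$high - r$low) / 3.92
    row <- data.frame(param = r$param, family = "point",
                      shape1 = NA_real_, shape2 = NA_real_,
                      shape = NA_real_, scale = NA_real_, base = m)
    if (sd == 0) return(row)
    v <- sd^2
    if (is_cost_param(r$param)) {
      row$family <- "gamma"
      row$shape <- m^2 / v
      row$scale <- v / m
    } else {
      if (m <= 0 || m >= 1)
        stop("beta family needs a base in (0,1) for ", r$param,
             call. = FALSE)
      nu <- m * (1 - m) / v - 1
      if (nu <= 0)
        stop("range too wide for a beta distribution at ", r$param,
             call. = FALSE)
      row$family <- "beta"
      row$shape1 <- m * nu
      row$shape2 <- (1 - m) * nu
    }
    row
  })
  do.call(rbind, out)
}

#' Default probabilistic-sensitivity distribution set
#'
#' The sampled parameters of the probabilistic analysis: stage costs
#' and test performance with their printed ranges, screening unit costs
#' at +/-20\% and utilities at +/-10\%. The discount rate is a policy
#' setting, varied in the one-way analysis only, and is excluded here.
#'
#' @param params a \code{bc_params} object.
#' @return Distribution specification data frame, see
#'   [assign_distributions()].
#' @export
default_psa_distributions <- function(params) {
  ranges <- default_dsa_ranges(params)
  ranges <- ranges[ranges$param != "econ.discount_rate", ]
  assign_distributions(params, ranges)
}

# deterministic substream seed for (root seed, parameter path,
# iteration): each draw depends only on this triple, so adding or
# removing a parameter never perturbs the others' draws
substream_seed <- function(seed, path, iteration) {
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(path)) h <- (h * 31 + b) %% m
  (seed %% m + h + iteration * 97003) %% m
}

draw_param <- function(spec, seed, iteration) {
  redraws <- 0L
  set.seed(substream_seed(seed, spec$param, iteration))
  repeat {
    x <- switch(spec$family,
      point = spec$base,
      beta = stats::rbeta(1, spec$shape1, spec$shape2),
      gamma = stats::rgamma(1, shape = spec$shape, scale = spec$scale),
      stop("unknown distribution family: ", spec$family, call. = FALSE))
    valid <- is.finite(x) && x >= 0 &&
      (is_cost_param(spec$param) || x <= 1)
    if (valid) return(list(value = x, redraws = redraws))
    redraws <- redraws + 1L
  }
}

#' Draw one joint parameter sample
#'
#' One Monte Carlo realisation of every parameter in a distribution
#' specification, under the substream contract of [run_psa()] (each
#' value depends only on the root seed, the parameter identifier and
#' the iteration index). Invalid draws (a probability outside
#' \eqn{[0,1]}) are redrawn and counted.
#'
#' @param specs distribution specification data frame, see
#'   [assign_distributions()].
#' @param seed root random seed.
#' @param iteration iteration index (>= 1).
#' @return List with \code{values} (named numeric vector by parameter
#'   identifier) and \code{redraws} (count).
#' @export
sample_distributions <- function(specs, seed, iteration = 1L) {
  redraws <- 0L
  values <- vapply(seq_len(nrow(specs)), function(i) {
    d <- draw_param(specs[i, ], seed, iteration)
    redraws <<- redraws + d$redraws
    d$value
  }, numeric(1))
  list(values = stats::setNames(values, specs$param), redraws = redraws)
}

#' Probabilistic sensitivity analysis (second-order Monte Carlo)
#'
#' Draws all sampled parameters jointly (independently across
#' parameters) in each iteration, runs the cohort model for both
#' strategies of the pair, and records the incremental cost and
#' incremental QALYs. Acceptability at the 3x-GDP willingness-to-pay
#' threshold and the 95\% confidence ellipse (sample mean and
#' covariance scaled by the chi-square(2) 0.95 quantile, 5.991) are
#' computed from the draws.
#'
#' Reproducibility contract: one root seed; each parameter draw uses a
#' substream derived deterministically from (seed, parameter,
#' iteration), so results are bit-identical across runs with the same
#' seed and adding a parameter does not perturb the other draws.
#'
#' @param params a \code{bc_params} object.
#' @param specs distribution specification data frame, e.g.
#'   [default_psa_distributions()].
#' @param strategy_pair list of two \code{bc_strategy} objects:
#'   (comparator, strategy of interest). Incremental quantities are
#'   strategy of interest minus comparator.
#' @param n_iterations number of Monte Carlo iterations (>= 1).
#' @param seed root random seed.
#' @param options engine options.
#' @return A \code{bc_psa}: list with \code{draws} (iteration,
#'   delta_cost, delta_effect), \code{n_iterations}, \code{seed},
#'   \code{acceptability} (at \code{wtp_3x}), \code{wtp},
#'   \code{ellipse} (center, covariance, level, scale) and
#'   \code{redraws}.
#' @export
run_psa <- function(params, specs = default_psa_distributions(params),
                    strategy_pair, n_iterations = 1000, seed,
                    options = cohort_options()) {
  stopifnot(n_iterations >= 1, !missing(seed))
  dc <- numeric(n_iterations)
  de <- numeric(n_iterations)
  redraws <- 0L
  for (it in seq_len(n_iterations)) {
    p_it <- params
    smp <- sample_distributions(specs, seed, it)
    redraws <- redraws + smp$redraws
    for (nm in names(smp$values))
      p_it <- param_set(p_it, nm, smp$values[[nm]])
    ref <- run_cohort(p_it, strategy_pair[[1]], options)
    alt <- run_cohort(p_it, strategy_pair[[2]], options)
    dc[it] <- alt$discounted_cost - ref$discounted_cost
    de[it] <- alt$discounted_qaly - ref$discounted_qaly
  }
  draws <- data.frame(iteration = seq_len(n_iterations),
                      delta_cost = dc, delta_effect = de)
  wtp <- params$econ$wtp_3x
  res <- structure(
    list(draws = draws, n_iterations = n_iterations, seed = seed,
         wtp = wtp, acceptability = NA_real_,
         ellipse = confidence_ellipse(cbind(dc, de)),
         redraws = redraws),
    class = "bc_psa")
  res$acceptability <- acceptability(res, wtp)
  res
}

#' 95\% confidence ellipse of a bivariate sample
#'
#' Center at the sample mean; shape from the sample covariance scaled
#' by the chi-square(2) quantile at the confidence level (5.991 at
#' 95\%). Semi-axis lengths are \code{sqrt(scale * eigenvalues)}.
#'
#' @param xy two-column matrix of points.
#' @param level confidence level.
#' @return List with \code{center} (length 2), \code{cov} (2x2),
#'   \code{level}, \code{scale}, and \code{semi_axes}.
#' @export
confidence_ellipse <- function(xy, level = 0.95) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2)
  ctr <- colMeans(xy)
  cv <- if (nrow(xy) > 1) stats::cov(xy) else matrix(0, 2, 2)
  scale <- stats::qchisq(level, df = 2)
  ev <- eigen(cv, symmetric = TRUE)$values
  list(center = ctr, cov = cv, level = level, scale = scale,
       semi_axes = sqrt(scale * pmax(ev, 0)))
}

#' Acceptability of a strategy at a willingness-to-pay threshold
#'
#' Fraction of PSA iterations with non-negative incremental net
#' monetary benefit, \code{delta_effect * wtp - delta_cost >= 0}. The
#' net-benefit rule handles negative incremental effects coherently,
#' unlike the raw ICUR sign.
#'
#' @param result a \code{bc_psa} from [run_psa()].
#' @param wtp willingness-to-pay threshold in CNY per QALY.
#' @return Fraction in \eqn{[0,1]}.
#' @export
acceptability <- function(result, wtp) {
  stopifnot(inherits(result, "bc_psa"), nrow(result$draws) >= 1)
  mean(result$draws$delta_effect * wtp - result$draws$delta_cost >= 0)
}

#' @export
print.bc_psa <- function(x, ...) {
  cat(sprintf("<bc_psa> %d iterations (seed %d)\n", x$n_iterations,
              x$seed))
  cat(sprintf("  mean incremental cost %.2f CNY, effect %.5f QALYs\n",
              mean(x$draws$delta_cost), mean(x$draws$delta_effect)))
  cat(sprintf("  acceptability at %s CNY/QALY: %.3f\n",
              format(x$wtp, big.mark = ","), x$acceptability))
  invisible(x)
}
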