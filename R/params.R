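#' @keywords internal
"_PACKAGE"

# Health-state labels used throughout the package. Diagnosed invasive
# stages follow TNM staging; DCIS is stage 0 (in situ).
STAGES <- c("DCIS", "I", "II", "III", "IV")
STATES <- c("Healthy", "DCIS", "I", "II", "III", "IV",
            "Death_BC", "Death_Other")

range_val <- function(base, low = base, high = base) {
  c(base = base, low = low, high = high)
}

#' Base-case model parameters
#'
#' Returns the packaged base-case parameter set for the cost-utility
#' model: annual stage-progression and stage-specific breast-cancer
#' mortality probabilities, age-specific incidence and all-cause /
#' breast-cancer / other-cause mortality, stage distributions at
#' diagnosis for screen-detected and clinically detected cancers,
#' screening and treatment unit costs (CNY, 2023 values), health-state
#' utilities, test sensitivity/specificity of the combined
#' (CBE+BUS)+MAM pathway, and economic settings (3\% annual discount
#' rate, willingness-to-pay thresholds of 1x and 3x the Shenzhen per
#' capita GDP, a closed cohort of 100,000 women entering at age 35 and
#' followed for 50 annual cycles).
#'
#' Two triage fractions are part of the screening-cost model:
#' \code{f_mam}, the fraction of screened women triaged to
#' supplementary mammography (BI-RADS 0/III, 0.229), and
#' \code{f_referral_pos}, the fraction referred BI-RADS IV+ (0.023).
#'
#' @return An object of class \code{bc_params}: a named list with
#'   components \code{progression}, \code{incidence}, \code{mortality},
#'   \code{stage_screen}, \code{stage_clinical}, \code{screening_costs},
#'   \code{stage_costs}, \code{utilities}, \code{test} and \code{econ}.
#' @seealso [validate_parameters()], [load_parameters()],
#'   [write_parameters()]
#' @examples
#' p <- default_parameters()
#' p$progression$p_III_IV     # 0.21
#' p$utilities[["IV"]]        # 0.3
#' @export
default_parameters <- function() {
  progression <- list(
    p_I_II   = 0.06,
    p_II_III = 0.11,
    p_I_IV   = 0.01,
    p_II_IV  = 0.08,
    p_III_IV = 0.21,
    mort = c(I = 0.002, II = 0.016, III = 0.039, IV = 0.2331),
    rr_dcis = 2.02
  )

  incidence <- data.frame(
    age_lower = c(35, 40, 45, 50, 55, 60, 65, 70, 75, 80),
    age_upper = c(39, 44, 49, 54, 59, 64, 69, 74, 79, Inf),
    lambda = c(0.000342, 0.000648, 0.000857, 0.001052, 0.001077,
               0.001086, 0.000987, 0.000925, 0.000834, 0.000637)
  )

  mortality <- data.frame(
    age_lower = c(35, 40, 45, 50, 55, 60, 65, 70, 75, 80, 85),
    age_upper = c(39, 44, 49, 54, 59, 64, 69, 74, 79, 84, Inf),
    mu_all = c(0.00052, 0.0008, 0.00125, 0.00178, 0.00331, 0.00506,
               0.0088, 0.01581, 0.02955, 0.05208, 0.17321),
    mu_bc = c(3.76e-05, 5.26e-05, 8.33e-05, 0.000113, 0.000162,
              0.000184, 0.000228, 0.000231, 0.000265, 0.000376,
              0.000562),
    # top band: the printed other-cause value (0.172646) differs from
    # mu_all - mu_bc by 2e-6; the derived value is stored so the
    # decomposition invariant holds exactly
    mu_other = c(0.000482, 0.000747, 0.001167, 0.001667, 0.003148,
                 0.004876, 0.008572, 0.015579, 0.029285, 0.051704,
                 0.172648)
  )

  stage_screen <- c(DCIS = 0.1119, I = 0.3785, II = 0.3881,
                    III = 0.1008, IV = 0.0207)
  stage_clinical <- c(DCIS = 0.0588, I = 0.2652, II = 0.457,
                      III = 0.1529, IV = 0.0661)

  screening_costs <- list(
    c_cbe = 33, c_mam = 249.33, c_us = 120, c_biopsy = 184,
    f_mam = 0.229, f_referral_pos = 0.023
  )

  # Per-stage costs (CNY): one-time treatment cost at diagnosis, by
  # detection mode; recurring annual outpatient cost; one-time direct
  # non-medical cost. Printed (low-high) ranges retained for DSA/PSA.
  stage_costs <- list(
    DCIS = list(
      c_treat_screen   = range_val(11432, 7089, 13186),
      c_treat_noscreen = range_val(13129, 5742, 19196),
      c_outpatient     = range_val(2710, 739, 6160),
      c_nonmedical     = range_val(18108, 3942, 34626)
    ),
    I = list(
      c_treat_screen   = range_val(13545, 12758, 15751),
      c_treat_noscreen = range_val(18103, 13730, 23692),
      c_outpatient     = range_val(4466, 2242, 29262),
      c_nonmedical     = range_val(12587, 2562, 26248)
    ),
    II = list(
      c_treat_screen   = range_val(13104, 11499, 14992),
      c_treat_noscreen = range_val(19798, 14785, 27026),
      c_outpatient     = range_val(5113, 1249, 23595),
      c_nonmedical     = range_val(8497, 2464, 26140)
    ),
    III = list(
      c_treat_screen   = range_val(14397, 12774, 16019),
      c_treat_noscreen = range_val(21138, 16485, 26791),
      c_outpatient     = range_val(3696, 961, 44356),
      c_nonmedical     = range_val(6637, 492, 26090)
    ),
    IV = list(
      c_treat_screen   = range_val(13292, 8990, 17593),
      c_treat_noscreen = range_val(29174, 15092, 37069),
      c_outpatient     = range_val(4928, 1971, 55445),
      c_nonmedical     = range_val(11491, 3696, 15637)
    )
  )

  utilities <- c(Healthy = 1, DCIS = 0.95, I = 0.9, II = 0.8,
                 III = 0.7, IV = 0.3)

  test <- list(
    sensitivity = range_val(0.851, 0.758, 0.944),
    specificity = range_val(0.967, 0.963, 0.971)
  )

  econ <- list(
    discount_rate = 0.03,
    gdp_per_capita = 179000,
    wtp_1x = 179000,
    wtp_3x = 537000,
    cohort_size = 100000,
    start_age = 35,
    n_cycles = 50
  )

  structure(
    list(progression = progression, incidence = incidence,
         mortality = mortality, stage_screen = stage_screen,
         stage_clinical = stage_clinical,
         screening_costs = screening_costs, stage_costs = stage_costs,
         utilities = utilities, test = test, econ = econ),
    class = "bc_params"
  )
}

#' Look up an age-banded table value
#'
#' Maps an integer age to the band with \code{age_lower <= age <=
#' age_upper} (top band may be open-ended with \code{age_upper = Inf}).
#'
#' @param table data frame with \code{age_lower}, \code{age_upper} and
#'   one or more value columns.
#' @param age integer age in years.
#' @param column value column name.
#' @return The value for the band containing \code{age}.
#' @export
age_lookup <- function(table, age, column) {
  i <- which(table$age_lower <= age & age <= table$age_upper)
  if (length(i) != 1L)
    stop("age ", age, " is not covered by exactly one band", call. = FALSE)
  table[[column]][i]
}

check <- function(violations, ok, msg) {
  if (!ok) c(violations, msg) else violations
}

check_prob <- function(violations, x, name) {
  bad <- !is.finite(x) | x < 0 | x > 1
  if (any(bad))
    violations <- c(violations, sprintf(
      "%s = %s out of [0,1]", name, paste(x[bad], collapse = ", ")))
  violations
}

check_range <- function(violations, rv, name) {
  if (!all(c("base", "low", "high") %in% names(rv))) {
    return(c(violations, sprintf("%s lacks base/low/high", name)))
  }
  if (any(rv < 0))
    violations <- c(violations, sprintf("%s negative", name))
  if (!(rv[["low"]] <= rv[["base"]] && rv[["base"]] <= rv[["high"]]))
    violations <- c(violations, sprintf(
      "%s violates low <= base <= high (%g, %g, %g)",
      name, rv[["low"]], rv[["base"]], rv[["high"]]))
  violations
}

check_bands <- function(violations, tab, name, lo = 35, hi = 85) {
  if (any(tab$age_lower > tab$age_upper))
    violations <- c(violations, sprintf("%s: band with lower > upper", name))
  for (a in lo:hi) {
    n <- sum(tab$age_lower <= a & a <= tab$age_upper)
    if (n != 1L) {
      violations <- c(violations, sprintf(
        "%s: age %d covered by %d bands (expected 1)", name, a, n))
      break
    }
  }
  violations
}

#' Validate a parameter set
#'
#' Checks every structural invariant of the model inputs: probabilities
#' in \eqn{[0,1]}, per-stage outgoing probability mass at most 1,
#' age bands non-overlapping and covering ages 35-85, other-cause
#' mortality equal to all-cause minus breast-cancer mortality (within
#' 1e-6), stage distributions summing to 1, non-negative costs with
#' \code{low <= base <= high}, utilities in \eqn{[0,1]} with healthy
#' utility 1, and consistent economic settings.
#'
#' @param params a \code{bc_params} object.
#' @return Character vector of violation descriptions; empty when the
#'   parameter set is valid. Reporting, not raising: callers that need
#'   an error use [assert_valid_parameters()].
#' @export
validate_parameters <- function(params) {
  v <- character()
  pr <- params$progression
  for (nm in c("p_I_II", "p_II_III", "p_I_IV", "p_II_IV", "p_III_IV"))
    v <- check_prob(v, pr[[nm]], paste0("progression.", nm))
  v <- check_prob(v, pr$mort, paste0("progression.mort.", names(pr$mort)))
  v <- check(v, pr$rr_dcis > 0, "progression.rr_dcis must be > 0")
  # outgoing mass per diagnosed stage (worst-case other-cause mortality)
  mu_max <- max(params$mortality$mu_other)
  out <- c(
    I   = pr$p_I_II + pr$p_I_IV + pr$mort[["I"]],
    II  = pr$p_II_III + pr$p_II_IV + pr$mort[["II"]],
    III = pr$p_III_IV + pr$mort[["III"]],
    IV  = pr$mort[["IV"]]
  ) + mu_max
  for (s in names(out))
    v <- check(v, out[[s]] <= 1, sprintf(
      "stage %s: outgoing probability mass %.4f exceeds 1", s, out[[s]]))

  v <- check_bands(v, params$incidence, "incidence")
  v <- check_prob(v, params$incidence$lambda, "incidence.lambda")
  v <- check_bands(v, params$mortality, "mortality")
  mt <- params$mortality
  for (col in c("mu_all", "mu_bc", "mu_other"))
    v <- check_prob(v, mt[[col]], paste0("mortality.", col))
  bad <- abs(mt$mu_other - (mt$mu_all - mt$mu_bc)) > 1e-6
  if (any(bad))
    v <- c(v, sprintf(
      "mortality band %g-%g: mu_other = %g differs from mu_all - mu_bc = %g",
      mt$age_lower[bad], mt$age_upper[bad], mt$mu_other[bad],
      (mt$mu_all - mt$mu_bc)[bad]))

  for (nm in c("stage_screen", "stage_clinical")) {
    sh <- params[[nm]]
    v <- check(v, identical(names(sh), STAGES),
               sprintf("%s must be named over %s", nm,
                       paste(STAGES, collapse = ", ")))
    v <- check(v, all(sh >= 0), sprintf("%s has negative shares", nm))
    v <- check(v, abs(sum(sh) - 1) <= 1e-6,
               sprintf("%s shares sum to %.6f, not 1", nm, sum(sh)))
  }

  sc <- params$screening_costs
  for (nm in c("c_cbe", "c_mam", "c_us", "c_biopsy"))
    v <- check(v, sc[[nm]] >= 0, sprintf("screening_costs.%s negative", nm))
  for (nm in c("f_mam", "f_referral_pos"))
    v <- check_prob(v, sc[[nm]], paste0("screening_costs.", nm))

  for (s in STAGES)
    for (nm in names(params$stage_costs[[s]]))
      v <- check_range(v, params$stage_costs[[s]][[nm]],
                       sprintf("stage_costs.%s.%s", s, nm))

  u <- params$utilities
  v <- check(v, identical(names(u), c("Healthy", STAGES)),
             "utilities must be named Healthy, DCIS, I, II, III, IV")
  for (nm in names(u))
    v <- check_prob(v, u[[nm]], paste0("utility out of [0,1]: utilities.", nm))
  v <- check(v, isTRUE(u[["Healthy"]] == 1), "utilities.Healthy must equal 1")

  for (nm in c("sensitivity", "specificity")) {
    v <- check_range(v, params$test[[nm]], paste0("test.", nm))
    v <- check_prob(v, params$test[[nm]], paste0("test.", nm))
  }

  ec <- params$econ
  v <- check(v, ec$discount_rate >= 0 && ec$discount_rate < 1,
             "econ.discount_rate must be in [0,1)")
  v <- check(v, abs(ec$wtp_3x - 3 * ec$gdp_per_capita) < 1e-6,
             "econ.wtp_3x must equal 3 * gdp_per_capita")
  v <- check(v, ec$n_cycles >= 1, "econ.n_cycles must be >= 1")
  v <- check(v, ec$cohort_size > 0, "econ.cohort_size must be positive")
  v
}

#' Stop on an invalid parameter set
#'
#' @param params a \code{bc_params} object.
#' @return \code{params}, invisibly, when valid.
#' @export
assert_valid_parameters <- function(params) {
  v <- validate_parameters(params)
  if (length(v))
    stop("invalid parameter set:\n  ", paste(v, collapse = "\n  "),
         call. = FALSE)
  invisible(params)
}

# ---- config I/O -----------------------------------------------------------

df_to_list <- function(df) lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))

list_to_df <- function(rows) {
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}

params_to_list <- function(params) {
  x <- unclass(params)
  x$incidence <- df_to_list(x$incidence)
  x$mortality <- df_to_list(x$mortality)
  x$progression$mort <- as.list(x$progression$mort)
  x$stage_screen <- as.list(x$stage_screen)
  x$stage_clinical <- as.list(x$stage_clinical)
  x$utilities <- as.list(x$utilities)
  x$stage_costs <- lapply(x$stage_costs, function(s) lapply(s, as.list))
  x$test <- lapply(x$test, as.list)
  x
}

#' Write a parameter set to a YAML config file
#'
#' @param params a \code{bc_params} object.
#' @param path file path to write.
#' @return \code{path}, invisibly.
#' @export
write_parameters <- function(params, path) {
  yaml::write_yaml(params_to_list(params), path, precision = 12L)
  invisible(path)
}

as_range <- function(x, name) {
  x <- unlist(x)
  if (is.null(names(x)) || !"base" %in% names(x)) {
    if (length(x) == 1L) x <- c(base = x[[1]])
    else stop("configuration error: field '", name,
              "' must name base/low/high", call. = FALSE)
  }
  range_val(x[["base"]],
            if ("low" %in% names(x)) x[["low"]] else x[["base"]],
            if ("high" %in% names(x)) x[["high"]] else x[["base"]])
}

merge_config <- function(base, override, path = character()) {
  for (nm in names(override)) {
    here <- c(path, nm)
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.data.frame(base[[nm]]) && !is.data.frame(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]], here)
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a parameter set from a config file or list
#'
#' Reads a YAML (or pre-parsed list) configuration whose sections mirror
#' the components of [default_parameters()]. Missing fields fall back to
#' the packaged base-case defaults; the result is validated before it is
#' returned. Age-banded tables (\code{incidence}, \code{mortality}) may
#' be given inline as row lists or as a path to a CSV file with columns
#' \code{age_lower}, \code{age_upper} and the value column(s); an
#' open-ended top band uses \code{Inf} (or the string \code{".inf"} in
#' YAML) as \code{age_upper}.
#'
#' @param config_source path to a YAML file, or a named list.
#' @return A validated \code{bc_params} object.
#' @export
load_parameters <- function(config_source) {
  if (is.character(config_source)) {
    if (!file.exists(config_source))
      stop("configuration error: file not found: ", config_source,
           call. = FALSE)
    cfg <- yaml::read_yaml(config_source)
  } else if (is.list(config_source)) {
    cfg <- config_source
  } else {
    stop("configuration error: config_source must be a path or a list",
         call. = FALSE)
  }
  known <- names(default_parameters())
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("configuration error: unknown section(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)

  for (tab in c("incidence", "mortality")) {
    if (is.character(cfg[[tab]]) && length(cfg[[tab]]) == 1L) {
      if (!file.exists(cfg[[tab]]))
        stop("configuration error: field '", tab, "' references missing file ",
             cfg[[tab]], call. = FALSE)
      cfg[[tab]] <- utils::read.csv(cfg[[tab]])
    } else if (is.list(cfg[[tab]]) && !is.data.frame(cfg[[tab]])) {
      cfg[[tab]] <- list_to_df(cfg[[tab]])
    }
  }

  base <- params_to_list(default_parameters())
  merged <- merge_config(base, cfg)

  p <- merged
  p$incidence <- if (is.data.frame(merged$incidence)) merged$incidence
                 else list_to_df(merged$incidence)
  p$mortality <- if (is.data.frame(merged$mortality)) merged$mortality
                 else list_to_df(merged$mortality)
  p$incidence$age_upper <- as.numeric(p$incidence$age_upper)
  p$mortality$age_upper <- as.numeric(p$mortality$age_upper)
  p$progression$mort <- unlist(p$progression$mort)[c("I", "II", "III", "IV")]
  p$stage_screen <- unlist(p$stage_screen)[STAGES]
  p$stage_clinical <- unlist(p$stage_clinical)[STAGES]
  p$utilities <- unlist(p$utilities)[c("Healthy", STAGES)]
  p$stage_costs <- lapply(stats::setNames(STAGES, STAGES), function(s) {
    lapply(stats::setNames(names(p$stage_costs[[s]]),
                           names(p$stage_costs[[s]])), function(nm)
      as_range(p$stage_costs[[s]][[nm]],
               sprintf("stage_costs.%s.%s", s, nm)))
  })
  p$test <- lapply(stats::setNames(names(p$test), names(p$test)),
                   function(nm) as_range(p$test[[nm]], paste0("test.", nm)))
  required <- c("progression", "incidence", "mortality", "stage_screen",
                "stage_clinical", "screening_costs", "stage_costs",
                "utilities", "test", "econ")
  missing <- required[vapply(p[required], is.null, logical(1))]
  if (length(missing))
    stop("configuration error: missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  params <- structure(p[required], class = "bc_params")
  viol <- validate_parameters(params)
  if (length(viol))
    stop("validation error:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  params
}

#' Read a parameter value by path
#'
#' Paths are dot-separated routes into the parameter set, e.g.
#' \code{"econ.discount_rate"}, \code{"utilities.IV"},
#' \code{"stage_costs.IV.c_outpatient"}, \code{"test.sensitivity"}.
#' For ranged costs and test performance the base value is returned.
#'
#' @param params a \code{bc_params} object.
#' @param path dot-separated parameter identifier.
#' @return The (base) numeric value at \code{path}.
#' @export
param_get <- function(params, path) {
  node <- params
  for (key in strsplit(path, ".", fixed = TRUE)[[1]]) {
    if (is.null(node[[key]]))
      stop("unknown parameter identifier: ", path, call. = FALSE)
    node <- node[[key]]
  }
  if (is.numeric(node) && "base" %in% names(node)) return(node[["base"]])
  if (!is.numeric(node) || length(node) != 1L)
    stop("parameter identifier does not resolve to a scalar: ", path,
         call. = FALSE)
  node
}

#' Set a parameter value by path
#'
#' The counterpart of [param_get()]; used by the sensitivity analyses to
#' perturb one input at a time. For ranged entries the base value is
#' replaced; if the new base falls outside the stored (low, high) range
#' - as probabilistic draws legitimately can - the range is widened to
#' contain it, so the set stays structurally valid.
#'
#' @param params a \code{bc_params} object.
#' @param path dot-separated parameter identifier.
#' @param value new numeric value.
#' @return The modified \code{bc_params} object.
#' @export
param_set <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  param_get(params, path)  # errors on unknown identifiers
  set_rec <- function(node, keys) {
    k <- keys[[1]]
    if (length(keys) == 1L) {
      if (is.numeric(node[[k]]) && "base" %in% names(node[[k]])) {
        node[[k]][["base"]] <- value
        node[[k]][["low"]] <- min(node[[k]][["low"]], value)
        node[[k]][["high"]] <- max(node[[k]][["high"]], value)
      } else {
        node[[k]] <- value
      }
    } else {
      node[[k]] <- set_rec(node[[k]], keys[-1])
    }
    node
  }
  out <- set_rec(unclass(params), keys)
  structure(out, class = "bc_params")
}

#' @export
print.bc_params <- function(x, ...) {
  cat("<bc_params> breast-cancer screening model parameters\n")
  cat("  cohort:", x$econ$cohort_size, "women, start age",
      x$econ$start_age, ",", x$econ$n_cycles, "annual cycles\n")
  cat("  discount rate:", x$econ$discount_rate,
      "| WTP:", x$econ$wtp_1x, "/", x$econ$wtp_3x, "CNY per QALY\n")
  cat("  test: Se", x$test$sensitivity[["base"]],
      "Sp", x$test$specificity[["base"]], "\n")
  v <- validate_parameters(x)
  cat("  validation:", if (length(v)) paste(length(v), "violation(s)")
      else "ok", "\n")
  invisible(x)
}
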