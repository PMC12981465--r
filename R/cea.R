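#' Incremental cost-utility ratio
#'
#' Extra cost per extra QALY of an alternative over a reference:
#' \eqn{(C_a - C_r) / (E_a - E_r)} in CNY per QALY.
#'
#' @param reference,alternative one-row CE-point data frames (or lists)
#'   with \code{cost} and \code{effect}.
#' @return ICUR in CNY per QALY.
#' @export
icur <- function(reference, alternative) {
  de <- alternative$effect - reference$effect
  if (de == 0)
    stop("undefined ICUR: strategies have equal effects", call. = FALSE)
  (alternative$cost - reference$cost) / de
}

#' Dominance analysis and cost-effectiveness frontier
#'
#' Classifies a set of CE points by dominance and builds the
#' cost-effectiveness frontier: (1) sort by effect ascending (ties:
#' cheaper first, then label); (2) drop strictly dominated points
#' (another point with at least the effect for at most the cost, one
#' strictly better); (3) iteratively drop extended-dominated points
#' (a point whose ICUR over its frontier predecessor exceeds the ICUR
#' of the next frontier point over itself) until sequential ICURs are
#' strictly increasing; (4) compute sequential ICURs along the
#' frontier.
#'
#' Points with identical cost and effect are duplicates: the
#' lexicographically first label is kept on the frontier, the rest are
#' marked strictly dominated.
#'
#' @param points data frame of CE points with columns \code{label},
#'   \code{cost}, \code{effect} (one row per strategy).
#' @return A \code{bc_frontier}: the input rows (sorted by effect) with
#'   columns \code{on_frontier}, \code{dominance} (\code{"none"},
#'   \code{"strict"} or \code{"extended"}), \code{comparator} (label of
#'   the next-less-effective frontier member) and \code{icur}
#'   (sequential; \code{NA} for the cheapest frontier member).
#' @export
frontier <- function(points) {
  stopifnot(is.data.frame(points), nrow(points) >= 1,
            all(c("label", "cost", "effect") %in% names(points)))
  pts <- points[order(points$effect, points$cost, points$label), ,
                drop = FALSE]
  rownames(pts) <- NULL
  n <- nrow(pts)
  dominance <- rep("none", n)

  # strict dominance (duplicates: first label survives)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ge_eff <- pts$effect[j] >= pts$effect[i]
      le_cost <- pts$cost[j] <= pts$cost[i]
      strict <- pts$effect[j] > pts$effect[i] || pts$cost[j] < pts$cost[i]
      dup_first <- pts$effect[j] == pts$effect[i] &&
        pts$cost[j] == pts$cost[i] && pts$label[j] < pts$label[i]
      if ((ge_eff && le_cost && strict) || dup_first) {
        dominance[i] <- "strict"
        break
      }
    }
  }

  cand <- which(dominance == "none")
  # extended dominance: prune until sequential ICURs strictly increase
  repeat {
    if (length(cand) <= 2) break
    ic <- diff(pts$cost[cand]) / diff(pts$effect[cand])
    bad <- which(ic[-length(ic)] >= ic[-1])
    if (!length(bad)) break
    drop <- cand[bad[1] + 1L]
    dominance[drop] <- "extended"
    cand <- setdiff(cand, drop)
  }

  pts$on_frontier <- dominance == "none"
  pts$dominance <- dominance
  pts$comparator <- NA_character_
  pts$icur <- NA_real_
  if (length(cand) > 1) {
    for (k in 2:length(cand)) {
      i <- cand[k]; prev <- cand[k - 1]
      pts$comparator[i] <- pts$label[prev]
      pts$icur[i] <- (pts$cost[i] - pts$cost[prev]) /
        (pts$effect[i] - pts$effect[prev])
    }
    ic <- pts$icur[cand[-1]]
    stopifnot(all(diff(ic) > 0))  # frontier ICURs strictly increasing
  }
  structure(pts, class = c("bc_frontier", "data.frame"))
}

#' Classify an ICUR against willingness-to-pay thresholds
#'
#' Below one times per-capita GDP per QALY: highly cost-effective;
#' below three times: cost-effective; otherwise not cost-effective.
#'
#' @param icur_value ICUR in CNY per QALY (finite).
#' @param econ economic settings (\code{wtp_1x}, \code{wtp_3x}), e.g.
#'   \code{default_parameters()$econ}.
#' @return List with \code{category} (one of
#'   \code{"highly_cost_effective"}, \code{"cost_effective"},
#'   \code{"not_cost_effective"}) and the thresholds used.
#' @export
classify_icur <- function(icur_value, econ = default_parameters()$econ) {
  stopifnot(is.finite(icur_value))
  category <- if (icur_value < econ$wtp_1x) "highly_cost_effective"
  else if (icur_value < econ$wtp_3x) "cost_effective"
  else "not_cost_effective"
  list(category = category, wtp_1x = econ$wtp_1x, wtp_3x = econ$wtp_3x)
}

#' Strategy rankings table
#'
#' The full cost-effectiveness ranking of a strategy set: per-strategy
#' discounted cost and QALYs, incremental cost and QALYs along the
#' frontier, sequential ICURs, dominance status and WTP category.
#'
#' @param points data frame of CE points (label, cost, effect).
#' @param econ economic settings for the WTP classification.
#' @return Data frame sorted by effect with incremental columns and a
#'   \code{wtp_category} for frontier members with a defined ICUR.
#' @export
rankings_table <- function(points, econ = default_parameters()$econ) {
  fr <- frontier(points)
  out <- as.data.frame(fr)
  out$incremental_cost <- NA_real_
  out$incremental_effect <- NA_real_
  idx <- which(out$on_frontier)
  if (length(idx) > 1) {
    for (k in 2:length(idx)) {
      i <- idx[k]; prev <- idx[k - 1]
      out$incremental_cost[i] <- out$cost[i] - out$cost[prev]
      out$incremental_effect[i] <- out$effect[i] - out$effect[prev]
    }
  }
  out$wtp_category <- vapply(out$icur, function(x)
    if (is.na(x)) NA_character_ else classify_icur(x, econ)$category,
    character(1))
  out
}

#' @export
print.bc_frontier <- function(x, ...) {
  cat("<bc_frontier>", sum(x$on_frontier), "of", nrow(x),
      "strategies on the cost-effectiveness frontier\n")
  on <- x[x$on_frontier, c("label", "cost", "effect", "icur")]
  print(as.data.frame(on), row.names = FALSE, digits = 7)
  invisible(x)
}
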