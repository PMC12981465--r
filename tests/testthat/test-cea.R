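ce <- function(label, cost, effect)
  data.frame(label = label, cost = cost, effect = effect)

test_that("pairwise ICUR is the incremental cost per incremental QALY", {
  expect_equal(icur(ce("a", 0, 24.0), ce("b", 1000, 24.01)), 100000)
  expect_equal(icur(ce("a", 500, 24.0), ce("b", 250, 24.01)), -25000)
  expect_error(icur(ce("a", 0, 24.0), ce("b", 1000, 24.0)), "equal effects")
})

test_that("frontier removes strict and extended dominance and orders ICURs", {
  pts <- rbind(ce("A", 0, 24.000), ce("B", 1000, 24.010),
               ce("C", 5000, 24.015), ce("D", 3000, 24.012))
  fr <- frontier(pts)
  expect_equal(fr$label[fr$on_frontier], c("A", "B", "C"))
  expect_equal(fr$dominance[fr$label == "D"], "extended")
  expect_equal(fr$icur[fr$label == "B"], 100000)
  expect_equal(fr$icur[fr$label == "C"], 800000)
  expect_equal(fr$comparator[fr$label == "C"], "B")
  expect_true(is.na(fr$icur[fr$label == "A"]))

  # singleton set
  one <- frontier(ce("only", 100, 1))
  expect_true(one$on_frontier)
  expect_true(is.na(one$icur))

  # strict dominance: worse on both axes
  pts2 <- rbind(ce("cheap", 10, 2), ce("bad", 20, 1))
  fr2 <- frontier(pts2)
  expect_equal(fr2$dominance[fr2$label == "bad"], "strict")

  # ties: equal effect keeps the cheaper; duplicates keep first label
  pts3 <- rbind(ce("x", 10, 1), ce("y", 5, 1), ce("y2", 5, 1))
  fr3 <- frontier(pts3)
  expect_equal(fr3$label[fr3$on_frontier], "y")
})

test_that("frontier membership matches brute-force dominance on random sets", {
  set.seed(20240915)
  for (rep in 1:40) {
    n <- sample(2:8, 1)
    pts <- ce(sprintf("s%02d", seq_len(n)),
              cost = round(runif(n, 0, 1000), 1),
              effect = round(runif(n, 0, 10), 2))
    fr <- frontier(pts)
    expect_equal(sort(fr$label[fr$on_frontier]),
                 oracle_frontier_members(pts),
                 info = paste("rep", rep))
    # ICURs strictly increase along the frontier
    ic <- fr$icur[fr$on_frontier]
    ic <- ic[!is.na(ic)]
    if (length(ic) > 1) expect_true(all(diff(ic) > 0))
    # permutation invariance
    perm <- pts[sample(n), ]
    fr_perm <- frontier(perm)
    expect_equal(fr_perm$label[fr_perm$on_frontier],
                 fr$label[fr$on_frontier])
    # idempotence on the frontier members
    members <- as.data.frame(fr[fr$on_frontier,
                                c("label", "cost", "effect")])
    fr2 <- frontier(members)
    expect_true(all(fr2$on_frontier))
    expect_equal(fr2$icur, fr$icur[fr$on_frontier])
  }
})

test_that("willingness-to-pay classification uses the GDP thresholds", {
  econ <- default_parameters()$econ
  expect_equal(classify_icur(140915, econ)$category, "highly_cost_effective")
  expect_equal(classify_icur(518120.51, econ)$category, "cost_effective")
  expect_equal(classify_icur(649251.82, econ)$category, "not_cost_effective")
  expect_equal(classify_icur(179000, econ)$category, "cost_effective")
})

test_that("rankings table reports incremental columns for frontier members", {
  pts <- rbind(ce("A", 0, 24.000), ce("B", 1000, 24.010),
               ce("C", 5000, 24.015))
  rk <- rankings_table(pts)
  expect_equal(nrow(rk), 3)
  expect_equal(rk$incremental_cost[rk$label == "B"], 1000)
  expect_equal(rk$incremental_effect[rk$label == "C"], 0.005)
  expect_equal(rk$wtp_category[rk$label == "B"], "highly_cost_effective")
  expect_equal(rk$wtp_category[rk$label == "C"], "not_cost_effective")
})
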