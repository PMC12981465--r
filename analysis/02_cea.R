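#!/usr/bin/env Rscript

# Cost-utility analysis of the 27-strategy design space.
#
# Runs the Markov cohort model for every screening strategy (starts
# 35/40/45, stops 65/69/74, intervals 1/2/3 years) plus the
# no-screening comparator, ranks them, prunes dominated strategies and
# reports the cost-effectiveness frontier with sequential ICURs and
# willingness-to-pay verdicts.

suppressMessages(library(bcscreen))
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

params <- default_parameters()
points <- run_strategy_set(params)
rankings <- rankings_table(points, params$econ)
write.csv(rankings, file.path(out_dir, "cea_rankings.csv"),
          row.names = FALSE)

fr <- frontier(points)
write.csv(as.data.frame(fr), file.path(out_dir, "cea_frontier.csv"),
          row.names = FALSE)

cat("== Cost-utility analysis, base case ==\n")
cur <- points[points$label == "(CBE+BUS)+MAM/2year/35_65", ]
alt <- points[points$label == "(CBE+BUS)+MAM/3year/45_65", ]
none <- points[points$label == "no screening", ]
cat(sprintf("Current programme (2year/35_65): %.2f CNY, %.4f QALYs per person\n",
            cur$cost, cur$effect))
cat(sprintf("ICUR vs no screening: %.0f CNY/QALY (%s)\n",
            icur(none, cur),
            classify_icur(icur(none, cur), params$econ)$category))
cat(sprintf("ICUR vs 3year/45_65: %.0f CNY/QALY (%s)\n",
            icur(alt, cur),
            classify_icur(icur(alt, cur), params$econ)$category))
cat("\n")
print(fr)

# CE plane with the frontier highlighted
if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  d <- as.data.frame(fr)
  gg <- ggplot(d, aes(effect, cost)) +
    geom_point(aes(colour = on_frontier)) +
    geom_line(data = d[d$on_frontier, ], linetype = 2) +
    scale_colour_manual(values = c(`TRUE` = "#1b7837",
                                   `FALSE` = "grey55"),
                        labels = c(`TRUE` = "undominated",
                                   `FALSE` = "dominated"),
                        name = NULL) +
    labs(x = "Discounted QALYs per person",
         y = "Discounted cost per person (CNY)",
         title = "Cost-effectiveness plane, 27 strategies + no screening") +
    theme_minimal()
  ggsave(file.path(out_dir, "cea_plane.png"), gg, width = 7, height = 5,
         dpi = 150)
  cat("\nFigure written to", file.path(out_dir, "cea_plane.png"), "\n")
}
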