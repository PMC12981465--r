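#!/usr/bin/env Rscript

# One-way (tornado) deterministic sensitivity analysis.
#
# Varies each model input over its range - printed ranges for stage
# costs and test performance, conventional ranges elsewhere (discount
# rate 0-5%, screening unit costs +/-20%, utilities +/-10%) - and
# records the ICUR at both ends, for the current biennial 35-65
# programme against no screening and against the triennial 45-65
# alternative.

suppressMessages(library(bcscreen))
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

params <- default_parameters()
pairs <- list(
  vs_no_screening = list(no_screening(), screening_strategy(35, 65, 2)),
  vs_3year_45_65 = list(screening_strategy(45, 65, 3),
                        screening_strategy(35, 65, 2))
)

for (nm in names(pairs)) {
  tor <- tornado(params, strategy_pair = pairs[[nm]])
  write.csv(tor, file.path(out_dir, paste0("tornado_", nm, ".csv")),
            row.names = FALSE)
  cat(sprintf("== Tornado: 2year/35_65 %s (base ICUR %.0f CNY/QALY) ==\n",
              gsub("_", " ", nm), attr(tor, "icur_base")))
  print(utils::head(tor, 8), row.names = FALSE)
  cat(sprintf("Widest swing: %s. All one-way ICURs below 537,000: %s\n\n",
              tor$param[1],
              all(tor$icur_at_low < 537000 & tor$icur_at_high < 537000)))

  if (requireNamespace("ggplot2", quietly = TRUE)) {
    library(ggplot2)
    top <- utils::head(tor, 12)
    top$param <- factor(top$param, levels = rev(top$param))
    gg <- ggplot(top) +
      geom_segment(aes(x = icur_at_low, xend = icur_at_high,
                       y = param, yend = param), linewidth = 4,
                   colour = "#2166ac") +
      geom_vline(xintercept = attr(tor, "icur_base"), linetype = 2) +
      labs(x = "ICUR (CNY/QALY)", y = NULL,
           title = paste("One-way sensitivity,", gsub("_", " ", nm))) +
      theme_minimal()
    ggsave(file.path(out_dir, paste0("tornado_", nm, ".png")), gg,
           width = 7, height = 5, dpi = 150)
  }
}
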