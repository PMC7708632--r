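#!/usr/bin/env Rscript
# Filter and normalize the RAD21-mClover-like degradation traces, estimate
# the non-responder fraction and the decay half-life. Reads results/data/,
# writes results/kinetics/.

suppressPackageStartupMessages({library(nucarch); library(ggplot2)})
out <- "results/kinetics"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

traces <- read_traces("results/data/rad21_traces.csv")
res <- filter_and_normalize_traces(traces, min_start = 50, window = 5,
                                   quantile = 0.90)
write.csv(res$traces, file.path(out, "normalized_traces.csv"), row.names = FALSE)
write.csv(res$exclusions, file.path(out, "exclusions.csv"), row.names = FALSE)
cat(sprintf("retained %d cells; excluded %d (start <= 50 counts: %d, fluctuation: %d)\n",
            length(unique(res$traces$cell_id)), nrow(res$exclusions),
            sum(res$exclusions$reason == "start_below_min"),
            sum(res$exclusions$reason == "fluctuation_above_quantile")))

finals <- vapply(split(res$traces, res$traces$cell_id),
                 function(df) df$normalized[which.max(df$t_index)], numeric(1))
nonresp <- mean(finals > 0.5)
cat(sprintf("non-responder fraction (final level > 0.5 of start): %.1f%%\n",
            100 * nonresp))

responders <- res$traces[res$traces$cell_id %in%
                           names(finals)[finals <= 0.5], ]
# half-life from the responder median trace: t at which the median crosses 1/2
med <- aggregate(normalized ~ t_index, responders, median)
t_half <- approx(med$normalized, med$t_index * 15, xout = 0.5)$y
cat(sprintf("estimated decay half-life: %.0f min (planted 35 min)\n", t_half))

p <- ggplot(res$traces, aes(t_index * 15, normalized, group = cell_id)) +
  geom_line(alpha = 0.15) +
  geom_line(data = transform(med, cell_id = 0), color = "red", linewidth = 1) +
  labs(x = "time after auxin (min)", y = "normalized intensity") +
  theme_minimal()
ggsave(file.path(out, "traces.png"), p, width = 6, height = 4, dpi = 120)
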