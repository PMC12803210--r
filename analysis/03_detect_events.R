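#!/usr/bin/env Rscript
# Detect calcium events on every dF/F0 recording (local maxima exceeding 20%
# dF/F0, minimum inter-peak distance 1 frame) and summarize per-neuron event
# frequency and mean peak amplitude.

suppressPackageStartupMessages(library(syncburst))

in_dir <- "results/dff"
out_dir <- "results/events"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

dff_files <- list.files(in_dir, pattern = "_dff\\.csv$", full.names = TRUE)
stopifnot(length(dff_files) > 0)

all_summaries <- list()
for (f in dff_files) {
  rec <- sub("_dff\\.csv$", "", basename(f))
  dff <- read_traces(f)
  ev <- detect_events(dff, threshold_dff = 0.20, min_distance_frames = 1)
  write_events(ev, file.path(out_dir, sprintf("%s_events.csv", rec)))
  ns <- summarize_neurons(ev)
  ns$recording <- rec
  all_summaries[[rec]] <- ns
  cat(sprintf("%-26s %5d events, %.2f events/min/neuron, mean amplitude %.2f\n",
              rec, nrow(ev), mean(ns$event_frequency),
              mean(ns$mean_amplitude, na.rm = TRUE)))
}

neuron_table <- do.call(rbind, all_summaries)
rownames(neuron_table) <- NULL
write.csv(neuron_table, file.path(out_dir, "neuron_summaries.csv"),
          row.names = FALSE)
cat(sprintf("\nwrote per-neuron summaries for %d recordings to %s\n",
            length(dff_files), out_dir))
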