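#!/usr/bin/env Rscript
# Convert every raw trace file from step 01 to dF/F0 using the 20-s
# sliding-minimum baseline (centered window), and report the resulting
# signal range per recording.

suppressPackageStartupMessages(library(syncburst))

in_dir <- "results/data"
out_dir <- "results/dff"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

raw_files <- list.files(in_dir, pattern = "_raw\\.csv$", full.names = TRUE)
stopifnot(length(raw_files) > 0)

for (f in raw_files) {
  tr <- read_traces(f)
  dff <- compute_dff(tr, window_s = 20, alignment = "centered")
  out <- file.path(out_dir, sub("_raw\\.csv$", "_dff.csv", basename(f)))
  write_traces(dff, out, extra_metadata = c(source = basename(f)))
  cat(sprintf("%-28s max dF/F0 = %.2f, median = %.3f\n",
              basename(out), max(dff$values), median(dff$values)))
}
cat(sprintf("\nwrote %d dF/F0 trace files to %s\n", length(raw_files), out_dir))
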