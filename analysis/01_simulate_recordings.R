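#!/usr/bin/env Rscript
# Simulate the study's recording design: paired baseline/post calcium-imaging
# recordings of dissociated cortical networks at 4 frames/s. Control sets get
# a null effect (the "post" epoch follows a rest period with no treatment);
# treated sets get a halved network-burst rate, the direction of the
# MEK-inhibition phenotype. Traces go to results/data/ as CSV, ground truth to
# a JSON sidecar.

suppressPackageStartupMessages(library(syncburst))

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

top_seed <- 20260929L %% .Machine$integer.max
n_control <- 6L   # recording sets per arm, mirroring the in vitro design
n_treated <- 8L
seeds <- derive_seeds(top_seed, n_control + n_treated)

sets <- data.frame(
  set = c(sprintf("control_%02d", seq_len(n_control)),
          sprintf("treated_%02d", seq_len(n_treated))),
  arm = rep(c("control", "treated"), c(n_control, n_treated)),
  seed = seeds
)

truth <- list()
for (i in seq_len(nrow(sets))) {
  eff <- if (sets$arm[i] == "treated") {
    effect_spec(burst_rate_multiplier = 0.5)
  } else effect_spec()
  sim <- simulate_paired_experiment(sim_params(seed = sets$seed[i]), eff)
  for (cond in c("baseline", "post")) {
    write_traces(sim[[cond]],
                 file.path(out_dir, sprintf("%s_%s_raw.csv", sets$set[i], cond)),
                 extra_metadata = c(source = "simulate"))
  }
  truth[[sets$set[i]]] <- list(
    arm = sets$arm[i], seed = sets$seed[i],
    effect = unclass(eff),
    baseline = sim$truth$baseline[c("burst_rate_per_min", "n_bursts")],
    post = sim$truth$post[c("burst_rate_per_min", "n_bursts")]
  )
  cat(sprintf("%s (%s): %d baseline / %d post ground-truth bursts\n",
              sets$set[i], sets$arm[i],
              sim$truth$baseline$n_bursts, sim$truth$post$n_bursts))
}

write.csv(sets, file.path(out_dir, "recording_sets.csv"), row.names = FALSE)
jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat(sprintf("\nwrote %d recording sets (%d trace files) to %s\n",
            nrow(sets), 2L * nrow(sets), out_dir))
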