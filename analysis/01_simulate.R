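#!/usr/bin/env Rscript
# Stage 1: simulate the demonstration cohort.
#
# 14 subjects in the screening composition (9 healthy-equivalent, of which 2
# are stroke subjects without spasticity; 2 at MAS 1; 3 at MAS 2), each
# performing all five tasks at the protocol repetition counts. Sessions are
# cached under scratch/ for the later stages; the summary table goes to
# results/.

library(spastiglove)
dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

spec <- cohort_spec(seed = 42L)
sim <- simulate_cohort(spec)
jsonlite::write_json(sim$manifest, "results/01_cohort_manifest.json",
                     auto_unbox = TRUE, digits = NA)

summ <- do.call(rbind, lapply(names(sim$sessions), function(key) {
  s <- sim$sessions[[key]]
  pulses <- if (s$task %in% c("S-BS", "F-BS"))
    count_pressure_pulses(
      pressure_offset(task_frames(s)$pressure, pressure_calibration(101325)),
      1000 * 0.3)
  else NA_integer_
  data.frame(session = key, subject = s$meta$subject_id, task = s$task,
             group = s$meta$group, mas = s$meta$mas_score,
             n_frames = nrow(s$frames),
             duration_s = nrow(s$frames) / s$sample_rate_hz,
             pressure_pulses = pulses)
}))
write.csv(summ, "results/01_cohort_summary.csv", row.names = FALSE)
saveRDS(sim$sessions, "scratch/sessions.rds")

cat(sprintf("simulated %d sessions (%d subjects x %d tasks)\n",
            nrow(summ), length(unique(summ$subject)),
            length(unique(summ$task))))
cat(sprintf("MAS composition: %s\n",
            paste(names(table(summ$mas[!duplicated(summ$subject)])),
                  table(summ$mas[!duplicated(summ$subject)]),
                  sep = ":", collapse = "  ")))
bs <- summ[!is.na(summ$pressure_pulses), ]
cat(sprintf("ball-squeeze sessions: %d/%d show the full 50 squeeze pulses\n",
            sum(bs$pressure_pulses == 50), nrow(bs)))
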