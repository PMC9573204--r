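#!/usr/bin/env Rscript
# Stage 3: attitude and joint angles.
#
# The screening features below are magnitude-based and do not consume fused
# angles; this stage reproduces the clinician-facing joint-angle view and
# quantifies how spasticity compresses the flexion cycles. For one healthy
# and one MAS-2 subject (slow flexion-extension task) the complementary
# filter is run on all finger-chain IMUs. The per-joint movement amplitude
# is measured spectrally — twice the dominant spectral amplitude of the
# joint-angle series in the movement band — which isolates the flexion
# cycles from the slow heading wander and tremor jitter of the per-sensor
# attitude estimates.

library(spastiglove)
calibrated <- readRDS("scratch/calibrated.rds")

pick <- function(mas) {
  keys <- names(calibrated)[vapply(calibrated, function(s)
    s$task == "S-FE" && s$meta$mas_score == mas, logical(1))]
  calibrated[[keys[1]]]
}

cycle_amplitudes <- function(ses) {
  fr <- task_frames(ses)
  task_ses <- new_session(fr, ses$task, ses$meta, validate = FALSE)
  jt <- joint_table()
  att <- list()
  for (imu in sort(unique(c(jt$imu_a, jt$imu_b))))
    att[[as.character(imu)]] <- estimate_attitude(task_ses, imu,
                                                  k_acc = 0.5, k_mag = 0.3)
  ja <- joint_angle_series(att, jt)
  # settle-in: drop the filter's convergence transient
  ja <- ja[-(1:250), , drop = FALSE]
  vapply(ja, function(a) {
    sp <- amplitude_spectrum(a, ses$sample_rate_hz)
    band <- sp$freq >= 0.2 & sp$freq <= 5
    2 * max(sp$amp[band])
  }, numeric(1))
}

h <- pick(0); s2 <- pick(2)
exc <- data.frame(joint = joint_table()$joint,
                  healthy_deg = round(cycle_amplitudes(h), 1),
                  mas2_deg = round(cycle_amplitudes(s2), 1))
exc$ratio <- round(exc$mas2_deg / exc$healthy_deg, 2)
write.csv(exc, "results/03_joint_cycle_amplitudes.csv", row.names = FALSE)

cat(sprintf("flexion-cycle amplitudes, healthy (%s) vs MAS 2 (%s), S-FE task:\n",
            h$meta$subject_id, s2$meta$subject_id))
print(exc, row.names = FALSE)
mcp <- exc[grepl("_mcp$", exc$joint), ]
cat(sprintf("\nmedian MCP cycle-amplitude ratio (MAS2/healthy): %.2f — the spastic subject moves over a compressed range (planted velocity scale 0.45)\n",
            median(mcp$ratio)))
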