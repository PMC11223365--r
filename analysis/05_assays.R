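#!/usr/bin/env Rscript
# Stage 5: in vitro assay calculators.
#
# Worked examples of the three deterministic readout computations on small
# synthetic plate readings: NBD-cholesterol efflux percentage per acceptor
# condition, knockdown expression by 2^-ddCt, and percent reduction in
# cholesterol uptake.

library(abostroke)

out_dir <- "results/assays"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

# synthetic fluorescence plate: three replicates per acceptor condition
readings <- data.frame(
  condition = rep(c("ApoA1 50 mg/L", "HDL 50 mg/L"), each = 3),
  replicate = rep(1:3, 2),
  fi_medium = c(312, 298, 305, 351, 344, 360),
  fi_lysate = c(688, 702, 695, 649, 656, 640))
eff <- efflux_summary(readings)
cat("cholesterol efflux by condition:\n")
print(eff, row.names = FALSE, digits = 4)
write.table(eff, file.path(out_dir, "efflux_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# synthetic qPCR: ABO knockdown vs control, GAPDH-normalised
kd <- data.frame(ct_target = c(27.9, 28.1, 28.0), ct_reference = c(18.0, 18.2, 18.1))
ctrl <- data.frame(ct_target = c(25.1, 25.0, 25.2), ct_reference = c(18.1, 18.0, 18.2))
fold <- relative_expression(kd, ctrl)
cat(sprintf("\nknockdown relative expression (2^-ddCt): %.3f-fold\n", fold))

# uptake reduction from control/treated fluorescence means
uptake <- data.frame(
  nbd_uM = c(0.2, 1, 5, 10),
  control_mean = c(1000, 2400, 5200, 9100),
  treated_mean = c(908, 2267, 4830, 7458))
uptake$reduction_percent <- percent_change(uptake$control_mean,
                                           uptake$treated_mean)
cat("\ncholesterol uptake reduction by NBD-cholesterol dose:\n")
print(uptake, row.names = FALSE)
write.table(uptake, file.path(out_dir, "uptake_reduction.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote efflux_summary.tsv, uptake_reduction.tsv to", out_dir, "\n")
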