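#!/usr/bin/env Rscript
# Multimodal region analysis: register MR-frame sensor coordinates to the
# fluorescence (CFM) frame by non-rigid coherent point drift, assign each
# sensor to a vimentin-positive or -negative region, and compare the local
# stress between the two groups.
library(mechanomr)
dir.create("results", showWarnings = FALSE)

model <- calibration_model()
ref <- generate_calibration_phantom(30, 0, seed = 51)
sbr0 <- estimate_reference_sbr0(
  filter_aggregates(detect_particles(ref$volume))$retained)

all_S <- c(); all_lab <- c(); per_tumor <- list()
for (k in 1:6) {
  rs <- generate_region_study(n_sensors = 45, seed = 500 + k)
  keep <- filter_aggregates(detect_particles(rs$volume))$retained
  S <- invert_signal(model, normalize_signal(keep$sbr, sbr0, model),
                     clamp = TRUE, clamp_slack = Inf)
  reg <- register_cpd(rs$source, rs$target, "nonrigid")
  mapped <- transform_points(reg, as.matrix(keep[, c("z_mm", "y_mm",
                                                     "x_mm")]))
  asg <- assign_regions(mapped, rs$labels)
  st <- region_stats(asg, as.numeric(S))
  per_tumor[[k]] <- cbind(tumor = k, st$table)
  ok <- !is.na(asg$region_label)
  all_S <- c(all_S, S[ok]); all_lab <- c(all_lab, asg$region_label[ok])
  cat(sprintf(
    "tumor %d: CPD %s in %d iters; groups n=%d/%d, means %.2f / %.2f kPa\n",
    k, if (reg$converged) "converged" else "did not converge",
    reg$iterations_run, st$table$n[1], st$table$n[2],
    st$table$mean_kPa[1], st$table$mean_kPa[2]))
}
write.csv(do.call(rbind, per_tumor), "results/region_stats_per_tumor.csv",
          row.names = FALSE)

pooled <- region_stats(data.frame(region_label = all_lab), all_S)
write.csv(pooled$table, "results/region_stats_pooled.csv", row.names = FALSE)
cat(sprintf(
  "\nPooled over %d sensors: vimentin-positive %.2f +- %.2f kPa, negative %.2f +- %.2f kPa (difference %.2f)\n",
  length(all_S),
  pooled$table$mean_kPa[pooled$table$region == "vimentin_positive"],
  pooled$table$sd_kPa[pooled$table$region == "vimentin_positive"],
  pooled$table$mean_kPa[pooled$table$region == "vimentin_negative"],
  pooled$table$sd_kPa[pooled$table$region == "vimentin_negative"],
  pooled$mean_difference))
cat("Generating distributions were 3.5 +- 2.8 (positive) and 7.4 +- 2.8",
    "(negative) kPa.\n")
cat("Wrote results/region_stats_{per_tumor,pooled}.csv\n")
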