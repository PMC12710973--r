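#!/usr/bin/env Rscript
# Compression-device mechanics: agarose material constants, displacement to
# stress conversion for the 10 x 10 mm cylinder, and the displacement
# schedules realizing the gradual and acute loading regimens.
library(mechanomr)
dir.create("results", showWarnings = FALSE)

geo <- device_geometry()
grades <- data.frame(concentration_pct = c(0.5, 1.0, 2.0))
grades$G_kPa <- vapply(grades$concentration_pct,
                       function(c) agarose_material(c)$G, numeric(1))
grades$E_kPa <- 2 * grades$G_kPa * (1 + 0.31)
write.csv(grades, "results/agarose_grades.csv", row.names = FALSE)
cat("Agarose grades (G in kPa):", paste(grades$G_kPa, collapse = ", "), "\n")

# displacement-stress curve for 2% agarose
mat <- agarose_material(2.0)
dx <- seq(0, 4, by = 0.25)
curve <- data.frame(displacement_mm = dx,
                    stress_kPa = displacement_to_stress(mat, geo, dx))
write.csv(curve, "results/displacement_stress_2pct.csv", row.names = FALSE)
cat(sprintf("2%% agarose: 2.2 mm displacement -> %.2f kPa; 5 kPa needs %.2f mm\n",
            displacement_to_stress(mat, geo, 2.2),
            stress_to_displacement(mat, geo, 5)))

# loading regimens as displacement schedules
for (kind in c("gradual", "acute")) {
  p <- loading_profile(kind)
  sched <- p$schedule
  sched$displacement_mm <- vapply(sched$stress_kPa, function(s)
    stress_to_displacement(mat, geo, s), numeric(1))
  write.csv(sched, sprintf("results/schedule_%s.csv", kind),
            row.names = FALSE)
  cat(sprintf("%-8s profile: peak %.1f kPa at %g h, max rate %.1f kPa/day\n",
              kind, max(sched$stress_kPa), max(sched$time_h),
              profile_max_rate(p)))
}
cat("Wrote results/agarose_grades.csv, displacement_stress_2pct.csv,",
    "schedule_{gradual,acute}.csv\n")
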