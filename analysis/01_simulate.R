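#!/usr/bin/env Rscript
# Simulate the catalytic cycle under both dosing modes and record the
# dosing-mode contrast that motivated the continuous-addition protocol:
# a one-shot oxidant bolus converts substrate almost immediately, while
# linear feeding spreads conversion over the hour.

suppressMessages(library(mimoxkin))
dir.create("results", showWarnings = FALSE)

truth <- default_truth()
for (mode in c("one_shot", "continuous")) {
  traj <- integrate_kinetics(truth, default_design(mode))
  write_trajectory(traj, file.path("results",
                                   sprintf("trajectory_%s.csv", mode)))
}

t_one <- half_conversion_time(
  integrate_kinetics(truth, default_design("one_shot")))
t_cont <- half_conversion_time(
  integrate_kinetics(truth, default_design("continuous")))
contrast <- data.frame(mode = c("one_shot", "continuous"),
                       half_conversion_min = c(t_one, t_cont) / 60)
write.csv(contrast, "results/dosing_contrast.csv", row.names = FALSE)

cat(sprintf("50%% conversion: one-shot %.1f min, continuous %.1f min\n",
            t_one / 60, t_cont / 60))
cat("The bolus is roughly", round(t_cont / t_one),
    "times faster to half-conversion: only continuous dosing yields a\n",
    "kinetic profile slow enough to resolve on the chromatographic grid.\n")

# the biphasic stress scenario: catalytic phase, catalyst-death stall,
# then direct oxidation by accumulating oxidant
biph <- integrate_kinetics(biphasic_truth(), default_design())
write_trajectory(biph, "results/trajectory_biphasic.csv")
n <- nrow(biph)
cat(sprintf("Biphasic truth: %.0f%% conversion, %.0f%% of flux non-catalytic\n",
            100 * (1 - biph$substrate[n] / 5e-4),
            100 * biph$metabolite_noncat[n] /
              (biph$metabolite_cat[n] + biph$metabolite_noncat[n])))
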