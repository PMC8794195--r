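#!/usr/bin/env Rscript
# Step 1 — generate the synthetic hospital panel.
#
# A 1329-day, 192-bed hospital census in which every discharge frees a bed
# refilled only after a random (geometric, mean 150 d) referral lag, plus
# the two data artifacts the cleaning stage must repair: impossible
# year-boundary admission/discharge counts and a 9-day recording gap.

library(wardwalk)

seed <- 3L   # simulation stream; analysis steps use their own master seed
dir.create("results", showWarnings = FALSE)

cfg <- hospital_config(inject_newyear_spike = TRUE, inject_gap = c(28, 9))
sim <- simulate_hospital(cfg, seed = seed)

write_panel_csv(sim$series, "results/panel_raw.csv")
message("Simulated ", nrow(sim$series), " days; census range [",
        min(sim$series$inp, na.rm = TRUE), ", ",
        max(sim$series$inp, na.rm = TRUE), "] of ", cfg$beds, " beds; ",
        sum(is.na(sim$series$inp)), " missing days and ",
        sum(sim$series$adm > cfg$beds, na.rm = TRUE),
        " impossible spike days injected.")
message("Mean refill lag drawn: ",
        round(mean(sim$true_lag_draws), 1), " days.")
message("Raw panel written to results/panel_raw.csv")
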