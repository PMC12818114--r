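#!/usr/bin/env Rscript
# Stage 6 — assemble the characterization report from stages 2-5.

suppressMessages(library(protonfilm))
fx <- "results/fixtures"

models <- lapply(c(B1 = "B1", B2 = "B2", B4 = "B4"), function(b)
  read_calibration_json(sprintf("results/calibration_%s.json", b)))

ts <- read.csv(file.path(fx, "kinetics_series.csv"))
kin <- lapply(c(red = "red", green = "green", blue = "blue"), function(ch)
  fit_biexponential(ts$time_h, ts[[paste0("netod_", ch)]]))
plateau <- vapply(kin, plateau_time, numeric(1))

stats <- jsonlite::read_json("results/response_stats.json", simplifyVector = TRUE)
tbl <- read.csv("results/lateral_deviation_table.csv")

chamber <- read_profile_csv(file.path(fx, "depth_chamber.csv"))
film <- read_profile_csv(file.path(fx, "depth_film_response.csv"))

film_report(
  list(calibration = models,
       kinetics = kin,
       plateau_h = plateau,
       statistics = lapply(stats, unlist),
       deviation_tables = list(lateral = tbl),
       peak_under_response_pct = c(red = peak_under_response(film, chamber))),
  path_md = "results/report.md", path_json = "results/report.json")
cat("report written to results/report.md and results/report.json\n")
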