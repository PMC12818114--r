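#' Write a complete synthetic fixture set
#'
#' Generates, under one directory, every input the pipeline consumes:
#' pre/post calibration scan pairs (48-bit TIFF) for the preset batches,
#' calibration netOD tables (CSV), darkening time series (CSV), depth and
#' lateral profiles (CSV), and the generating truths (JSON).  Byte-stable
#' for a fixed seed.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer master seed.
#' @param batches Preset batch ids to simulate.
#' @param scan_doses Doses (Gy) for which example TIFF scan pairs are
#'   written.
#' @param shape Pixel extent of the simulated film pieces.
#' @return Invisibly, a named list of the written paths.
#' @export
write_fixture_set <- function(out_dir, seed = 1L, batches = c("B1", "B2", "B4"),
                              scan_doses = c(0, 5, 10), shape = c(32L, 32L)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_pf("cannot create output directory '%s'", out_dir)
  paths <- list()
  for (b in batches) {
    truth <- preset_truth(b)
    p <- file.path(out_dir, sprintf("truth_%s.json", b))
    write_truth_json(truth, p)
    paths[[paste0("truth_", b)]] <- p
    ns <- noise_spec(seed = derive_seed(seed, match(b, batches)))
    for (d in scan_doses) {
      pair <- simulate_scan_pair(d, truth, ns, shape)
      for (w in c("pre", "post")) {
        p <- file.path(out_dir, sprintf("scan_%s_%sGy_%s.tif", b, format(d), w))
        save_scan(pair[[w]], p)
        paths[[basename(p)]] <- p
      }
    }
    cal <- simulate_calibration_dataset(truth, noise = ns, shape = shape)
    p <- file.path(out_dir, sprintf("calibration_%s.csv", b))
    utils::write.csv(cal, p, row.names = FALSE)
    paths[[paste0("calibration_", b)]] <- p
  }
  kin <- kinetics_truth(netod_inf = c(red = 0.40, green = 0.22, blue = 0.08),
                        C1 = c(red = 0.05, green = 0.028, blue = 0.010),
                        T1 = 1, C2 = c(red = 0.03, green = 0.016, blue = 0.006),
                        T2 = 12)
  write_truth_json(kin, file.path(out_dir, "truth_kinetics.json"))
  ts <- simulate_kinetics_series(kin, noise_fraction = 0.005,
                                 seed = derive_seed(seed, 101L))
  p <- file.path(out_dir, "kinetics_series.csv")
  utils::write.csv(ts, p, row.names = FALSE)
  paths$kinetics <- p
  beam <- beam_truth()
  write_truth_json(beam, file.path(out_dir, "truth_beam.json"))
  depth <- simulate_depth_profiles(beam)
  lat <- simulate_lateral_profiles(beam)
  for (nm in names(depth)) {
    p <- file.path(out_dir, sprintf("depth_%s.csv", nm))
    write_profile_csv(depth[[nm]], p)
    paths[[paste0("depth_", nm)]] <- p
  }
  for (nm in names(lat)) {
    p <- file.path(out_dir, sprintf("lateral_%s.csv", nm))
    write_profile_csv(lat[[nm]], p)
    paths[[paste0("lateral_", nm)]] <- p
  }
  invisible(paths)
}

#' Assemble a characterization report
#'
#' Collects the results of the analysis stages into one summary, written
#' as Markdown (human-readable) and JSON (machine-readable).  Sections are
#' included for whatever results are supplied; at least one is required.
#'
#' @param results A named list with any of: `calibration` (named list of
#'   [fit_calibration()] models), `kinetics` (named list of
#'   [fit_biexponential()] fits), `plateau_h` (named numeric),
#'   `statistics` (named list of statistic vectors), `deviation_tables`
#'   (named list of [lateral_deviation_table()] outputs),
#'   `peak_under_response_pct` (named numeric).
#' @param path_md,path_json Optional output paths.
#' @return Invisibly, the report list.
#' @export
film_report <- function(results, path_md = NULL, path_json = NULL) {
  known <- c("calibration", "kinetics", "plateau_h", "statistics",
             "deviation_tables", "peak_under_response_pct")
  if (!is.list(results) || !any(known %in% names(results))) {
    stop_pf("`results` must contain at least one of: %s",
            paste(known, collapse = ", "))
  }
  lines <- c("# Film characterization report", "")
  if (!is.null(results$calibration)) {
    lines <- c(lines, "## Dose-response calibration", "",
               "| batch | channel | a | b | n | R2 | RMSE |",
               "|---|---|---|---|---|---|---|")
    for (nm in names(results$calibration)) {
      m <- results$calibration[[nm]]
      for (ch in names(m$channels)) {
        p <- m$channels[[ch]]
        lines <- c(lines, sprintf("| %s | %s | %.4f | %.4f | %.4f | %.4f | %.2e |",
                                  nm, ch, p$a, p$b, p$n, p$r2, p$rmse))
      }
    }
    lines <- c(lines, "")
  }
  if (!is.null(results$kinetics)) {
    lines <- c(lines, "## Darkening kinetics", "",
               "| channel | netOD_inf | C1 | T1 (h) | C2 | T2 (h) | RMSE |",
               "|---|---|---|---|---|---|---|")
    for (ch in names(results$kinetics)) {
      k <- results$kinetics[[ch]]
      lines <- c(lines, sprintf("| %s | %.4f | %.4f | %.3g | %.4f | %.3g | %.2e |",
                                ch, k$netod_inf, k$C1, k$T1, k$C2, k$T2, k$rmse))
    }
    lines <- c(lines, "")
  }
  if (!is.null(results$plateau_h)) {
    lines <- c(lines, "## Plateau times (h)", "",
               paste(sprintf("- %s: %.2f h", names(results$plateau_h),
                             results$plateau_h)), "")
  }
  if (!is.null(results$statistics)) {
    lines <- c(lines, "## Characterization statistics", "")
    for (nm in names(results$statistics)) {
      v <- results$statistics[[nm]]
      lines <- c(lines, sprintf("- %s: %s", nm,
                                paste(sprintf("%s=%.4g", names(v), v),
                                      collapse = ", ")))
    }
    lines <- c(lines, "")
  }
  if (!is.null(results$deviation_tables)) {
    lines <- c(lines, "## Lateral deviation tables", "")
    for (nm in names(results$deviation_tables)) {
      tb <- results$deviation_tables[[nm]]
      lines <- c(lines, sprintf("### %s", nm), "",
                 "| position (mm) | chamber (%) | film (%) | deviation (pp) |",
                 "|---|---|---|---|")
      for (i in seq_len(nrow(tb))) {
        lines <- c(lines, sprintf("| %.1f | %.1f | %.1f | %+.1f |",
                                  tb$position_mm[i], tb$chamber_pct[i],
                                  tb$film_pct[i], tb$deviation_pp[i]))
      }
      lines <- c(lines, "")
    }
  }
  if (!is.null(results$peak_under_response_pct)) {
    lines <- c(lines, "## Bragg-peak under-response (%)", "",
               paste(sprintf("- %s: %.2f %%",
                             names(results$peak_under_response_pct),
                             results$peak_under_response_pct)), "")
  }
  if (!is.null(path_md)) writeLines(lines, path_md)
  if (!is.null(path_json)) {
    json_ready <- results
    if (!is.null(json_ready$calibration)) {
      json_ready$calibration <- lapply(json_ready$calibration, function(m)
        list(film_model = m$film_model, batch = m$batch,
             dose_range_gy = m$dose_range,
             channels = lapply(m$channels, function(p)
               p[c("a", "b", "n", "a_inv", "b_inv", "n_inv", "r2", "rmse")])))
    }
    jsonlite::write_json(json_ready, path_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, dataframe = "rows")
  }
  invisible(c(results, list(markdown = lines)))
}
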