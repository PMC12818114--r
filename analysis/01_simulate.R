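#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study inputs.
#
# Writes, under results/fixtures/: pre/post calibration scan pairs (48-bit
# TIFF) for batches B1, B2 and B4, per-batch calibration netOD tables,
# a darkening time series, depth and lateral beam profiles, and the
# generating truth parameters as JSON.  Everything downstream reads from
# this directory, so the whole analysis is reproducible from one seed.

suppressMessages(library(protonfilm))
seed <- 20260924L
out <- "results/fixtures"

paths <- write_fixture_set(out, seed = seed)
cat(sprintf("wrote %d fixture files under %s\n", length(paths), out))
cat("batches: B1, B2 (EBT4), B4 (EBT3); scans at 0, 5, 10 Gy\n")
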