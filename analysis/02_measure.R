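#!/usr/bin/env Rscript

# Stage 2: measure every sample of the study written by 01_simulate.R.
#
# Per sample: peel tension from the trace and its width, truncation at the
# failure drop, sigmoid fit for the delamination strength S_d; for samples
# with histology, nearest-centroid composition (lambda_ela from EM,
# lambda_col from Azan) and the interlaminar-fiber fraction from the EM
# image via the threshold / open / particle-filter / subtract chain.
# Writes results/measurements.csv.

suppressMessages(library(delamina))

res <- analyze_study("results/study")
write.csv(res, "results/measurements.csv", row.names = FALSE)

ok <- res$status == "ok"
cat(sprintf("measured %d samples (%d ok, %d flagged)\n",
            nrow(res), sum(ok), sum(!ok)))
cat(sprintf("converged fits: %d / %d\n",
            sum(res$converged, na.rm = TRUE), sum(!is.na(res$converged))))
cat("\nDelamination strength (N/m) by group x direction:\n")
print(summarize_cells(res, "S_d", by = c("group", "direction")))
cat("\nInterlaminar-fiber fraction by group:\n")
print(summarize_cells(res[is.finite(res$lambda_fibers), ],
                      "lambda_fibers", by = "group"))
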