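#!/usr/bin/env Rscript

# Stage 1: generate the synthetic three-group study on disk.
#
# Writes peel-trace CSVs, Elastica-Masson and Azan images, ROI masks,
# annotation points, per-sample truth JSON, the manifest and a provenance
# record under results/study/. The design mirrors the rat study: Control,
# Pre-dissection and Dissection groups with delamination strengths around
# 20 / 16 / 11 N/m and interlaminar-fiber fractions around 10.4 / 8.6 /
# 5.2% of the media, nine histology images per group.

suppressMessages(library(delamina))

seed <- 42
out <- "results/study"

manifest <- simulate_study(out, default_study_spec(), seed = seed)

cat(sprintf("study written to %s (seed %d)\n", out, seed))
cat(sprintf("  %d samples, %d with histology\n",
            nrow(manifest), sum(nzchar(manifest$em_file))))
print(table(manifest$group, manifest$direction))
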