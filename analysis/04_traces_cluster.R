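#!/usr/bin/env Rscript
# Extract per-cell reporter traces through the nuclear masks, cluster the
# normalised traces, classify early / late / non-responders, and build the
# heatmap and peak-time histogram.

library(smadtrace)
pop <- readRDS("scratch/population.rds")
ts <- readRDS("scratch/tracks.rds")
stack <- read_stack("scratch/movie.tiff", channels = 2)
ip <- imaging_params()

tr <- suppressWarnings(extract_traces(ts, stack,
                                      gfp_channel = ip$gfp_channel,
                                      frame_interval = 3))
cat("traces:", length(tr$cell_id), "\n")

cl <- cluster_traces(tr$norm, k = 3)
feats <- classify_responders(tr, cl)
cat("responder classes:\n")
print(table(feats$responder_class))
cat(sprintf("median onset: early %.0f min, late %.0f min\n",
            median(feats$onset_min[feats$responder_class == "early"],
                   na.rm = TRUE),
            median(feats$onset_min[feats$responder_class == "late"],
                   na.rm = TRUE)))
write.csv(feats, "results/responder_features.csv", row.names = FALSE)

hm <- heatmap_matrix(tr, features = feats, sort_by = "onset")
write.csv(hm$matrix, "results/heatmap_matrix.csv", row.names = TRUE)
png("results/heatmap.png", width = 900, height = 700)
image(t(hm$matrix[rev(seq_len(nrow(hm$matrix))), ]),
      col = hcl.colors(64, "Blue-Red 3"), axes = FALSE,
      xlab = "time (frames)", ylab = "cells (sorted by onset)",
      main = "Normalised reporter traces")
dev.off()

hist_df <- peak_time_histogram(feats, bin_width = 60)
write.csv(hist_df, "results/peak_time_histogram.csv", row.names = FALSE)

# recovery scorecard vs ground truth
truth <- sapply(tr$cell_id, function(id) {
  trk <- ts$tracks[ts$tracks$track_id == id, ]
  mid <- trk[round(nrow(trk) / 2), ]
  pop$cells$responder_class[
    which.min((pop$x[mid$frame, ] - mid$x)^2 +
                (pop$y[mid$frame, ] - mid$y)^2)]
})
ari <- mclust::adjustedRandIndex(feats$responder_class, truth)
cat(sprintf("adjusted Rand index vs ground truth: %.3f\n", ari))
write.csv(data.frame(metric = "ARI", value = ari),
          "results/classification_ari.csv", row.names = FALSE)
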