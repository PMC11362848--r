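#!/usr/bin/env Rscript
# Simulate the synthetic study material: a NeuN reference slide (hematoxylin
# nuclei = all cells, immunostain particles = neurons) and an Abeta serial
# section related by a small rigid transform, with exported ground truth.

suppressMessages(library(ihcquant))
dir.create("results/slides", recursive = TRUE, showWarnings = FALSE)

spec <- slide_spec(1400, 1400,
                   nucleus_count = 900, particle_count = 250,
                   nucleus_gradient = -0.9, seed = 2024)
ref <- generate_slide(spec)
abeta <- generate_serial_section(ref, transform = c(4, 12, -9), seed = 2025,
                                 particles = list(count = 250, gradient = 0.9))

write_slide_png(ref$image, "results/slides/neun.png")
write_slide_png(abeta$image, "results/slides/abeta.png")
write_centroids_csv(ref$truth, "results/slides/neun_truth.csv")
write_centroids_csv(abeta$truth, "results/slides/abeta_truth.csv")
write_annotation_geojson(
  annotation_set(list(list(label = "cortex", vertices = spec$tissue_polygon))),
  "results/slides/cortex.geojson"
)

message(sprintf(
  "wrote NeuN slide (%d nuclei, %d neuron particles) and Abeta serial section (%d plaques),",
  nrow(ref$truth$nucleus_centroids), nrow(ref$truth$particle_centroids),
  nrow(abeta$truth$particle_centroids)))
message("serial transform: rotation 4 deg, shift (12, -9) px; ground truth under results/slides/")
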