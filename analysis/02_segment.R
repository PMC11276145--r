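#!/usr/bin/env Rscript
# Step 2: segmentation accuracy. Voxelizes the right phantom under both
# modality models and runs the full segmentation chain (origin alignment,
# polarity-aware thresholding, seeded selection, hole filling, mesh
# extraction), comparing recovered S and V with the source mesh. Writes
# results/02_segmentation_accuracy.csv.

library(condylometry)
dir.create("results", showWarnings = FALSE)

m <- make_condyle_mesh(phantom_spec(side = "right"))
rows <- list()
for (mod in c("cbct_like", "mri_like")) {
  for (noisy in c(FALSE, TRUE)) {
    modality <- if (noisy) modality_model(mod)
      else modality_model(mod, boundary_noise_sd = 0,
                          intensity_noise_sd = 0)
    v <- voxelize(m, modality, seed = 2)
    seg <- segment_volume(align_origin(v))
    rows[[paste(mod, noisy)]] <- data.frame(
      modality = mod, noise = noisy,
      erosion_bias_mm = modality$erosion_bias,
      S_mm2 = surface_area(seg), V_mm3 = mesh_volume(seg),
      S_rel_error = surface_area(seg) / surface_area(m) - 1,
      V_rel_error = mesh_volume(seg) / mesh_volume(m) - 1)
  }
}
acc <- do.call(rbind, rows)
write.csv(acc, "results/02_segmentation_accuracy.csv", row.names = FALSE)
print(acc, digits = 4)

cat(sprintf(paste0(
  "\nNoise-free CBCT-like segmentation recovers V within %.2f%%;\n",
  "the MRI-like erosion bias of %.2g mm shrinks V by %.1f%% as expected,\n",
  "while boundary noise inflates the stair-cased surface estimate.\n"),
  100 * abs(acc$V_rel_error[acc$modality == "cbct_like" & !acc$noise]),
  modality_model("mri_like")$erosion_bias,
  -100 * acc$V_rel_error[acc$modality == "mri_like" & !acc$noise]))
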