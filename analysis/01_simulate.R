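#!/usr/bin/env Rscript
# Step 1: generate the phantom condyle pair and render it under both
# imaging models, checking voxel-volume convergence against the phantom's
# reference volume. Writes results/01_phantom_summary.csv and
# results/01_voxel_convergence.csv plus the raw volumes and meshes under
# results/volumes/.

library(condylometry)
dir.create("results/volumes", showWarnings = FALSE, recursive = TRUE)

pair <- make_condyle_pair()
ref <- pair$reference

summary <- do.call(rbind, lapply(c("left", "right"), function(side) {
  m <- pair[[side]]
  data.frame(side = side,
             mesh_S_mm2 = surface_area(m), mesh_V_mm3 = mesh_volume(m),
             reference_S_mm2 = ref[[side]]$S,
             reference_V_mm3 = ref[[side]]$V,
             reference_method = ref[[side]]$method)
}))
write.csv(summary, "results/01_phantom_summary.csv", row.names = FALSE)
print(summary, digits = 6)

write_stl(pair$left, "results/volumes/phantom_left.stl")
write_stl(pair$right, "results/volumes/phantom_right.stl")

for (mod in c("cbct_like", "mri_like")) {
  v <- voxelize(pair$right, modality_model(mod), seed = 1)
  write_volume(v, sprintf("results/volumes/right_%s.nii.gz", mod))
}

# voxel-size convergence of the occupied volume (noise-free CBCT model)
conv <- do.call(rbind, lapply(c(1.2, 0.8, 0.55, 0.4), function(h) {
  v <- voxelize(pair$right,
                modality_model("cbct_like", voxel_size = rep(h, 3),
                               boundary_noise_sd = 0,
                               intensity_noise_sd = 0), seed = 1)
  mv <- mask_volume(threshold_bone(v, 500))
  data.frame(voxel_mm = h, mask_V_mm3 = mv,
             rel_error = mv / mesh_volume(pair$right) - 1)
}))
write.csv(conv, "results/01_voxel_convergence.csv", row.names = FALSE)
print(conv, digits = 4)
cat(sprintf(
  "\nVoxel volume converges to the mesh volume: error %.2f%% at 1.2 mm -> %.2f%% at 0.4 mm.\n",
  100 * abs(conv$rel_error[1]), 100 * abs(conv$rel_error[4])))
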