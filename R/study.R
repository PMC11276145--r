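#' Configuration of a full replicate study
#'
#' Bundles every parameter of the end-to-end emulation: the phantom pair,
#' the two modality models, the pseudo-operator settings (threshold and
#' seed-point jitter), per-replicate pose offsets, registration and cut
#' parameters, and the master seed from which every downstream RNG stream
#' is derived. Two runs with an identical config are bit-identical.
#'
#' Pseudo-operators emulate the between-operator variability of manual
#' segmentation: each (operator, replicate) segmentation perturbs the
#' intensity threshold by `threshold_jitter_sd` and the brush seed voxel
#' by up to `seed_jitter_vox` voxels. The left condyle's boundary noise is
#' multiplied by `left_noise_factor` to emulate the poorer image
#' reconstruction reported for the left side.
#'
#' @param master_seed integer master seed.
#' @param spec_left,spec_right phantom specs for the two sides.
#' @param cbct,mri modality models.
#' @param operators character vector of operator labels (default A, B).
#' @param replicates replicates per operator/modality/side (default 3).
#' @param threshold_jitter_sd SD of the per-segmentation threshold jitter
#'   (intensity units).
#' @param seed_jitter_vox maximum per-axis brush-seed displacement
#'   (voxels).
#' @param left_noise_factor multiplier on `boundary_noise_sd` for the
#'   left side.
#' @param replicate_max_angle,replicate_max_shift per-replicate random
#'   rigid offset bounds (degrees, mm) applied before voxelization.
#' @param icp_radius patch selection radius for registration (mm).
#' @param cut_z height of the head/neck cutting plane (mm, phantom frame).
#' @param reference which model is the registration reference
#'   (operator/modality/replicate).
#' @return an object of class `study_config`.
#' @export
study_config <- function(master_seed = 1L,
                         spec_left = phantom_spec(side = "left"),
                         spec_right = phantom_spec(side = "right"),
                         cbct = modality_model("cbct_like"),
                         mri = modality_model("mri_like"),
                         operators = c("A", "B"),
                         replicates = 3L,
                         threshold_jitter_sd = 40,
                         seed_jitter_vox = 1L,
                         left_noise_factor = 2,
                         replicate_max_angle = 2,
                         replicate_max_shift = 1,
                         icp_radius = 8,
                         cut_z = -3.5,
                         reference = list(operator = "A",
                                          modality = "CBCT",
                                          replicate = 1L)) {
  structure(list(master_seed = as.integer(master_seed),
                 spec_left = spec_left, spec_right = spec_right,
                 cbct = cbct, mri = mri, operators = operators,
                 replicates = as.integer(replicates),
                 threshold_jitter_sd = threshold_jitter_sd,
                 seed_jitter_vox = as.integer(seed_jitter_vox),
                 left_noise_factor = left_noise_factor,
                 replicate_max_angle = replicate_max_angle,
                 replicate_max_shift = replicate_max_shift,
                 icp_radius = icp_radius, cut_z = cut_z,
                 reference = reference),
            class = "study_config")
}

# deterministic per-task seed derived from the master seed (< 2^31)
derive_seed <- function(master, ...) {
  key <- paste(master, ..., sep = "/")
  h <- sum(utf8ToInt(key) * (seq_along(utf8ToInt(key)) %% 97 + 1))
  as.integer((h + as.numeric(master)) %% 2147480000)
}

#' Landmarks of the phantom cutting planes
#'
#' The mid-sagittal ANS stand-in and the two sigmoid-notch stand-ins, all
#' at the head/neck cut height: plane A is the horizontal cut isolating
#' the condylar head; plane B (through the notch points, orthogonal to
#' plane A) lies posterior to the phantom.
#'
#' @param config a [study_config()].
#' @return list with `ANS`, `notch_L`, `notch_R` (mm).
#' @export
phantom_landmarks <- function(config) {
  off <- config$spec_left$lateral_offset
  b <- config$spec_left$semi_axes[2]
  list(ANS = c(0, 70, config$cut_z),
       notch_L = c(off, -b - 4, config$cut_z),
       notch_R = c(-off, -b - 4, config$cut_z))
}

#' Run the full replicate study
#'
#' End-to-end emulation of the replicate design: generate the phantom
#' pair, render each (modality, side, replicate) volume with a small
#' random pose offset, segment each with per-operator jitter, register
#' every model to the reference model of its side, cut the condylar head
#' with the landmark planes, measure S and V, compare every model to its
#' side reference by cloud distance, and build the statistical report.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory; when given, volumes (NIfTI), meshes
#'   (STL), poses, measurement and distance CSVs and report tables are
#'   written there.
#' @param verbose print progress.
#' @return list: `table` (measurement data.frame), `report`
#'   (`condyle_report`), `distances` (named `distance_field` list),
#'   `mri_vs_ref` (MRI-to-CBCT-reference distance fields), `cap_area`
#'   (per-model planar cap area), `truth` (phantom reference S/V and
#'   per-replicate true poses), `config`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  pair <- make_condyle_pair(config$spec_left, config$spec_right)
  lm <- phantom_landmarks(config)
  sides <- c(L = "left", R = "right")
  mods <- list(CBCT = config$cbct, MRI = config$mri)
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  rows <- list(); meshes <- list(); poses <- list(); caps <- list()
  truth_pose <- list()
  for (mod_name in names(mods)) {
    for (side_code in names(sides)) {
      base_mesh <- pair[[sides[side_code]]]
      modality <- mods[[mod_name]]
      if (side_code == "L")
        modality$boundary_noise_sd <-
          modality$boundary_noise_sd * config$left_noise_factor
      for (rep_i in seq_len(config$replicates)) {
        pseed <- derive_seed(config$master_seed, "pose", mod_name,
                             side_code, rep_i)
        pert <- perturb_replicate(base_mesh,
                                  max_angle = config$replicate_max_angle,
                                  max_shift = config$replicate_max_shift,
                                  seed = pseed)
        vseed <- derive_seed(config$master_seed, "vox", mod_name,
                             side_code, rep_i)
        vol <- voxelize(pert$mesh, modality, seed = vseed)
        key0 <- paste(mod_name, side_code, rep_i, sep = ".")
        truth_pose[[key0]] <- pert$transform
        if (!is.null(out_dir))
          write_volume(vol, file.path(out_dir,
            sprintf("vol_%s.nii.gz", key0)))
        for (op in config$operators) {
          say("segmenting %s operator %s", key0, op)
          sseed <- derive_seed(config$master_seed, "seg", mod_name,
                               side_code, rep_i, op)
          set.seed(sseed)
          band <- default_bone_band(vol)
          jit <- stats::rnorm(1, 0, config$threshold_jitter_sd)
          if (vol$polarity == "bone_bright") band$lo <- band$lo + jit
          else band$hi <- band$hi + jit
          # brush seed: voxel nearest the phantom centre, jittered
          ctr <- colMeans(pert$mesh$vertices)
          vol0 <- align_origin(vol)
          shift <- attr(vol0, "origin_shift")
          seedvox <- round((ctr - shift) / vol0$spacing) + 1L +
            sample(seq(-config$seed_jitter_vox, config$seed_jitter_vox),
                   3L, replace = TRUE)
          seedvox <- pmin(pmax(seedvox, 1L), dim(vol0$intensities))
          mesh <- segment_volume(vol0, lo = band$lo, hi = band$hi,
                                 seeds = seedvox)
          # back to world coordinates of the scan
          mesh$vertices <- sweep(mesh$vertices, 2L, -shift)
          meshes[[paste(op, key0, sep = ".")]] <- mesh
        }
      }
    }
  }

  # registration: align every model to its side's reference model
  ref_op <- config$reference$operator
  ref_mod <- config$reference$modality
  ref_rep <- config$reference$replicate
  registered <- list()
  for (side_code in names(sides)) {
    ref_key <- paste(ref_op, paste(ref_mod, side_code, ref_rep, sep = "."),
                     sep = ".")
    ref_mesh <- meshes[[ref_key]]
    for (key in names(meshes)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      if (parts[3] != side_code) next
      if (key == ref_key) {
        registered[[key]] <- ref_mesh
        poses[[key]] <- rigid_transform()
        next
      }
      say("registering %s", key)
      reg <- register_meshes(ref_mesh, meshes[[key]],
                             radius = config$icp_radius)
      registered[[key]] <- apply_transform(meshes[[key]], reg$transform)
      poses[[key]] <- reg$transform
    }
  }

  # condylar head cut in the shared (reference) frame
  planes <- build_cut_planes(lm$ANS, lm$notch_L, lm$notch_R)
  for (key in names(registered)) {
    say("cutting %s", key)
    cut <- suppressWarnings(cut_head(registered[[key]], planes))
    caps[[key]] <- attr(cut, "cap_area")
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    rows[[key]] <- measure_mesh(cut, operator = parts[1],
                                modality = parts[2], side = parts[3],
                                replicate = as.integer(parts[4]))
    registered[[key]] <- cut
    if (!is.null(out_dir))
      write_stl(cut, file.path(out_dir, sprintf("head_%s.stl", key)))
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL

  # cloud distances of every model to its side's reference head
  distances <- list(); mri_vs_ref <- list()
  for (side_code in names(sides)) {
    ref_key <- paste(ref_op, paste(ref_mod, side_code, ref_rep, sep = "."),
                     sep = ".")
    for (key in names(registered)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      if (parts[3] != side_code || key == ref_key) next
      fld <- cloud_distance(registered[[ref_key]], registered[[key]])
      if (parts[2] == "MRI") mri_vs_ref[[key]] <- fld
      distances[[key]] <- fld
    }
  }

  report <- build_report(table)
  out <- list(table = table, report = report, distances = distances,
              mri_vs_ref = mri_vs_ref, cap_area = caps,
              truth = list(reference = pair$reference,
                           poses = truth_pose),
              meshes = registered, config = config)
  if (!is.null(out_dir)) {
    cfgtxt <- paste(deparse(config), collapse = "")
    jsonlite::write_json(list(
      master_seed = config$master_seed,
      config_hash = sprintf("%08x",
        sum(utf8ToInt(cfgtxt) * (seq_along(utf8ToInt(cfgtxt)) %% 31 + 1)) %%
          .Machine$integer.max),
      phantom_reference = pair$reference),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE,
      digits = NA)
    utils::write.csv(table, file.path(out_dir, "measurements.csv"),
                     row.names = FALSE)
    write_report(report, file.path(out_dir, "report"))
    for (key in names(distances))
      write_distance_csv(distances[[key]],
        file.path(out_dir, sprintf("dist_%s.csv", key)))
    for (key in names(poses))
      write_pose(poses[[key]],
        file.path(out_dir, sprintf("pose_%s.txt", key)))
  }
  out
}
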