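# Orchestration: subject-level splits, per-fold two-stage training,
# full-volume segmentation (single fold or ensemble), evaluation and
# reporting.

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end experiment. Two profiles are
#' provided: `"full"` mirrors the clinical-scale recipe (depth-4/64-filter
#' networks, 100/500 epochs, k = 6 folds), `"desk"` is the small phantom
#' profile the package's tests and examples run (depth-3/8-filter networks,
#' 30/60 epochs, k = 2 folds, 5-slice phantoms) — same structure, scaled
#' problem size.
#'
#' @param modality `"ct"` or `"mri"` phantom style.
#' @param profile `"desk"` or `"full"`.
#' @param n_train_subjects subjects in the cross-validation pool.
#' @param n_test_subjects held-out test subjects (fixed across folds).
#' @param k number of cross-validation folds (each fold validates on one
#'   subject).
#' @param phantom template [phantom_params()] for the cohort.
#' @param unet1,unet2 [unet_config()] for the global and local networks.
#' @param train1,train2 [train_config()] for the two stages.
#' @param boundary_px thickness of the rasterized stage-2 boundary truth.
#' @param side half-image containing the orbit.
#' @param roi_size stage-2 region-of-interest side (128 px).
#' @param n_angles,pad_cols,pad_weight_prob graph-search parameters.
#' @param saturate_stage2 also apply CT percentile saturation on the local
#'   network's input (default FALSE: saturation is a global-network
#'   preprocessing step).
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir optional experiment directory for artifacts and model
#'   checkpoints (enables resume).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(modality = c("ct", "mri"),
                            profile = c("desk", "full"),
                            n_train_subjects = 6L,
                            n_test_subjects = NULL,
                            k = NULL,
                            phantom = NULL,
                            unet1 = NULL, unet2 = NULL,
                            train1 = NULL, train2 = NULL,
                            boundary_px = 3L,
                            side = "left",
                            roi_size = 128L,
                            n_angles = 360L,
                            pad_cols = 2L,
                            pad_weight_prob = 1 - 1e-5,
                            saturate_stage2 = FALSE,
                            seed = 1L,
                            out_dir = NULL) {
  modality <- match.arg(modality)
  profile <- match.arg(profile)
  desk <- profile == "desk"
  k <- k %||% (if (desk) 2L else 6L)
  n_test_subjects <- n_test_subjects %||% (if (desk) 2L else 5L)
  phantom <- phantom %||% phantom_params(
    modality = modality,
    n_slices = if (desk) 5L else 9L,
    slice_shape = if (desk) c(128L, 128L) else c(352L, 512L),
    medial_radius = if (desk) 20 else 45)
  ucfg <- function() unet_config(depth = if (desk) 3L else 4L,
                                 base_filters = if (desk) 8L else 64L)
  unet1 <- unet1 %||% ucfg()
  unet2 <- unet2 %||% ucfg()
  aug <- augment_config(flip_probability = 0.5, rotation_range_deg = 10)
  # desk batches are small: with ~25 training slices the short desk
  # schedules need the extra gradient updates per epoch to converge
  train1 <- train1 %||% stage1_train_config(profile = if (desk) "desk" else "full",
                                            augment = aug,
                                            batch_size = if (desk) 2L else 128L)
  train2 <- train2 %||% stage2_train_config(profile = if (desk) "desk" else "full",
                                            augment = aug,
                                            batch_size = if (desk) 2L else 128L)
  if (k > n_train_subjects) stop("need at least k training subjects")
  structure(list(modality = modality, profile = profile,
                 n_train_subjects = as.integer(n_train_subjects),
                 n_test_subjects = as.integer(n_test_subjects),
                 k = as.integer(k), phantom = phantom,
                 unet1 = unet1, unet2 = unet2,
                 train1 = train1, train2 = train2,
                 boundary_px = as.integer(boundary_px),
                 side = side, roi_size = as.integer(roi_size),
                 n_angles = as.integer(n_angles),
                 pad_cols = as.integer(pad_cols),
                 pad_weight_prob = pad_weight_prob,
                 saturate_stage2 = isTRUE(saturate_stage2),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Subject-level cross-validation folds
#'
#' Builds `k` folds over the training subjects: fold i validates on the
#' i-th (optionally shuffled) subject and trains on all others; the test
#' subjects are held fixed outside this function. Splits are always by
#' subject, never by slice, so no subject's slices can appear on both sides
#' of a split.
#'
#' @param subjects vector of subject identifiers (length >= k).
#' @param k number of folds.
#' @param seed optional seed for a reproducible shuffle before assignment.
#' @return list of `k` lists with elements `fold`, `validation` (one
#'   subject) and `training` (the rest).
#' @export
make_folds <- function(subjects, k = 6L, seed = NULL) {
  if (length(subjects) < k) stop("need at least k subjects")
  if (!is.null(seed)) {
    set.seed(seed)
    subjects <- sample(subjects)
  }
  lapply(seq_len(k), function(i) {
    list(fold = i, validation = subjects[i], training = subjects[-i])
  })
}

# stage-1 training pair for one slice: half-image input and filled-region
# labels (CT inputs percentile-saturated before normalization)
prep_stage1 <- function(volume, s, cfg) {
  img <- crop_half(volume$intensities[[s]], cfg$side)
  if (volume$params$modality == "ct") img <- saturate_percentiles(img)
  img <- normalize_minmax(img)
  msk <- crop_half(volume$region_masks[[s]], cfg$side)
  msk <- matrix(as.integer(msk > 0), nrow(msk), ncol(msk))
  list(image = img, mask = msk)
}

# stage-2 training pair: normalized ROI around the true center and a
# boundary-ring label of configurable thickness
prep_stage2 <- function(volume, s, cfg) {
  img <- volume$intensities[[s]]
  if (cfg$saturate_stage2 && volume$params$modality == "ct") {
    img <- saturate_percentiles(img)
  }
  img <- normalize_minmax(img)
  roi <- extract_roi(img, volume$centers[s, ], cfg$roi_size)
  mroi <- extract_roi(volume$region_masks[[s]], volume$centers[s, ], cfg$roi_size)
  ring <- mask_boundary(mroi$roi)
  if (cfg$boundary_px >= 3) ring <- dilate3(ring, (cfg$boundary_px - 1L) %/% 2L)
  list(image = roi$roi, mask = ring, spec = roi$spec)
}

gather_pairs <- function(volumes, ids, prep, cfg) {
  imgs <- list(); msks <- list()
  for (id in ids) {
    vol <- volumes[[id]]
    for (s in seq_along(vol$intensities)) {
      p <- prep(vol, s, cfg)
      imgs[[length(imgs) + 1L]] <- p$image
      msks[[length(msks) + 1L]] <- p$mask
    }
  }
  list(images = imgs, masks = msks)
}

train_fold <- function(volumes, fold, cfg, stage) {
  prep <- if (stage == 1) prep_stage1 else prep_stage2
  tr <- gather_pairs(volumes, fold$training, prep, cfg)
  va <- gather_pairs(volumes, fold$validation, prep, cfg)
  ucfg <- if (stage == 1) cfg$unet1 else cfg$unet2
  tcfg <- if (stage == 1) cfg$train1 else cfg$train2
  seed <- (cfg$seed %% 100000L) * 101L + fold$fold * 10L + stage
  tcfg$seed <- seed
  model <- build_unet(ucfg, seed = seed)
  fit <- train_unet(model, tr$images, tr$masks, va$images, va$masks, tcfg)
  fit$fold <- fold$fold
  fit
}

#' Segment a full volume with trained stage models
#'
#' Runs the complete per-slice chain — preprocessing, stage-1 localization
#' with fallback, 128x128 ROI extraction, stage-2 boundary map (majority
#' voted across folds in ensemble mode), polar graph search — followed by
#' adjacent-slice 2-of-3 voting with end-slice omission. Contours and
#' centers of the returned slices are recomputed from the voted masks.
#'
#' @param volume a `phantom_volume` (or compatible list with
#'   `intensities` and `params$modality`).
#' @param models list with `stage1` (a `trained_unet`, or list of them) and
#'   `stage2` (likewise); when a stage holds several fold models the
#'   stage-2 maps are ensemble majority voted (stage-1 localization uses the
#'   first fold's model).
#' @param cfg a [pipeline_config()].
#' @return list with `slice_indices` (evaluated input slices), `masks`,
#'   `contours`, `centers`, `roi_specs`, `pre_masks` (per-slice masks
#'   before slice voting) and `status` (per-slice localization status).
#' @export
run_segment <- function(volume, models, cfg) {
  n <- length(volume$intensities)
  m1 <- if (inherits(models$stage1, "unet_model")) models$stage1 else models$stage1[[1]]
  m2list <- if (inherits(models$stage2, "unet_model")) list(models$stage2) else models$stage2
  centers <- matrix(NA_real_, n, 2)
  status <- rep("ok", n)
  # pass 1: localize every slice
  for (s in seq_len(n)) {
    half <- crop_half(volume$intensities[[s]], cfg$side)
    col_off <- attr(half, "crop_offset")
    if (volume$params$modality == "ct") half <- saturate_percentiles(half)
    loc <- localize_orbit(predict_map(m1, normalize_minmax(half)))
    if (loc$status == "ok") {
      centers[s, ] <- loc$center + c(0, col_off)
    } else {
      status[s] <- "not_found"
    }
  }
  found <- which(status == "ok")
  if (length(found) == 0) stop("stage-1 localization failed on every slice")
  for (s in which(status != "ok")) {
    centers[s, ] <- centers[found[which.min(abs(found - s))], ]
  }
  # pass 2: boundary extraction per slice
  masks <- vector("list", n); contours <- vector("list", n)
  roi_specs <- vector("list", n); low_conf <- logical(n)
  for (s in seq_len(n)) {
    img <- volume$intensities[[s]]
    if (cfg$saturate_stage2 && volume$params$modality == "ct") {
      img <- saturate_percentiles(img)
    }
    img <- normalize_minmax(img)
    roi <- extract_roi(img, centers[s, ], cfg$roi_size)
    maps <- lapply(m2list, function(m) predict_map(m, roi$roi))
    prob <- if (length(maps) == 1) maps[[1]] else majority_vote(maps)
    center_roi <- centers[s, ] - as.numeric(roi$spec$offset)
    eb <- extract_boundary(prob, center_roi,
                           n_angles = cfg$n_angles,
                           pad_cols = cfg$pad_cols,
                           pad_weight_prob = cfg$pad_weight_prob,
                           roi_spec = roi$spec,
                           slice_dim = dim(volume$intensities[[s]]))
    masks[[s]] <- eb$mask
    contours[[s]] <- eb$contour
    roi_specs[[s]] <- roi$spec
    low_conf[s] <- eb$low_confidence
  }
  voted <- average_adjacent_slices(masks)
  idx <- attr(voted, "slice_indices")
  out_contours <- vector("list", length(idx))
  out_centers <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    if (sum(voted[[j]]) > 0) {
      out_centers[[j]] <- mask_centroid(voted[[j]])
      out_contours[[j]] <- mask_contour(voted[[j]], center = out_centers[[j]])
    } else {
      out_centers[[j]] <- c(NA_real_, NA_real_)
      out_contours[[j]] <- matrix(numeric(0), 0, 2)
    }
  }
  list(slice_indices = idx, masks = voted, contours = out_contours,
       centers = out_centers, roi_specs = roi_specs[idx],
       pre_masks = masks, status = status, low_confidence = low_conf)
}

# evaluate a segmentation result against phantom ground truth
evaluate_segmentation <- function(seg, volume, spacing_mm = 0.5) {
  idx <- seg$slice_indices
  truth <- list(masks = volume$region_masks[idx],
                contours = volume$contours[idx],
                centers = lapply(idx, function(s) volume$centers[s, ]))
  evaluate_volume(list(masks = seg$masks, contours = seg$contours,
                       centers = seg$centers),
                  truth, spacing_mm = spacing_mm, rois = seg$roi_specs)
}

#' Run the full experiment: simulate, train per fold, segment, evaluate
#'
#' Generates a phantom cohort, builds subject-level folds, trains both
#' stages per fold, segments the fixed test subjects with each fold's
#' models and with the majority-vote ensemble, and aggregates the
#' evaluation metrics into a table with one row per fold, a fold-mean row
#' and an ensemble row. When `cfg$out_dir` is set, model checkpoints are
#' cached there and reused on re-runs, and the report table, per-slice
#' metrics and contours are written alongside.
#'
#' @param cfg a [pipeline_config()].
#' @param verbose print progress.
#' @return object of class `orbit_experiment`: `config`, `folds`,
#'   `manifest` (per-fold training/validation/test subjects), `models`,
#'   `table` (summary data frame), `evals` (nested per fold/subject),
#'   `test_subjects`.
#' @export
run_all <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  n_all <- cfg$n_train_subjects + cfg$n_test_subjects
  volumes <- generate_dataset(n_all, cfg$phantom,
                              seed = (cfg$seed %% 100000L) * 13L + 7L)
  train_ids <- seq_len(cfg$n_train_subjects)
  test_ids <- cfg$n_train_subjects + seq_len(cfg$n_test_subjects)
  folds <- make_folds(train_ids, k = cfg$k)
  manifest <- lapply(folds, function(f) {
    list(fold = f$fold, training = f$training, validation = f$validation,
         test = test_ids)
  })
  # leak guard: training subjects must exclude validation and test subjects
  for (f in folds) {
    stopifnot(length(intersect(f$training, f$validation)) == 0,
              length(intersect(f$training, test_ids)) == 0,
              length(intersect(f$validation, test_ids)) == 0)
  }
  cache_path <- function(fold, stage) {
    if (is.null(cfg$out_dir)) return(NULL)
    file.path(cfg$out_dir, "models", sprintf("fold%d_stage%d.rds", fold, stage))
  }
  models <- lapply(folds, function(f) {
    fit <- lapply(1:2, function(stage) {
      cp <- cache_path(f$fold, stage)
      if (!is.null(cp) && file.exists(cp)) return(readRDS(cp))
      if (verbose) message(sprintf("training fold %d stage %d", f$fold, stage))
      m <- train_fold(volumes, f, cfg, stage)
      if (!is.null(cp)) {
        dir.create(dirname(cp), recursive = TRUE, showWarnings = FALSE)
        saveRDS(m, cp)
      }
      m
    })
    names(fit) <- c("stage1", "stage2")
    fit
  })
  runs <- c(lapply(seq_len(cfg$k), function(i) {
    list(label = sprintf("fold%d", i),
         models = list(stage1 = models[[i]]$stage1, stage2 = models[[i]]$stage2))
  }), list(list(label = "ensemble",
                models = list(stage1 = lapply(models, `[[`, "stage1"),
                              stage2 = lapply(models, `[[`, "stage2")))))
  evals <- lapply(runs, function(run) {
    if (verbose) message("segmenting test subjects: ", run$label)
    lapply(test_ids, function(id) {
      seg <- run_segment(volumes[[id]], run$models, cfg)
      list(subject = id, seg = seg,
           eval = evaluate_segmentation(seg, volumes[[id]],
                                        spacing_mm = cfg$phantom$spacing_mm[1]))
    })
  })
  names(evals) <- vapply(runs, `[[`, "", "label")
  tab <- summarize_experiment(evals, cfg$k)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(tab, file.path(cfg$out_dir, "summary.csv"), row.names = FALSE)
    jsonlite::write_json(
      lapply(evals, function(e) lapply(e, function(x) {
        r <- x$eval; r$per_slice <- NULL; unclass(r)
      })),
      file.path(cfg$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  structure(list(config = cfg, folds = folds, manifest = manifest,
                 models = models, table = tab, evals = evals,
                 test_subjects = test_ids),
            class = "orbit_experiment")
}

# one row per fold + fold-mean + ensemble, aggregated over test subjects
summarize_experiment <- function(evals, k) {
  row_of <- function(label, items) {
    g <- function(f) vapply(items, f, 0)
    vols <- g(function(x) x$eval$dice_orbit_volumetric)
    volb <- g(function(x) x$eval$dice_background_volumetric)
    pso <- g(function(x) x$eval$dice_orbit_per_slice[["mean"]])
    psb <- g(function(x) x$eval$dice_background_per_slice[["mean"]])
    ce <- g(function(x) x$eval$centroid_error_px[["mean"]])
    mae <- g(function(x) x$eval$boundary_mae_px[["mean"]])
    hd <- g(function(x) x$eval$hausdorff_px[["mean"]])
    data.frame(run = label,
               vol_dice_orbit = mean(vols), vol_dice_background = mean(volb),
               slice_dice_orbit = mean(pso), slice_dice_background = mean(psb),
               centroid_error_px = mean(ce), boundary_mae_px = mean(mae),
               hausdorff_px = mean(hd))
  }
  fold_rows <- do.call(rbind, lapply(seq_len(k), function(i) {
    row_of(sprintf("fold%d", i), evals[[sprintf("fold%d", i)]])
  }))
  mean_row <- fold_rows[1, ]
  mean_row$run <- "fold_mean"
  for (cn in names(fold_rows)[-1]) mean_row[[cn]] <- mean(fold_rows[[cn]])
  ens_row <- row_of("ensemble", evals[["ensemble"]])
  rbind(fold_rows, mean_row, ens_row)
}

#' @export
print.orbit_experiment <- function(x, ...) {
  cat(sprintf("<orbit_experiment> %s phantoms, %s profile, k = %d folds, %d test subjects\n",
              x$config$modality, x$config$profile, x$config$k,
              length(x$test_subjects)))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
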