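#' Apply the segment inclusion filter
#'
#' Retains segments without a stent that are visible on CMRA; stented
#' segments suffer imaging artifacts that preclude stenosis assessment, and
#' segments invisible on CMRA cannot be annotated. Order is preserved and the
#' filter is idempotent.
#'
#' @param records A segment-record tibble with logical columns `has_stent`
#'   and `visible_on_cmra`.
#' @return The retained records, same columns and order.
#' @export
apply_inclusion_filter <- function(records) {
  dplyr::filter(records, !.data$has_stent, .data$visible_on_cmra)
}

#' Extract a 21x21x21 volume of interest around an annotation
#'
#' The patch is centered on the annotated voxel (10 voxels on each side per
#' axis). If the annotation lies within 10 voxels of a volume border, the
#' patch is completed by edge replication and a warning is issued; with
#' `border = "reject"` such annotations are an error instead.
#'
#' @param volume 3D intensity array, each dimension >= 21.
#' @param annotation Integer triple: 0-based voxel coordinate of the center.
#' @param border `"replicate"` (default) or `"reject"`.
#' @return A 21x21x21 numeric array.
#' @export
extract_voi <- function(volume, annotation, border = c("replicate", "reject")) {
  border <- match.arg(border)
  d <- dim(volume)
  if (length(d) != 3 || any(d < 21)) {
    abort("volume must be a 3D array with each dimension >= 21")
  }
  ann <- as.integer(annotation)
  if (length(ann) != 3 || any(ann < 0) || any(ann >= d)) {
    abort("annotation coordinate lies outside the volume")
  }
  center <- ann + 1L  # to 1-based
  idx <- lapply(1:3, function(a) center[a] + (-10:10))
  padded <- any(vapply(1:3, function(a) any(idx[[a]] < 1 | idx[[a]] > d[a]),
                       logical(1)))
  if (padded) {
    if (border == "reject") {
      abort("annotation is within 10 voxels of a border (border = \"reject\")")
    }
    warn("VOI extends past a volume border; edge-replication padding applied")
    idx <- lapply(1:3, function(a) pmin(pmax(idx[[a]], 1L), d[a]))
  }
  volume[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Normalize a VOI by the patient's mean signal value
#'
#' Signal values are divided by the average signal of the patient's whole
#' CMRA volume, making patches dimensionless and removing per-patient
#' intensity scale.
#'
#' @param patch Raw 21^3 intensity patch.
#' @param patient_volume_mean Positive scalar: mean signal of the patient's
#'   volume.
#' @return The normalized patch.
#' @export
normalize_voi <- function(patch, patient_volume_mean) {
  if (!is.numeric(patient_volume_mean) || length(patient_volume_mean) != 1 ||
      !is.finite(patient_volume_mean) || patient_volume_mean <= 0) {
    abort("patient_volume_mean must be a positive finite scalar")
  }
  patch / patient_volume_mean
}

#' Mean signal of a patient volume
#'
#' By default the mean is taken over all voxels of the volume, including
#' background. With `mask` a logical array of the same shape, only masked
#' voxels contribute (e.g., a body mask).
#'
#' @param volume 3D intensity array.
#' @param mask Optional logical array, same shape.
#' @return Scalar mean.
#' @export
patient_volume_mean <- function(volume, mask = NULL) {
  if (is.null(mask)) mean(volume) else mean(volume[mask])
}

# 90-degree rotation of a 3D array about one axis, counterclockwise when
# viewed from the positive end of that axis, axes in index order.
rotate90_3d <- function(a, axis) {
  d <- dim(a)
  switch(axis,
    aperm(a, c(1, 3, 2))[, rev(seq_len(d[3])), , drop = FALSE],
    aperm(a, c(3, 2, 1))[, , rev(seq_len(d[1])), drop = FALSE],
    aperm(a, c(2, 1, 3))[rev(seq_len(d[2])), , , drop = FALSE]
  )
}

#' Four-fold rotation augmentation of positive VOIs
#'
#' Each VOI with significant stenosis is rotated 90 degrees about each axis,
#' yielding four training patches per positive (original plus three
#' rotations). Rotations permute voxels, so labels are unaffected; patient
#' and segment identity is inherited so augmented copies can never cross a
#' patient-level fold boundary.
#'
#' @param vois A VOI tibble (see [build_voi_table()]) whose rows all have
#'   `label == 1`; augmenting a negative VOI is an error.
#' @return A VOI tibble with 4x the rows and `augmentation_tag` set to
#'   `original` / `rot_x` / `rot_y` / `rot_z`.
#' @export
augment_positives <- function(vois) {
  if (nrow(vois) == 0) return(vois)
  if (any(vois$label != 1L)) {
    abort("only VOIs with significant stenosis (label 1) are augmented")
  }
  tags <- c("original", "rot_x", "rot_y", "rot_z")
  out <- purrr::map(1:4, function(k) {
    v <- vois
    v$augmentation_tag <- tags[k]
    if (k > 1) {
      v$values <- purrr::map(v$values, rotate90_3d, axis = k - 1L)
    }
    v
  })
  dplyr::bind_rows(out)
}

#' Extract and normalize VOIs for a table of segment records
#'
#' For each record, extracts the 21^3 patch centered on its annotation from
#' the corresponding patient volume and divides it by that patient's mean
#' signal value.
#'
#' @param records Segment records with `patient_id`, `segment_id`, `x`, `y`,
#'   `z` (0-based annotation) and `label`.
#' @param volumes Named list of 3D arrays keyed by `patient_id`.
#' @param border Border policy passed to [extract_voi()].
#' @return A VOI tibble: `patient_id`, `segment_id`, `label`,
#'   `augmentation_tag` (`"original"`), and a list-column `values` of
#'   normalized 21^3 arrays.
#' @export
build_voi_table <- function(records, volumes, border = "replicate") {
  missing_pat <- setdiff(unique(records$patient_id), names(volumes))
  if (length(missing_pat) > 0) {
    abort(paste0("no volume supplied for patient(s): ",
                 paste(missing_pat, collapse = ", ")))
  }
  means <- purrr::map_dbl(volumes, patient_volume_mean)
  values <- purrr::pmap(
    list(records$patient_id, records$x, records$y, records$z),
    function(pid, x, y, z) {
      raw <- extract_voi(volumes[[pid]], c(x, y, z), border = border)
      normalize_voi(raw, means[[pid]])
    }
  )
  tibble(
    patient_id = records$patient_id,
    segment_id = records$segment_id,
    label = as.integer(records$label),
    augmentation_tag = "original",
    values = values
  )
}

#' Stenosis-balanced patient-level fold assignment
#'
#' Assigns whole patients to folds so the per-fold counts of significantly
#' stenotic segments are as equal as patient granularity allows: patients are
#' sorted by descending positive-segment count (ties broken by a seeded
#' shuffle) and each is placed in the fold currently holding the fewest
#' positives.
#'
#' @param records Segment records with `patient_id` and `label`.
#' @param n_folds Number of folds (default 4).
#' @param seed Integer seed for tie-breaking.
#' @return A tibble `patient_id`, `fold` (0-based fold index), one row per
#'   patient.
#' @export
assign_folds <- function(records, n_folds = 4L, seed = 1L) {
  per_patient <- records |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_pos = sum(.data$label), .groups = "drop")
  if (nrow(per_patient) < n_folds) {
    abort("fewer patients than folds")
  }
  per_patient <- with_local_seed(seed, {
    per_patient[sample.int(nrow(per_patient)), , drop = FALSE]
  })
  per_patient <- per_patient[order(-per_patient$n_pos), , drop = FALSE]

  fold_pos <- rep(0L, n_folds)
  fold_n <- rep(0L, n_folds)
  fold_of <- integer(nrow(per_patient))
  for (i in seq_len(nrow(per_patient))) {
    # fewest positives; ties to the emptier fold, then lowest index
    cand <- which(fold_pos == min(fold_pos))
    cand <- cand[fold_n[cand] == min(fold_n[cand])]
    f <- cand[1]
    fold_of[i] <- f - 1L
    fold_pos[f] <- fold_pos[f] + per_patient$n_pos[i]
    fold_n[f] <- fold_n[f] + 1L
  }
  tibble(patient_id = per_patient$patient_id, fold = fold_of) |>
    dplyr::arrange(.data$patient_id)
}

#' Rotating train/validation/test splits from a four-fold assignment
#'
#' For rotation r in 0..3, fold r is the test set, fold (r + 1) mod 4 the
#' validation set, and the remaining two folds the training set; each fold
#' serves as test exactly once.
#'
#' @param assignment Tibble from [assign_folds()] with exactly 4 folds.
#' @return A tibble with one row per rotation: `rotation`, and list-columns
#'   `train`, `validation`, `test` holding patient-id vectors.
#' @export
make_cv_splits <- function(assignment) {
  folds <- sort(unique(assignment$fold))
  if (!identical(as.integer(folds), 0:3)) {
    abort("assignment must contain exactly folds 0..3")
  }
  patients_of <- function(f) assignment$patient_id[assignment$fold %in% f]
  purrr::map_dfr(0:3, function(r) {
    test_f <- r
    val_f <- (r + 1L) %% 4L
    train_f <- setdiff(0:3, c(test_f, val_f))
    tibble(
      rotation = r,
      train = list(patients_of(train_f)),
      validation = list(patients_of(val_f)),
      test = list(patients_of(test_f))
    )
  })
}
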