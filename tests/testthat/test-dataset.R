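records_fixture <- function() {
  tibble::tibble(
    patient_id = c("A", "A", "B", "C", "C"),
    segment_id = paste0("S", 1:5),
    label = c(1L, 0L, 0L, 1L, 0L),
    has_stent = c(TRUE, FALSE, TRUE, FALSE, FALSE),
    visible_on_cmra = c(TRUE, TRUE, TRUE, FALSE, TRUE)
  )
}

test_that("inclusion filter drops stented and invisible segments, preserves order, idempotent", {
  rec <- records_fixture()
  kept <- apply_inclusion_filter(rec)
  expect_identical(kept$segment_id, c("S2", "S5"))
  expect_identical(apply_inclusion_filter(kept), kept)

  clean <- dplyr::mutate(rec, has_stent = FALSE, visible_on_cmra = TRUE)
  expect_identical(apply_inclusion_filter(clean), clean)
  expect_equal(nrow(apply_inclusion_filter(rec[0, ])), 0L)
})

test_that("VOI extraction is centered, padded at borders, and bounds-checked", {
  withr::with_seed(8, vol <- array(rnorm(64^3), c(64, 64, 64)))
  p <- extract_voi(vol, c(31, 31, 31))
  expect_identical(p, vol[22:42, 22:42, 22:42])
  expect_identical(p[11, 11, 11], vol[32, 32, 32])

  expect_warning(pc <- extract_voi(vol, c(0, 0, 0)), "border")
  expect_identical(dim(pc), c(21L, 21L, 21L))
  expect_identical(pc[11, 11, 11], vol[1, 1, 1])  # centering survives padding
  expect_identical(pc[1, 1, 1], vol[1, 1, 1])     # replicated corner

  expect_error(extract_voi(vol, c(64, 0, 0)), "outside")
  expect_error(extract_voi(vol, c(0, 0, 0), border = "reject"), "border")
  expect_error(extract_voi(array(0, c(20, 64, 64)), c(5, 5, 5)), ">= 21")
})

test_that("normalization divides by the patient mean and is scale-equivariant", {
  patch <- array(2, c(21, 21, 21))
  expect_true(all(normalize_voi(patch, 2) == 1))
  expect_identical(normalize_voi(patch, 1), patch)
  patch[1, 1, 1] <- 4
  expect_setequal(unique(as.vector(normalize_voi(patch, 2))), c(1, 2))
  expect_error(normalize_voi(patch, 0), "positive")
  expect_error(normalize_voi(patch, -3), "positive")

  withr::with_seed(2, vol <- array(abs(rnorm(30^3)) + 0.1, c(30, 30, 30)))
  v1 <- normalize_voi(extract_voi(vol, c(15, 15, 15)), patient_volume_mean(vol))
  v2 <- normalize_voi(extract_voi(vol * 7, c(15, 15, 15)),
                      patient_volume_mean(vol * 7))
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("positive augmentation yields four rotated copies preserving voxels and identity", {
  withr::with_seed(3, v <- array(runif(21^3), c(21, 21, 21)))
  vois <- tibble::tibble(patient_id = "P1", segment_id = "P1_S01", label = 1L,
                         augmentation_tag = "original", values = list(v))
  aug <- augment_positives(vois)
  expect_equal(nrow(aug), 4L)
  expect_identical(aug$augmentation_tag, c("original", "rot_x", "rot_y", "rot_z"))
  expect_true(all(aug$patient_id == "P1"))
  for (i in 2:4) {
    expect_identical(sort(as.vector(aug$values[[i]])), sort(as.vector(v)))
    expect_false(identical(aug$values[[i]], v))
  }
  expect_error(augment_positives(dplyr::mutate(vois, label = 0L)), "label 1")
})

test_that("four applications of any 90-degree rotation recover the original", {
  withr::with_seed(4, v <- array(rnorm(21^3), c(21, 21, 21)))
  for (axis in 1:3) {
    r <- v
    for (i in 1:4) r <- stenonet:::rotate90_3d(r, axis)
    expect_identical(r, v)
  }
})

test_that("a spherically symmetric patch is invariant under all axis rotations", {
  g <- (seq_len(21) - 11)^2
  sphere <- exp(-outer(outer(g, g, "+"), g, "+") / 50)
  vois <- tibble::tibble(patient_id = "P", segment_id = "S", label = 1L,
                         augmentation_tag = "original", values = list(sphere))
  aug <- augment_positives(vois)
  for (i in 2:4) expect_equal(aug$values[[i]], sphere, tolerance = 1e-15)
})

test_that("VOI table extraction normalizes per patient and tags provenance", {
  cfg <- phantom_config(n_patients = 2, segments_per_patient = 3, seed = 6)
  ds <- generate_phantom_dataset(cfg)
  vois <- build_voi_table(ds$truth, ds$volumes)
  expect_equal(nrow(vois), 6L)
  expect_true(all(vois$augmentation_tag == "original"))
  i <- 4L
  raw <- extract_voi(ds$volumes[[vois$patient_id[i]]],
                     c(ds$truth$x[i], ds$truth$y[i], ds$truth$z[i]))
  expect_equal(vois$values[[i]],
               raw / mean(ds$volumes[[vois$patient_id[i]]]),
               tolerance = 1e-15)
  expect_error(build_voi_table(ds$truth, ds$volumes["P001"]), "no volume")
})

test_that("fold assignment balances positives at patient granularity", {
  # forced balance: four patients, one positive each
  rec <- tibble::tibble(patient_id = sprintf("Q%d", 1:4),
                        segment_id = sprintf("Q%d_S1", 1:4),
                        label = 1L)
  fa <- assign_folds(rec, seed = 1)
  expect_setequal(fa$fold, 0:3)

  # 84 positives over patients carrying at most 3 each
  n_pos_per_patient <- c(rep(3L, 20), rep(2L, 9), rep(1L, 6), rep(0L, 15))
  stopifnot(sum(n_pos_per_patient) == 84)
  rows <- purrr::map_dfr(seq_along(n_pos_per_patient), function(i) {
    k <- n_pos_per_patient[i]
    tibble::tibble(patient_id = sprintf("P%02d", i),
                   segment_id = sprintf("P%02d_S%02d", i, seq_len(k + 2)),
                   label = c(rep(1L, k), 0L, 0L))
  })
  for (seed in c(1, 7, 99)) {
    fa <- assign_folds(rows, seed = seed)
    expect_equal(nrow(fa), length(n_pos_per_patient))
    expect_false(any(duplicated(fa$patient_id)))
    per_fold <- rows |>
      dplyr::inner_join(fa, by = "patient_id") |>
      dplyr::group_by(fold) |>
      dplyr::summarise(pos = sum(label), .groups = "drop")
    expect_equal(sum(per_fold$pos), 84L)
    expect_true(all(per_fold$pos >= 18 & per_fold$pos <= 24))
    expect_lte(max(per_fold$pos) - min(per_fold$pos), max(n_pos_per_patient))
  }
  expect_identical(assign_folds(rows, seed = 5), assign_folds(rows, seed = 5))
  expect_error(assign_folds(rec[1:2, ]), "fewer patients")
})

test_that("cross-validation splits rotate test/validation/train as a partition", {
  rec <- tibble::tibble(patient_id = sprintf("P%02d", 1:12),
                        segment_id = sprintf("P%02d_S1", 1:12),
                        label = rep(c(1L, 0L, 0L), 4))
  fa <- assign_folds(rec, seed = 2)
  splits <- make_cv_splits(fa)
  expect_equal(nrow(splits), 4L)
  all_pat <- sort(rec$patient_id)
  for (r in seq_len(4)) {
    trio <- c(splits$train[[r]], splits$validation[[r]], splits$test[[r]])
    expect_identical(sort(trio), all_pat)          # partition
    expect_equal(anyDuplicated(trio), 0L)          # pairwise disjoint
    expect_identical(sort(splits$validation[[r]]),
                     sort(fa$patient_id[fa$fold == (splits$rotation[r] + 1) %% 4]))
  }
  test_sets <- unlist(splits$test)
  expect_identical(sort(test_sets), all_pat)       # each fold tests once
})
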