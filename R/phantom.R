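#' Configuration for the synthetic vessel phantom generator
#'
#' The phantom generator emulates the data substrate the classifier assumes:
#' bright tubular vessels on a darker background, with focal luminal narrowing
#' (>= 50% diameter reduction defining the positive class), Gaussian blur and
#' additive noise, grouped into synthetic "patients" that differ by a
#' multiplicative intensity scale so patient-mean normalization is exercised.
#'
#' @param n_patients Number of synthetic patients.
#' @param segments_per_patient Number of vessel segments (tubes) per patient
#'   volume. Must be between 1 and 18.
#' @param stenosis_prevalence Probability that a segment carries a significant
#'   stenosis (fraction in `[0, 1]`).
#' @param vessel_radius Tube radius in voxels (> 0).
#' @param lumen_intensity Signal value inside the vessel lumen (arbitrary
#'   units). Must exceed `background_intensity`.
#' @param background_intensity Signal value outside the lumen.
#' @param stenosis_fraction_range Length-2 numeric: range of the diameter
#'   reduction fraction for positive segments. The lower bound must be >= 0.5
#'   so every positive meets the >= 50% definition of significant stenosis.
#' @param blur_sigma Standard deviation in voxels of the isotropic Gaussian
#'   blur applied after rendering (>= 0; 0 disables blurring).
#' @param noise_sigma Scale of the additive noise in signal units (>= 0).
#' @param noise_model `"gaussian"` (additive) or `"rician"` (magnitude of a
#'   complex Gaussian perturbation, the physical MR magnitude-noise model).
#' @param volume_shape Integer triple, each >= 21 voxels.
#' @param curvature_max Maximum quadratic centerline perturbation in voxels
#'   (mild curvature; 0 gives straight tubes).
#' @param stenosis_extent_range Integer range (voxels along the centerline) of
#'   the focal narrowed region.
#' @param stenosis_intensity_drop Optional co-located fractional intensity drop
#'   inside the narrowed region (0 disables; 0.3 dims the residual lumen 30%).
#' @param mild_narrowing_prob Probability that a negative segment carries a
#'   sub-significant narrowing (diameter reduction drawn in `[0.25, 0.45]`).
#' @param patient_scale_sd Log-scale SD of the per-patient multiplicative
#'   intensity factor (drawn around 1.0).
#' @param seed Integer seed; identical config + seed gives bit-identical output.
#'
#' @return A validated `phantom_config` object (a named list).
#' @export
phantom_config <- function(n_patients = 60L,
                           segments_per_patient = 12L,
                           stenosis_prevalence = 0.1,
                           vessel_radius = 3.0,
                           lumen_intensity = 1.0,
                           background_intensity = 0.1,
                           stenosis_fraction_range = c(0.5, 1.0),
                           blur_sigma = 0.5,
                           noise_sigma = 0.02,
                           noise_model = c("gaussian", "rician"),
                           volume_shape = c(64L, 64L, 64L),
                           curvature_max = 2.0,
                           stenosis_extent_range = c(3L, 5L),
                           stenosis_intensity_drop = 0,
                           mild_narrowing_prob = 0.05,
                           patient_scale_sd = 0.1,
                           seed = 1L) {
  noise_model <- match.arg(noise_model)
  cfg <- list(
    n_patients = as.integer(n_patients),
    segments_per_patient = as.integer(segments_per_patient),
    stenosis_prevalence = stenosis_prevalence,
    vessel_radius = vessel_radius,
    lumen_intensity = lumen_intensity,
    background_intensity = background_intensity,
    stenosis_fraction_range = as.numeric(stenosis_fraction_range),
    blur_sigma = blur_sigma,
    noise_sigma = noise_sigma,
    noise_model = noise_model,
    volume_shape = as.integer(volume_shape),
    curvature_max = curvature_max,
    stenosis_extent_range = as.integer(stenosis_extent_range),
    stenosis_intensity_drop = stenosis_intensity_drop,
    mild_narrowing_prob = mild_narrowing_prob,
    patient_scale_sd = patient_scale_sd,
    seed = as.integer(seed)
  )
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  stopifnot_msg(cfg$n_patients >= 1, "n_patients must be >= 1")
  stopifnot_msg(cfg$segments_per_patient >= 1 && cfg$segments_per_patient <= 18,
                "segments_per_patient must be in [1, 18]")
  stopifnot_msg(cfg$stenosis_prevalence >= 0 && cfg$stenosis_prevalence <= 1,
                "stenosis_prevalence must be a fraction in [0, 1]")
  stopifnot_msg(cfg$vessel_radius > 0, "vessel_radius must be > 0")
  stopifnot_msg(cfg$lumen_intensity > cfg$background_intensity,
                "lumen_intensity must exceed background_intensity")
  stopifnot_msg(length(cfg$stenosis_fraction_range) == 2 &&
                  cfg$stenosis_fraction_range[1] >= 0.5 &&
                  cfg$stenosis_fraction_range[2] <= 1 &&
                  diff(cfg$stenosis_fraction_range) >= 0,
                "stenosis_fraction_range must lie in [0.5, 1] (positives must be >= 50% diameter reduction)")
  stopifnot_msg(cfg$blur_sigma >= 0, "blur_sigma must be >= 0")
  stopifnot_msg(cfg$noise_sigma >= 0, "noise_sigma must be >= 0")
  stopifnot_msg(length(cfg$volume_shape) == 3 && all(cfg$volume_shape >= 21),
                "volume_shape must be three integers, each >= 21 (a 21^3 patch must fit)")
  invisible(cfg)
}

stopifnot_msg <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
}

# Evaluate a seeded expression without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Cross-section slot grid for placing non-overlapping tubes. The margin
# keeps a 21^3 patch around any centerline annotation inside the volume.
tube_slots <- function(shape, radius, curvature_max) {
  margin <- max(ceiling(radius + curvature_max) + 2, 11)
  spacing <- ceiling(2 * (radius + curvature_max)) + 3
  ys <- seq(margin + 1, shape[2] - margin, by = spacing)
  zs <- seq(margin + 1, shape[3] - margin, by = spacing)
  slots <- expand.grid(y = ys, z = zs)
  slots[order(slots$y, slots$z), , drop = FALSE]
}

# Separable Gaussian blur with edge-replication padding.
gaussian_blur3 <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  r <- max(1L, ceiling(3 * sigma))
  kern <- exp(-(((-r):r)^2) / (2 * sigma^2))
  kern <- kern / sum(kern)
  d <- dim(vol)
  for (axis in 1:3) {
    n <- d[axis]
    acc <- array(0, d)
    for (j in seq_along(kern)) {
      idx <- pmin(pmax(seq_len(n) + (j - r - 1L), 1L), n)
      acc <- acc + kern[j] * switch(axis,
        vol[idx, , , drop = FALSE],
        vol[, idx, , drop = FALSE],
        vol[, , idx, drop = FALSE]
      )
    }
    vol <- acc
  }
  vol
}

#' Generate one synthetic patient volume with its ground-truth table
#'
#' Renders `segments_per_patient` tubular vessels along the x axis of a single
#' volume (one per cross-section slot), each with a mildly curved centerline.
#' Positive segments get a focal radius reduction drawn from
#' `stenosis_fraction_range`, centered at the annotation coordinate; negative
#' segments are annotated at a uniformly drawn centerline point. The volume is
#' then scaled by a per-patient intensity factor, blurred, and corrupted by
#' noise (clamped at zero, as MR magnitude data are non-negative).
#'
#' @param config A [phantom_config()].
#' @param patient_seed Integer seed for this patient's randomness.
#' @param patient_id Identifier recorded in the truth table.
#' @return A list with `volume` (3D array) and `truth`, a tibble with one row
#'   per segment: `patient_id`, `segment_id`, `scct_segment`, `x`, `y`, `z`
#'   (0-based annotation voxel), `stenosis_fraction` (true diameter reduction),
#'   `label`, `has_stent`, `visible_on_cmra`.
#' @export
generate_patient_volume <- function(config, patient_seed, patient_id = "P1") {
  validate_phantom_config(config)
  shape <- config$volume_shape
  slots <- tube_slots(shape, config$vessel_radius, config$curvature_max)
  if (nrow(slots) < config$segments_per_patient) {
    abort("volume_shape too small to hold segments_per_patient non-overlapping tubes")
  }
  if (shape[1] < 21) abort("volume_shape too small to contain a 21^3 patch")

  with_local_seed(patient_seed, {
    nx <- shape[1]
    xg <- seq_len(nx)
    # annotations must sit where a (mostly) interior 21^3 patch exists
    x_lo <- 11L
    x_hi <- nx - 10L
    patient_scale <- exp(rnorm(1, 0, config$patient_scale_sd))

    vol <- array(config$background_intensity, shape)
    truths <- vector("list", config$segments_per_patient)

    for (s in seq_len(config$segments_per_patient)) {
      y0 <- slots$y[s]
      z0 <- slots$z[s]
      ay <- runif(1, -config$curvature_max, config$curvature_max)
      az <- runif(1, -config$curvature_max, config$curvature_max)
      xm <- (1 + nx) / 2
      cy <- y0 + ay * ((xg - xm) / (nx / 2))^2
      cz <- z0 + az * ((xg - xm) / (nx / 2))^2

      is_pos <- runif(1) < config$stenosis_prevalence
      frac <- 0
      if (is_pos) {
        frac <- runif(1, config$stenosis_fraction_range[1],
                      config$stenosis_fraction_range[2])
      } else if (runif(1) < config$mild_narrowing_prob) {
        frac <- runif(1, 0.25, 0.45)
      }

      xa <- sample(seq(x_lo, x_hi), 1)
      radius <- rep(config$vessel_radius, nx)
      lumen_gain <- rep(1, nx)
      if (frac > 0) {
        extent <- sample(seq(config$stenosis_extent_range[1],
                             config$stenosis_extent_range[2]), 1)
        half <- extent / 2
        sel <- abs(xg - xa) <= half
        taper <- cos(pi * (xg[sel] - xa) / (2 * half))^2
        radius[sel] <- config$vessel_radius * (1 - frac * taper)
        lumen_gain[sel] <- 1 - config$stenosis_intensity_drop * taper
      }

      # rasterize: local block around the tube only
      span <- ceiling(config$vessel_radius + config$curvature_max) + 1
      yy <- seq(max(1, y0 - span), min(shape[2], y0 + span))
      zz <- seq(max(1, z0 - span), min(shape[3], z0 + span))
      for (xi in xg) {
        r2 <- radius[xi]^2
        if (r2 <= 0) next
        dy2 <- (yy - cy[xi])^2
        dz2 <- (zz - cz[xi])^2
        inside <- outer(dy2, dz2, "+") < r2
        if (any(inside)) {
          blk <- vol[xi, yy, zz]
          blk[inside] <- config$lumen_intensity * lumen_gain[xi]
          vol[xi, yy, zz] <- blk
        }
      }

      truths[[s]] <- tibble(
        patient_id = patient_id,
        segment_id = sprintf("%s_S%02d", patient_id, s),
        scct_segment = s,
        x = xa - 1L,                       # 0-based voxel coordinates
        y = as.integer(round(cy[xa])) - 1L,
        z = as.integer(round(cz[xa])) - 1L,
        stenosis_fraction = frac,
        label = as.integer(frac >= 0.5),
        has_stent = FALSE,
        visible_on_cmra = TRUE
      )
    }

    vol <- vol * patient_scale
    vol <- gaussian_blur3(vol, config$blur_sigma)
    if (config$noise_sigma > 0) {
      n <- length(vol)
      if (config$noise_model == "rician") {
        vol <- sqrt((vol + rnorm(n, 0, config$noise_sigma))^2 +
                      rnorm(n, 0, config$noise_sigma)^2)
        dim(vol) <- shape
      } else {
        vol <- vol + array(rnorm(n, 0, config$noise_sigma), shape)
      }
    }
    vol[vol < 0] <- 0

    list(volume = vol, truth = dplyr::bind_rows(truths))
  })
}

#' Generate a full synthetic dataset of patients
#'
#' @param config A [phantom_config()]; `config$n_patients` volumes are
#'   generated with per-patient seeds derived from `config$seed`.
#' @return A list with `volumes` (named list of 3D arrays, one per patient)
#'   and `truth` (tibble of all segment records, columns as in
#'   [generate_patient_volume()]).
#' @export
generate_phantom_dataset <- function(config) {
  validate_phantom_config(config)
  ids <- sprintf("P%03d", seq_len(config$n_patients))
  out <- purrr::map2(seq_len(config$n_patients), ids, function(i, id) {
    generate_patient_volume(config, patient_seed = config$seed + 101L * i,
                            patient_id = id)
  })
  list(
    volumes = setNames(purrr::map(out, "volume"), ids),
    truth = dplyr::bind_rows(purrr::map(out, "truth"))
  )
}

#' Build a segment-table fixture with prescribed exclusion-filter arithmetic
#'
#' Emits a coronary segment table whose counts reconcile exactly:
#' `n_total_visible_on_ica` records of which `n_stented` carry stents,
#' `n_invisible` are not visible on CMRA (both excluded by the inclusion
#' filter), and `n_stenotic` of the retained records are significantly
#' stenotic. Grades for stenotic records are drawn from the observed
#' all-dataset category proportions 37:40:7 over 50-69% / 70-99% / 100%;
#' retained negatives are split 852:15 over 0-24% / 25-49%.
#'
#' @param n_total_visible_on_ica Total segment count (ICA-visible).
#' @param n_stented Number of stented records (excluded downstream).
#' @param n_invisible Number of records not visible on CMRA (excluded).
#' @param n_stenotic Number of significantly stenotic records among the
#'   retained (non-stented, visible) records.
#' @param seed Integer seed.
#' @param n_patients Number of synthetic patients the records are spread over.
#' @return A tibble of segment records with columns `patient_id`,
#'   `segment_id`, `scct_segment`, `x`, `y`, `z`, `stenosis_percent_category`,
#'   `label`, `has_stent`, `visible_on_cmra`.
#' @export
generate_dataset_fixture <- function(n_total_visible_on_ica,
                                     n_stented,
                                     n_invisible,
                                     n_stenotic,
                                     seed = 1L,
                                     n_patients = 75L) {
  n_total <- as.integer(n_total_visible_on_ica)
  n_stented <- as.integer(n_stented)
  n_invisible <- as.integer(n_invisible)
  n_stenotic <- as.integer(n_stenotic)
  if (n_stented + n_invisible > n_total) {
    abort("inconsistent counts: n_stented + n_invisible exceeds the total")
  }
  n_retained <- n_total - n_stented - n_invisible
  if (n_stenotic > n_retained) {
    abort("inconsistent counts: n_stenotic exceeds the retained record count")
  }

  with_local_seed(seed, {
    patient_id <- sprintf("P%03d", rep_len(seq_len(n_patients), n_total))
    # order records patient-major so scct segments cycle within patient
    patient_id <- sort(patient_id)
    idx_within <- sequence(as.integer(table(patient_id)))
    scct <- ((idx_within - 1L) %% 18L) + 1L

    status <- rep("retained", n_total)
    excl <- sample.int(n_total, n_stented + n_invisible)
    status[excl[seq_len(n_stented)]] <- "stented"
    if (n_invisible > 0) {
      status[excl[n_stented + seq_len(n_invisible)]] <- "invisible"
    }
    retained_idx <- which(status == "retained")
    stenotic_idx <- if (n_stenotic > 0) sample(retained_idx, n_stenotic) else integer(0)

    grade <- rep(NA_character_, n_total)
    grade[stenotic_idx] <- sample(c("50-69", "70-99", "100"), n_stenotic,
                                  replace = TRUE, prob = c(37, 40, 7))
    neg_idx <- setdiff(seq_len(n_total), stenotic_idx)
    grade[neg_idx] <- sample(c("0-24", "25-49"), length(neg_idx),
                             replace = TRUE, prob = c(852, 15))

    tibble(
      patient_id = patient_id,
      segment_id = sprintf("%s_S%02d", patient_id, idx_within),
      scct_segment = as.integer(scct),
      x = sample(10:53, n_total, replace = TRUE),
      y = sample(10:53, n_total, replace = TRUE),
      z = sample(10:53, n_total, replace = TRUE),
      stenosis_percent_category = factor(grade, levels = stenosis_grade_levels()),
      label = as.integer(grade %in% c("50-69", "70-99", "100")),
      has_stent = status == "stented",
      visible_on_cmra = status != "invisible"
    )
  })
}

#' Stenosis grade categories
#'
#' Diameter-reduction categories used in segment tables; >= 50% defines the
#' positive class.
#' @return Character vector of the five category labels.
#' @export
stenosis_grade_levels <- function() {
  c("0-24", "25-49", "50-69", "70-99", "100")
}
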