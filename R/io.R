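#' Read a 3D volume from a NIfTI-1 file
#'
#' Intensities are returned as stored. Axis order follows the file's voxel
#' grid (i, j, k); all package coordinates are 0-based voxel indices into
#' that grid. 4D (or higher) images are rejected.
#'
#' @param path Path to a NIfTI-1 file.
#' @return A 3D numeric array with attribute `voxel_indexing = "0-based"`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3) {
    abort(paste0("expected a 3D volume, got ", length(d), " dimensions"))
  }
  vol <- array(as.numeric(img), d)
  attr(vol, "voxel_indexing") <- "0-based"
  vol
}

#' Write a 3D volume to a NIfTI-1 file
#'
#' @param volume 3D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (length(dim(volume)) != 3) abort("volume must be a 3D array")
  attr(volume, "voxel_indexing") <- NULL
  RNifti::writeNifti(RNifti::asNifti(volume), path)
  invisible(path)
}

config_sections <- c("phantom", "network", "training")

config_builders <- function() {
  list(phantom = phantom_config, network = network_config,
       training = train_config)
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file with optional top-level sections `phantom`, `network`
#' and `training`; omitted sections and keys take the package defaults
#' (batch size 4, max 50 epochs, learning rate 1e-4, momentum 0.9, Gaussian
#' SD 0.75, ...). Unknown sections or keys are rejected, and every section is
#' validated by its constructor, so invariant violations (e.g., a pooling
#' setup that breaks the 21 -> 11 -> 6 shape contract) fail with a message
#' naming the constraint.
#'
#' @param path Path to a YAML file. An empty file yields all defaults.
#' @return A named list of validated configs: `phantom`, `network`,
#'   `training`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), config_sections)
  if (length(unknown) > 0) {
    abort(paste0("unknown config section(s): ", paste(unknown, collapse = ", ")))
  }
  builders <- config_builders()
  out <- lapply(config_sections, function(sec) {
    args <- raw[[sec]] %||% list()
    known <- names(formals(builders[[sec]]))
    bad <- setdiff(names(args), known)
    if (length(bad) > 0) {
      abort(paste0("unknown key(s) in section '", sec, "': ",
                   paste(bad, collapse = ", ")))
    }
    do.call(builders[[sec]], args)
  })
  setNames(out, config_sections)
}

#' Write a configuration list back to YAML
#'
#' Inverse of [load_config()]: `load_config(dump_config(cfg, f))` reproduces
#' the same values.
#'
#' @param configs Named list as returned by [load_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(configs, path) {
  plain <- lapply(configs, function(x) lapply(unclass(x), function(v) {
    if (is.numeric(v) && length(v) > 1) as.list(v) else v
  }))
  yaml::write_yaml(plain, path)
  invisible(path)
}

checkpoint_tensor_order <- list(
  c("conv1", "W"), c("conv1", "b"),
  c("bn1", "gamma"), c("bn1", "beta"), c("bn1", "run_mean"), c("bn1", "run_var"),
  c("conv2", "W"), c("conv2", "b"),
  c("bn2", "gamma"), c("bn2", "beta"), c("bn2", "run_mean"), c("bn2", "run_var"),
  c("fc", "W"), c("fc", "b")
)

#' Save network parameters to a checkpoint file
#'
#' The file starts with a single JSON header line (config echo, epoch, seed,
#' tensor names and shapes) followed by the tensor values as little-endian
#' IEEE doubles in the declared order. Reloading is bit-stable: a forward
#' pass in eval mode with reloaded parameters reproduces scores exactly.
#'
#' @param params A `network_params` object.
#' @param config The [network_config()] the parameters belong to.
#' @param path Output path.
#' @param epoch,seed Optional provenance recorded in the header.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(params, config, path, epoch = NA, seed = NA) {
  tensors <- lapply(checkpoint_tensor_order, function(p) {
    v <- params[[p[1]]][[p[2]]]
    list(name = paste(p, collapse = "."),
         dims = if (is.matrix(v)) dim(v) else length(v))
  })
  header <- jsonlite::toJSON(list(
    format = "stenonet-checkpoint", format_version = 1L,
    config = unclass(config), epoch = epoch, seed = seed,
    tensors = tensors
  ), auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(header, "\n")), con)
  for (p in checkpoint_tensor_order) {
    writeBin(as.numeric(params[[p[1]]][[p[2]]]), con, endian = "little")
  }
  invisible(path)
}

#' Load network parameters from a checkpoint file
#'
#' @param path Checkpoint written by [save_checkpoint()].
#' @return A list with `params` (a `network_params`), `config` (a
#'   `network_config`), `epoch`, `seed`.
#' @export
load_checkpoint <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  nl <- which(bytes == as.raw(10L))[1]
  if (is.na(nl)) abort("not a stenonet checkpoint: missing header line")
  header <- tryCatch(
    jsonlite::fromJSON(rawToChar(bytes[seq_len(nl - 1L)]),
                       simplifyVector = TRUE),
    error = function(e) abort("not a stenonet checkpoint: unreadable header"))
  if (!identical(header$format, "stenonet-checkpoint")) {
    abort("not a stenonet checkpoint")
  }
  cfg <- do.call(network_config, as.list(header$config))
  vals <- readBin(bytes[(nl + 1L):length(bytes)], "double",
                  n = (length(bytes) - nl) / 8, endian = "little")
  params <- list()
  offset <- 0L
  for (i in seq_along(checkpoint_tensor_order)) {
    p <- checkpoint_tensor_order[[i]]
    dims <- header$tensors$dims[[i]]
    len <- prod(dims)
    v <- vals[offset + seq_len(len)]
    if (length(dims) == 2) v <- matrix(v, dims[1], dims[2])
    params[[p[1]]][[p[2]]] <- v
    offset <- offset + len
  }
  list(params = structure(params, class = "network_params"),
       config = cfg,
       epoch = header$epoch, seed = header$seed)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a pipeline stage: the full config
#' echo, all seeds, the package version, MD5 digests of input and output
#' files, and a timestamp.
#'
#' @param path Output JSON path.
#' @param configs Named list of configs (any subset of phantom / network /
#'   training).
#' @param seeds Named list or vector of seeds used.
#' @param inputs,outputs Character vectors of file paths to digest.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, configs = list(), seeds = list(),
                           inputs = character(0), outputs = character(0)) {
  digest_files <- function(paths) {
    paths <- paths[file.exists(paths)]
    if (length(paths) == 0) return(setNames(list(), character(0)))
    as.list(tools::md5sum(paths))
  }
  manifest <- list(
    package = "stenonet",
    version = as.character(utils::packageVersion("stenonet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    configs = lapply(configs, unclass),
    seeds = seeds,
    input_digests = digest_files(inputs),
    output_digests = digest_files(outputs)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
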