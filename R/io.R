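# NIfTI-1 / JSON / YAML input-output with provenance sidecars. Times are
# seconds on disk; voxel indexing is 1-based in R and world coordinates go
# through the NIfTI affine.

.writeSidecar <- function(path, x) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

.readSidecar <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

.sidecarPath <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Write a 3D/4D array as NIfTI-1
#'
#' @param data numeric array.
#' @param path output path (.nii or .nii.gz).
#' @param voxelSize voxel edge lengths in mm (length 1 or 3).
#' @return The path, invisibly.
#' @export
writeNiftiVolume <- function(data, path, voxelSize = 1) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  img <- RNifti::asNifti(data + 0)   # coerce logical/integer to numeric
  RNifti::pixdim(img) <- c(voxelSize, rep(1, length(dim(data)) - 3L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume as a plain array
#'
#' @param path input path.
#' @return Numeric array with attribute \code{voxelSize} (mm).
#' @export
readNiftiVolume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "voxelSize") <- RNifti::pixdim(img)[1:3]
  out
}

#' Write a dynamic image with its frame-timing sidecar
#'
#' The 4D volume goes to \code{path}; frame starts/durations (seconds from
#' injection) and the decay-correction state go to the JSON sidecar next to
#' it.
#'
#' @param img a [DynamicImage-class].
#' @param path output path (.nii or .nii.gz).
#' @return The path, invisibly.
#' @export
writeDynamicImage <- function(img, path) {
  stopifnot(is(img, "DynamicImage"))
  writeNiftiVolume(img@data, path, img@voxelSize)
  .writeSidecar(.sidecarPath(path),
                list(frame_start_s = frameStart(img@scheme),
                     frame_duration_s = frameDuration(img@scheme),
                     decay_corrected = img@decayCorrected,
                     units = "kBq/ml",
                     decay_reference = "injection (t = 0)"))
  invisible(path)
}

#' Read a dynamic image and its frame-timing sidecar
#'
#' @param path the NIfTI path written by [writeDynamicImage()].
#' @return A [DynamicImage-class].
#' @export
readDynamicImage <- function(path) {
  arr <- readNiftiVolume(path)
  sc <- .readSidecar(.sidecarPath(path))
  vs <- attr(arr, "voxelSize")
  attr(arr, "voxelSize") <- NULL
  dynamicImage(arr, frameScheme(sc$frame_start_s, sc$frame_duration_s),
               vs, isTRUE(sc$decay_corrected))
}

#' Write a parametric map with its provenance sidecar
#'
#' @param map a [ParametricMap-class].
#' @param path output path (.nii or .nii.gz).
#' @param voxelSize voxel edge lengths in mm.
#' @return The path, invisibly.
#' @export
writeParametricMap <- function(map, path, voxelSize = 1) {
  stopifnot(is(map, "ParametricMap"))
  writeNiftiVolume(map@values, path, voxelSize)
  .writeSidecar(.sidecarPath(path),
                c(list(quantity = map@quantity, units = map@units),
                  map@provenance))
  invisible(path)
}

#' Read a parametric map written by [writeParametricMap()]
#'
#' @param path the NIfTI path.
#' @return A [ParametricMap-class].
#' @export
readParametricMap <- function(path) {
  arr <- readNiftiVolume(path)
  sc <- .readSidecar(.sidecarPath(path))
  attr(arr, "voxelSize") <- NULL
  new("ParametricMap", values = arr, quantity = sc$quantity,
      units = sc$units,
      provenance = sc[setdiff(names(sc), c("quantity", "units"))])
}

#' Write a phantom specification as YAML
#'
#' @param spec a [PhantomSpec-class].
#' @param path output .yaml path.
#' @return The path, invisibly.
#' @export
writePhantomSpec <- function(spec, path) {
  stopifnot(is(spec, "PhantomSpec"))
  lesions <- lapply(spec@lesions, function(l) {
    if (!is.null(l$profile)) l$profile <- as.list(l$profile)
    l
  })
  yaml::write_yaml(list(
    grid_shape = spec@gridShape, voxel_size_mm = spec@voxelSizeMm,
    brain_radius_mm = spec@brainRadiusMm, wm_radius_mm = spec@wmRadiusMm,
    frame_scheme = spec@frameSchemeSpec, tissue_params = spec@tissueParams,
    lesions = lesions, blood_voxels = spec@bloodVoxels,
    noise_scale = spec@noiseScale, seed = spec@seed,
    injected_dose_MBq = spec@injectedDoseMBq,
    body_weight_kg = spec@bodyWeightKg, cbf_params = spec@cbfParams,
    asl_params = spec@aslParams,
    dti_params = lapply(spec@dtiParams, as.numeric)), path)
  invisible(path)
}

#' Read a phantom specification from YAML
#'
#' @param path .yaml path written by [writePhantomSpec()] (missing fields
#'   fall back to the [phantomSpec()] defaults).
#' @return A [PhantomSpec-class].
#' @export
readPhantomSpec <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  take <- function(from, to = from) if (!is.null(y[[from]])) args[[to]] <<- y[[from]]
  take("grid_shape", "gridShape"); take("voxel_size_mm", "voxelSizeMm")
  take("brain_radius_mm", "brainRadiusMm"); take("wm_radius_mm", "wmRadiusMm")
  take("frame_scheme", "frameSchemeSpec"); take("tissue_params", "tissueParams")
  take("blood_voxels", "bloodVoxels"); take("noise_scale", "noiseScale")
  take("seed"); take("injected_dose_MBq", "injectedDoseMBq")
  take("body_weight_kg", "bodyWeightKg"); take("cbf_params", "cbfParams")
  take("asl_params", "aslParams")
  if (!is.null(y$dti_params)) args$dtiParams <- y$dti_params
  if (!is.null(y$lesions))
    args$lesions <- lapply(y$lesions, function(l) {
      l$center <- as.numeric(l$center)
      if (!is.null(l$profile)) l$profile <- as.data.frame(l$profile)
      l
    })
  do.call(phantomSpec, args)
}
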