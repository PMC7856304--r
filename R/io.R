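## tiny polynomial rolling hash for provenance records (no external
## digest dependency; collision resistance is not a goal here)
.fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Read co-registered volumes into a multi-contrast image
#'
#' All volumes must be NIfTI files on an identical grid (same dimensions
#' and voxel size); the tool performs no registration or resampling, so a
#' mismatch is a hard error instructing co-registration.  The affine is
#' taken from the first volume.
#'
#' @param paths character vector of NIfTI paths.
#' @param roles channel roles (`"t1w"`, `"t2w"`, `"flair"`, `"other"`),
#'   recycled.
#' @param mask optional path to a binary brain-mask NIfTI.
#' @return a [MultiContrastImage-class].
#' @export
readVolumes <- function(paths, roles = "other", mask = NULL) {
  if (!length(paths)) stop("at least one input volume is required")
  roles <- rep_len(roles, length(paths))
  vols <- lapply(paths, RNifti::readNifti)
  dims <- lapply(vols, dim)
  pix <- lapply(vols, function(v) RNifti::pixdim(v))
  for (i in seq_along(vols)[-1]) {
    if (!identical(dims[[i]], dims[[1L]]) ||
        max(abs(pix[[i]] - pix[[1L]])) > 1e-6)
      stop("volume ", paths[i], " does not match the grid of ", paths[1L],
           "; co-register and resample the inputs before segmentation")
  }
  D <- vapply(vols, function(v) as.numeric(v), numeric(prod(dims[[1L]])))
  nBad <- sum(!is.finite(D))
  if (nBad > 0) stop(nBad, " non-finite voxel values in the input volumes")
  d <- length(dims[[1L]])
  aff <- tryCatch(unclass(RNifti::xform(vols[[1L]])),
                  error = function(e) NULL)
  geom <- gridGeometry(dims[[1L]], pix[[1L]][seq_len(d)], affine = aff)
  maskVec <- if (is.null(mask)) NULL
             else as.numeric(RNifti::readNifti(mask)) > 0
  multiContrastImage(D, geom, mask = maskVec, roles = roles)
}

## write a per-voxel vector as a NIfTI volume on the given geometry
writeVolumeNifti <- function(values, geometry, path) {
  arr <- array(as.numeric(values), geometry@dim)
  img <- RNifti::asNifti(arr)
  pd <- RNifti::pixdim(img)
  pd[seq_along(geometry@voxelSize)] <- geometry@voxelSize
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write segmentation outputs
#'
#' Writes the label map (integer NIfTI), lesion posterior (float NIfTI),
#' lesion mask (binary NIfTI), a per-structure volume table (CSV, mm^3,
#' lesions included) and a JSON provenance record.
#'
#' @param result a [SegmentationResult-class].
#' @param geometry the image [GridGeometry-class].
#' @param outdir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
writeOutputs <- function(result, geometry, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(labelMap = file.path(outdir, "label_map.nii.gz"),
             posterior = file.path(outdir, "lesion_posterior.nii.gz"),
             lesionMask = file.path(outdir, "lesion_mask.nii.gz"),
             volumes = file.path(outdir, "volumes.csv"),
             provenance = file.path(outdir, "provenance.json"))
  writeVolumeNifti(result@labelMap, geometry, paths[["labelMap"]])
  writeVolumeNifti(result@lesionPosterior, geometry, paths[["posterior"]])
  writeVolumeNifti(as.numeric(result@lesionMask), geometry,
                   paths[["lesionMask"]])
  vols <- vapply(seq_along(result@structures), function(k)
    maskVolume(result@labelMap == k, geometry@voxelSize), numeric(1))
  utils::write.csv(data.frame(structure = result@structures,
                              volume_mm3 = vols),
                   paths[["volumes"]], row.names = FALSE)
  prov <- c(result@provenance,
            list(package = "wmlseg",
                 version = as.character(utils::packageVersion("wmlseg")),
                 rVersion = R.version.string,
                 configHash = .fnv1a(result@provenance)))
  jsonlite::write_json(prov, paths[["provenance"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Write and read an atlas bundle
#'
#' An atlas is serialized as a directory of plain-text arrays (vertices,
#' simplices, label and lesion probabilities, full `%.17g` precision so
#' the round trip is bit-exact) plus a JSON manifest with the label names,
#' stiffness and grid geometry.
#'
#' @param atlas a [MeshAtlas-class].
#' @param dir bundle directory.
#' @return `writeAtlasBundle` the directory invisibly; `readAtlasBundle`
#'   the [MeshAtlas-class].
#' @export
writeAtlasBundle <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(K = length(atlas@labels), labels = atlas@labels,
                   stiffness = atlas@stiffness, dim = atlas@geometry@dim,
                   voxelSize = atlas@geometry@voxelSize)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeNumericCsv(atlas@vertices, file.path(dir, "vertices.csv"))
  writeNumericCsv(atlas@simplices, file.path(dir, "simplices.csv"))
  writeNumericCsv(atlas@labelProbs, file.path(dir, "label_probs.csv"))
  writeNumericCsv(cbind(atlas@lesionProbs),
                  file.path(dir, "lesion_probs.csv"))
  invisible(dir)
}

#' @rdname writeAtlasBundle
#' @export
readAtlasBundle <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  geom <- gridGeometry(manifest$dim, manifest$voxelSize)
  meshAtlas(readNumericCsv(file.path(dir, "vertices.csv")),
            matrix(as.integer(readNumericCsv(file.path(dir,
                                                       "simplices.csv"))),
                   ncol = length(manifest$dim) + 1L),
            readNumericCsv(file.path(dir, "label_probs.csv")),
            readNumericCsv(file.path(dir, "lesion_probs.csv"))[, 1L],
            manifest$labels, geom, stiffness = as.numeric(manifest$stiffness))
}

#' Write and read a lesion shape model
#'
#' Weights are serialized as one full-precision CSV per layer plus a JSON
#' manifest; the round trip reproduces the model bit-exactly.
#'
#' @param model a [LesionShapeModel-class].
#' @param dir model directory.
#' @return `writeShapeModel` the directory invisibly; `readShapeModel` the
#'   [LesionShapeModel-class].
#' @export
writeShapeModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(latentDim = model@latentDim,
                   inputShape = model@inputShape,
                   training = model@training,
                   encoderLayers = names(model@encoder),
                   decoderLayers = names(model@decoder))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(model@encoder))
    writeNumericCsv(rbind(model@encoder[[nm]]),
                    file.path(dir, paste0("enc_", nm, ".csv")))
  for (nm in names(model@decoder))
    writeNumericCsv(rbind(model@decoder[[nm]]),
                    file.path(dir, paste0("dec_", nm, ".csv")))
  invisible(dir)
}

#' Read a segmentation run configuration from YAML
#'
#' A run configuration names the input volumes and their channel roles,
#' the atlas bundle and (optionally) the shape model, and overrides any
#' of the [fitConfig()] knobs (`gamma`, `samples`, `burnin`, `nu`,
#' `kappa`, `biasOrder`, `diagonalCov`, `seed`).
#'
#' @param path YAML file with fields `inputs` (list of `path`/`role`),
#'   `atlas`, optional `shapeModel` and `outdir`, and fit overrides.
#' @return list with elements `paths`, `roles`, `atlas`, `shapeModel`,
#'   `outdir` and a [FitConfig-class] in `config`.
#' @export
readRunConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read run configurations")
  raw <- yaml::read_yaml(path)
  if (is.null(raw$inputs) || !length(raw$inputs))
    stop("run configuration needs at least one input channel")
  paths <- vapply(raw$inputs, function(x) x$path, character(1))
  roles <- vapply(raw$inputs, function(x) x$role %||% "other",
                  character(1))
  if (is.null(raw$atlas)) stop("run configuration needs an atlas path")
  cfg <- fitConfig(gamma = raw$gamma %||% 0.5,
                   mcSamples = raw$samples %||% 50L,
                   mcBurnin = raw$burnin %||% 20L,
                   nu = raw$nu %||% 500, kappa = raw$kappa %||% 50,
                   biasOrder = raw$biasOrder %||% 3L,
                   diagonalCov = raw$diagonalCov %||% TRUE,
                   seed = raw$seed %||% 1L)
  list(paths = paths, roles = roles, atlas = raw$atlas,
       shapeModel = raw$shapeModel, outdir = raw$outdir %||% "wmlseg-out",
       config = cfg)
}

#' @rdname writeShapeModel
#' @export
readShapeModel <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  readLayer <- function(prefix, nm) {
    m <- readNumericCsv(file.path(dir, paste0(prefix, nm, ".csv")))
    if (nrow(m) == 1L && substr(nm, 1L, 1L) %in% c("b", "c")) m[1L, ]
    else m
  }
  enc <- lapply(manifest$encoderLayers, function(nm) readLayer("enc_", nm))
  names(enc) <- manifest$encoderLayers
  dec <- lapply(manifest$decoderLayers, function(nm) readLayer("dec_", nm))
  names(dec) <- manifest$decoderLayers
  new("LesionShapeModel", decoder = dec, encoder = enc,
      latentDim = as.integer(manifest$latentDim),
      inputShape = as.integer(manifest$inputShape),
      training = manifest$training)
}
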