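#' Image volume container
#'
#' A minimal 3-D voxel grid with per-axis spacing, origin and a modality tag.
#' Axial slices lie along the third array axis. World coordinates follow
#' `world = (index - 1) * spacing + origin` (1-based indices, so the first
#' voxel centre sits at the origin).
#'
#' @param voxels numeric 3-D array (a 2-D matrix is promoted to one slice).
#' @param spacing_mm numeric length-3: in-plane x, in-plane y, slice pitch.
#' @param origin_mm numeric length-3 world position of the first voxel centre.
#' @param modality one of `"MRI"`, `"CT"`, `"PET"`, `"LABEL"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(voxels, spacing_mm = c(1.1719, 1.1719, 7.2),
                         origin_mm = c(0, 0, 0),
                         modality = c("MRI", "CT", "PET", "LABEL")) {
  modality <- match.arg(modality)
  if (is.matrix(voxels)) dim(voxels) <- c(dim(voxels), 1L)
  if (length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3-D array (or a single-slice matrix)")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("'spacing_mm' must be three positive numbers")
  structure(
    list(voxels = voxels, spacing_mm = spacing_mm,
         origin_mm = as.numeric(origin_mm), modality = modality),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume> %s  %d x %d x %d voxels  spacing %.4f x %.4f x %.4f mm\n",
              x$modality, d[1], d[2], d[3],
              x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  rng <- range(x$voxels)
  cat(sprintf("  intensity range [%.3g, %.3g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$voxels)

#' Voxel volume in millilitres
#'
#' One voxel's volume, `px * py * pitch`, converted from cubic millimetres to
#' millilitres (1 mL = 1000 mm^3). The slice pitch (centre-to-centre spacing)
#' is used rather than the slice thickness so that inter-slice gaps are
#' counted as contiguous anatomy.
#'
#' @param volume an `image_volume` or a length-3 spacing vector (mm).
#' @return voxel volume in mL.
#' @export
voxel_volume_ml <- function(volume) {
  sp <- if (inherits(volume, "image_volume")) volume$spacing_mm else as.numeric(volume)
  prod(sp) / 1000
}

#' Read / write NIfTI-1 volumes
#'
#' Thin wrappers over RNifti that preserve voxel data, spacing and modality
#' (the modality tag is carried in the NIfTI description/intent fields is not
#' standard, so it is supplied by the caller on read).
#'
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @param modality modality tag to attach to the volume read.
#' @return `read_volume`: an `image_volume`. `write_volume`: the path,
#'   invisibly.
#' @export
read_volume <- function(path, modality = c("MRI", "CT", "PET", "LABEL")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("no such NIfTI file: ", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("cannot read NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  vox <- as.array(img)
  pix <- RNifti::pixdim(img)
  if (length(dim(vox)) == 2L) dim(vox) <- c(dim(vox), 1L)
  if (length(dim(vox)) == 3L) {
    image_volume(vox, spacing_mm = pix[1:3], modality = modality)
  } else if (length(dim(vox)) == 4L) {
    frames <- lapply(seq_len(dim(vox)[4]), function(i)
      image_volume(vox[, , , i, drop = FALSE][, , , 1],
                   spacing_mm = pix[1:3], modality = modality))
    frames
  } else stop("unsupported NIfTI dimensionality in '", path, "'")
}

#' @rdname read_volume
#' @param volume an `image_volume`, or a list of them (written as 4-D).
#' @export
write_volume <- function(volume, path) {
  if (inherits(volume, "image_volume")) {
    arr <- volume$voxels
    sp <- volume$spacing_mm
  } else if (is.list(volume) && all(vapply(volume, inherits, TRUE, "image_volume"))) {
    sp <- volume[[1]]$spacing_mm
    arr <- array(0, c(dim(volume[[1]]$voxels), length(volume)))
    for (i in seq_along(volume)) arr[, , , i] <- volume[[i]]$voxels
  } else stop("'volume' must be an image_volume or a list of them")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(sp, rep(1, length(dim(arr)) - 3L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
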