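#' Hounsfield-unit volume
#'
#' A 3-D voxel grid of Hounsfield units with isotropic spacing and an origin
#' at the corner of the first voxel. Axis convention: x = left-right,
#' y = posterior (increasing towards the nasopharynx), z = superior.
#' Voxel centre (i, j, k) sits at `origin + (c(i, j, k) - 0.5) * spacing`.
#'
#' @param values 3-D numeric array of HU values.
#' @param spacing voxel spacing in mm (isotropic).
#' @param origin corner of the first voxel, mm.
#' @return an `hu_volume` object.
#' @export
hu_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(values), length(dim(values)) == 3, spacing > 0)
  if (any(!is.finite(values))) stopf("HU volume contains non-finite values")
  if (min(values) < -1024 || max(values) > 3000)
    stopf("HU values outside [-1024, 3000]")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "hu_volume")
}

#' @export
print.hu_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("HU volume: %d x %d x %d voxels, %.3g mm spacing, HU [%d, %d]\n",
              d[1], d[2], d[3], x$spacing,
              round(min(x$values)), round(max(x$values))))
  invisible(x)
}

#' Read / write HU volumes as NIfTI
#'
#' Volumes are stored as NIfTI-1 (`.nii` or `.nii.gz`) with the voxel spacing
#' in `pixdim`. Reading honours the file's spacing; the origin is taken as 0.
#'
#' @param vol an `hu_volume`.
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns an
#'   `hu_volume`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "hu_volume"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- rep(vol$spacing, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1]
  hu_volume(array(as.numeric(img), dim = dim(img)), spacing = sp)
}
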