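# Volume containers and NIfTI-1 I/O (via RNifti)

SCALAR_UNITS <- c(FA = "", MD = "mm^2/s", AD = "mm^2/s", RD = "mm^2/s",
                  RTOP = "mm^-3", RTAP = "mm^-2", RTPP = "mm^-1")

#' Scalar map container
#'
#' One named per-voxel measure on a grid. FA is checked to lie in
#' \[0, 1\]; diffusivities and return probabilities must be non-negative.
#'
#' @param grid a [volume_grid()].
#' @param name one of FA, MD, AD, RD, RTOP, RTAP, RTPP.
#' @param values 3-D array of finite values matching `grid$shape`.
#'   Voxels outside any mask may be NA.
#' @return object of class `scalar_map`.
#' @export
scalar_map <- function(grid, name, values) {
  name <- match.arg(name, names(SCALAR_UNITS))
  values <- as.array(values)
  if (!all(dim(values) == grid$shape))
    stop_validation("values shape does not match grid")
  v <- values[!is.na(values)]
  if (any(!is.finite(v)))
    stop_validation("non-finite values in scalar map ", name)
  if (name == "FA" && length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
    stop_validation("FA values outside [0, 1]")
  if (name != "FA" && length(v) && min(v) < -1e-12)
    stop_validation(name, " values must be non-negative")
  structure(list(grid = grid, name = name, values = values,
                 units = SCALAR_UNITS[[name]]),
            class = "scalar_map")
}

#' Label map container
#'
#' @param grid a [volume_grid()].
#' @param labels 3-D array of non-negative integers (0 = background).
#' @param lookup named character vector or data.frame (id, name) mapping
#'   every nonzero label to a region name.
#' @return object of class `label_map`.
#' @export
label_map <- function(grid, labels, lookup) {
  labels <- as.array(labels)
  if (!all(dim(labels) == grid$shape))
    stop_validation("labels shape does not match grid")
  if (any(labels < 0) || any(labels != round(labels)))
    stop_validation("labels must be non-negative integers")
  if (is.data.frame(lookup))
    lookup <- setNames(as.character(lookup[[2]]), lookup[[1]])
  present <- sort(unique(as.vector(labels)))
  present <- present[present > 0]
  missing <- setdiff(as.character(present), names(lookup))
  if (length(missing))
    stop_validation("labels without lookup entry: ",
                    paste(missing, collapse = ", "))
  structure(list(grid = grid, labels = labels, lookup = lookup),
            class = "label_map")
}

#' Diffusion-weighted image stack
#'
#' @param grid a [volume_grid()].
#' @param data 4-D array (x, y, z, volume) of non-negative intensities.
#' @param scheme the matching [gradient_scheme()].
#' @return object of class `dwi_stack`.
#' @export
dwi_stack <- function(grid, data, scheme) {
  data <- as.array(data)
  if (length(dim(data)) != 4L)
    stop_format("DWI data must be 4-D")
  if (!all(dim(data)[1:3] == grid$shape))
    stop_validation("data shape does not match grid")
  if (dim(data)[4] != length(scheme$bvals))
    stop_validation("4th dimension (", dim(data)[4],
                    ") does not match scheme length (", length(scheme$bvals), ")")
  if (any(!is.finite(data)) || any(data < 0))
    stop_validation("DWI intensities must be finite and non-negative")
  structure(list(grid = grid, data = data, scheme = scheme),
            class = "dwi_stack")
}

grid_from_nifti <- function(img) {
  hdr <- RNifti::niftiHeader(img)
  d <- dim(img)
  volume_grid(d[1:3], hdr$pixdim[2:4], affine = RNifti::xform(img))
}

#' Read a NIfTI volume
#'
#' 3-D files become a [scalar_map()] or [label_map()], 4-D files a
#' [dwi_stack()] (a `scheme` is then required). Grid geometry comes from
#' the header.
#'
#' @param path NIfTI-1 file.
#' @param type "scalar", "label", "dwi" or "auto" (3-D -> scalar,
#'   4-D -> dwi).
#' @param name scalar measure name (required for scalar maps).
#' @param scheme [gradient_scheme()], for `type = "dwi"`.
#' @param lookup label lookup, for `type = "label"`.
#' @return the dispatched container.
#' @export
read_volume <- function(path, type = c("auto", "scalar", "label", "dwi"),
                        name = "FA", scheme = NULL, lookup = NULL) {
  type <- match.arg(type)
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (nd > 4L || nd < 3L)
    stop_format(nd, "-D NIfTI input is not supported (need 3-D or 4-D)")
  nbad <- sum(!is.finite(img))
  if (nbad > 0)
    stop_validation(nbad, " non-finite voxel(s) in ", path)
  grid <- grid_from_nifti(img)
  arr <- array(as.vector(img), dim(img))   # strip NIfTI attributes
  if (type == "auto") type <- if (nd == 4L) "dwi" else "scalar"
  switch(type,
    scalar = scalar_map(grid, name, arr),
    label = label_map(grid, array(as.integer(round(arr)), dim(arr)),
                      lookup),
    dwi = {
      if (is.null(scheme))
        stop_validation("a gradient scheme is required to read a DWI stack")
      dwi_stack(grid, arr, scheme)
    })
}

#' Write a volume container to NIfTI-1
#'
#' Stores the affine in the sform/qform and, for scalar maps, the units in
#' the header description field.
#'
#' @param x a `scalar_map`, `label_map` or `dwi_stack`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(x, path) {
  arr <- switch(class(x)[1],
                scalar_map = x$values,
                label_map = x$labels,
                dwi_stack = x$data,
                stop_format("cannot write object of class ", class(x)[1]))
  arr[is.na(arr)] <- 0
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- if (length(dim(arr)) == 4L)
    c(x$grid$voxel_size, 1) else x$grid$voxel_size
  RNifti::sform(img) <- structure(x$grid$affine, code = 2L)
  if (inherits(x, "scalar_map"))
    img <- RNifti::asNifti(img, list(
      descrip = paste0(x$name, ifelse(nzchar(x$units),
                                      paste0(" [", x$units, "]"), ""))))
  RNifti::writeNifti(img, path)
  invisible(path)
}
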