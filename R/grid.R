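#' Define a voxel grid
#'
#' A `grid_spec` describes an axis-aligned voxel lattice in world (mm)
#' coordinates. The grid occupies the half-open box
#' `[origin, origin + dim * voxel_size)`; the centre of voxel `(i, j, k)`
#' (1-based array index) sits at `origin + (index - 0.5) * voxel_size`.
#'
#' @param voxel_size numeric length-3, voxel edge lengths in mm (all > 0).
#' @param dim integer length-3, number of voxels per axis (all > 0).
#' @param origin numeric length-3, world coordinate (mm) of the grid corner.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(voxel_size, dim, origin = c(0, 0, 0)) {
  voxel_size <- as.numeric(rep_len(voxel_size, 3L))
  dim <- as.integer(rep_len(dim, 3L))
  origin <- as.numeric(rep_len(origin, 3L))
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be positive and finite")
  if (any(is.na(dim)) || any(dim <= 0L))
    stop("dim must be positive integers")
  structure(list(voxel_size = voxel_size, dim = dim, origin = origin),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels of %.4g x %.4g x %.4g mm, origin (%g, %g, %g)\n",
              x$dim[1], x$dim[2], x$dim[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Grid helpers
#'
#' `voxel_volume_mm3()` returns one voxel's volume in cubic mm;
#' `grid_axis_centers()` the world coordinates of voxel centres along one
#' axis; `grid_extent()` the world bounds of the grid box.
#'
#' @param grid a [grid_spec()].
#' @param axis axis index 1..3.
#' @name grid-helpers
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$voxel_size)

#' @rdname grid-helpers
#' @export
grid_axis_centers <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dim[axis]) - 0.5) * grid$voxel_size[axis]
}

#' @rdname grid-helpers
#' @export
grid_extent <- function(grid) {
  rbind(lower = grid$origin, upper = grid$origin + grid$dim * grid$voxel_size)
}

#' World coordinates of all voxel centres
#'
#' @param grid a [grid_spec()].
#' @return An `prod(dim)` x 3 matrix, fastest index first (column-major
#'   array order, matching how values are stored in [activity_image()]).
#' @export
grid_voxel_centers <- function(grid) {
  cx <- grid_axis_centers(grid, 1L)
  cy <- grid_axis_centers(grid, 2L)
  cz <- grid_axis_centers(grid, 3L)
  cbind(rep(cx, times = grid$dim[2] * grid$dim[3]),
        rep(rep(cy, each = grid$dim[1]), times = grid$dim[3]),
        rep(cz, each = grid$dim[1] * grid$dim[2]))
}

#' Refine a grid by an integer factor per axis
#'
#' Used to build the fine internal simulation grid associated with a
#' reconstruction profile: the refined grid covers exactly the same world
#' box with `factor` times more voxels per axis.
#'
#' @param grid a [grid_spec()].
#' @param factor integer length-1 or -3 refinement factor (>= 1).
#' @export
refine_grid <- function(grid, factor) {
  factor <- as.integer(rep_len(factor, 3L))
  if (any(factor < 1L)) stop("refinement factor must be >= 1")
  grid_spec(grid$voxel_size / factor, grid$dim * factor, grid$origin)
}

#' Crop a grid to a window around a world point, snapped to the lattice
#'
#' Returns a sub-grid of `grid` whose box contains the ball of radius
#' `half_extent` around `center`. The window corner is snapped to the
#' parent lattice so that the sub-grid's voxels coincide with parent
#' voxels: a target that moves in world coordinates therefore still moves
#' relative to the voxel lattice, which is what produces the tissue
#' fraction effect under repositioning.
#'
#' @param grid a [grid_spec()].
#' @param center world point (mm), length 3.
#' @param half_extent half edge length of the window in mm (scalar or
#'   length 3).
#' @export
crop_grid <- function(grid, center, half_extent) {
  half_extent <- rep_len(half_extent, 3L)
  lo <- floor((center - half_extent - grid$origin) / grid$voxel_size)
  hi <- ceiling((center + half_extent - grid$origin) / grid$voxel_size)
  lo <- pmax(lo, 0)
  hi <- pmin(hi, grid$dim)
  if (any(hi <= lo)) stop("window does not intersect grid")
  grid_spec(grid$voxel_size, hi - lo, grid$origin + lo * grid$voxel_size)
}

#' Construct an activity image
#'
#' An `activity_image` is a 3-D array of activity concentrations (kBq/mL)
#' on a [grid_spec()], together with a provenance list recording the
#' operations that produced it (applied transform, blur FWHM, noise seed,
#' frame, ...).
#'
#' @param values numeric 3-D array matching `grid$dim`.
#' @param grid a [grid_spec()].
#' @param provenance named list of operation records.
#' @export
activity_image <- function(values, grid, provenance = list()) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3-D array")
  if (!all(dim(values) == grid$dim))
    stop("values dimensions do not match grid dimensions")
  if (any(!is.finite(values)))
    stop("activity image values must be finite")
  structure(list(values = values, grid = grid, provenance = provenance),
            class = "activity_image")
}

#' @export
print.activity_image <- function(x, ...) {
  cat(sprintf("<activity_image> %d x %d x %d voxels, range [%.4g, %.4g] kBq/mL\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              min(x$values), max(x$values)))
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance), collapse = ", "), "\n")
  invisible(x)
}

note_provenance <- function(image, key, record) {
  image$provenance[[key]] <- record
  image
}

#' Total activity of an image
#'
#' Sum of voxel concentration times voxel volume, in kBq.
#'
#' @param image an [activity_image()].
#' @export
total_activity <- function(image) {
  sum(image$values) * voxel_volume_mm3(image$grid) / 1000
}

#' Block-average an image onto a coarser grid
#'
#' Averages `factor^3` fine voxels into each coarse voxel. Because values
#' are concentrations, block averaging conserves total activity exactly.
#'
#' @param image an [activity_image()] whose dimensions are divisible by
#'   `factor`.
#' @param factor integer length-1 or -3 downsampling factor.
#' @export
downsample_image <- function(image, factor) {
  factor <- as.integer(rep_len(factor, 3L))
  if (all(factor == 1L)) return(image)
  d <- image$grid$dim
  if (any(d %% factor != 0L))
    stop("image dimensions not divisible by downsampling factor")
  nd <- d %/% factor
  a <- array(image$values, dim = c(factor[1], nd[1], factor[2], nd[2], factor[3], nd[3]))
  vals <- apply(a, c(2L, 4L, 6L), sum) / prod(factor)
  out_grid <- grid_spec(image$grid$voxel_size * factor, nd, image$grid$origin)
  activity_image(vals, out_grid, image$provenance)
}

#' Read and write activity images as NIfTI-1
#'
#' `write_activity_image()` writes the voxel array with the grid's voxel
#' sizes in the header and the grid origin as the spatial offset (RAS);
#' `read_activity_image()` reads any scalar NIfTI-1 volume back into an
#' [activity_image()], taking voxel sizes from `pixdim` and the origin
#' from the stored affine. Values are assumed to be activity
#' concentrations in kBq/mL.
#'
#' @param image an [activity_image()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @name nifti-io
#' @export
write_activity_image <- function(image, path) {
  half <- image$grid$voxel_size / 2
  nii <- RNifti::asNifti(image$values, reference = NULL)
  nii <- RNifti::`pixdim<-`(nii, image$grid$voxel_size)
  aff <- diag(c(image$grid$voxel_size, 1))
  aff[1:3, 4] <- image$grid$origin + half
  nii <- RNifti::`sform<-`(nii, structure(aff, code = 2L))
  nii <- RNifti::`qform<-`(nii, structure(aff, code = 2L))
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname nifti-io
#' @export
read_activity_image <- function(path) {
  nii <- RNifti::readNifti(path)
  vals <- array(as.numeric(nii), dim = dim(nii)[1:3])
  vs <- RNifti::pixdim(nii)[1:3]
  aff <- RNifti::xform(nii)
  origin <- aff[1:3, 4] - vs / 2
  activity_image(vals, grid_spec(vs, dim(vals), origin),
                 provenance = list(source = path))
}
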