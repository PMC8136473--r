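# Volume container and tomographic volume I/O.

#' Tomographic volume
#'
#' A 3D grey-level scalar grid with isotropic voxel size. Axis convention:
#' `data[row, col, plane]`, where the plane index (third axis) is the TIFF
#' page index and increases along the tomographic rotation axis. `offset`
#' holds the 0-based voxel coordinates of this grid's origin within a
#' parent volume (all zero for a full volume), so chunks cut from a larger
#' volume know where they came from.
#'
#' @param data numeric 3D array of grey values (arbitrary units).
#' @param voxel_size isotropic voxel edge length in micrometres.
#' @param offset integer length-3 vector, 0-based voxel origin within the
#'   parent volume.
#' @param meta free-form provenance list (source path, bit depth, ...).
#' @return An object of class `ab_volume`.
#' @examples
#' v <- volume(array(0.3, c(8, 8, 4)), voxel_size = 0.332)
#' physical_volume_cm3(v)
#' @export
volume <- function(data, voxel_size, offset = c(0L, 0L, 0L), meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array")
  if (any(dim(data) < 1L)) stop("volume extents must all be >= 1")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L ||
      !is.finite(voxel_size) || voxel_size <= 0)
    stop("voxel_size must be a single positive finite value (um)")
  if (anyNA(data) || !all(is.finite(data)))
    stop("volume grey values must all be finite")
  if (length(offset) != 3L || any(offset != round(offset)) || any(offset < 0))
    stop("offset must be three non-negative integer voxel coordinates")
  structure(
    list(data = data, voxel_size = voxel_size,
         offset = as.integer(offset), meta = meta),
    class = "ab_volume"
  )
}

#' @export
print.ab_volume <- function(x, ...) {
  d <- dim(x$data)
  ext <- physical_extents_um(d, x$voxel_size)
  cat(sprintf("<ab_volume> %d x %d x %d voxels @ %g um\n", d[1], d[2], d[3],
              x$voxel_size))
  cat(sprintf("  physical extents: %.1f x %.1f x %.1f um (V_c = %.4g cm^3)\n",
              ext[1], ext[2], ext[3], physical_volume_cm3(x)))
  if (any(x$offset != 0))
    cat("  offset (voxels, 0-based):", paste(x$offset, collapse = ", "), "\n")
  invisible(x)
}

#' Physical tissue volume V_c of a grid, in cm^3
#'
#' `V_c = n_voxels * voxel_size^3 * 1e-12`, the denominator of the burden
#' conversion.
#'
#' @param volume an [volume()] object.
#' @return Physical volume in cm^3.
#' @export
physical_volume_cm3 <- function(volume) {
  stopifnot(inherits(volume, "ab_volume"))
  prod(dim(volume$data)) * volume$voxel_size^3 * 1e-12
}

#' Physical extents of a voxel grid, in micrometres
#'
#' @param extents integer voxel counts per axis.
#' @param voxel_size voxel edge length in micrometres.
#' @return `extents * voxel_size`, in micrometres.
#' @examples
#' physical_extents_um(c(2560, 2560, 2160), 0.325)  # 832 x 832 x 702 um
#' @export
physical_extents_um <- function(extents, voxel_size) {
  stopifnot(all(extents >= 1), voxel_size > 0)
  extents * voxel_size
}

#' Effective voxel size of a magnified detector
#'
#' Detector pixel pitch divided by the optical magnification, e.g. a
#' 6.5 um camera pixel behind 20x optics gives 0.325 um voxels.
#'
#' @param detector_pixel_um physical detector pixel size in micrometres.
#' @param magnification optical magnification factor.
#' @return Effective isotropic voxel size in micrometres.
#' @export
effective_voxel_size <- function(detector_pixel_um, magnification) {
  stopifnot(detector_pixel_um > 0, magnification > 0)
  detector_pixel_um / magnification
}

#' Read a tomographic volume from a multi-page TIFF stack
#'
#' Pages become planes (third axis). Grey values are preserved bit-exactly
#' for 8/16-bit unsigned input and value-exactly for 32-bit float input.
#' The voxel size is deliberately user-supplied metadata and never inferred
#' from TIFF resolution tags, which are unreliable for synchrotron data.
#'
#' @param path path to an existing multi-page grayscale TIFF.
#' @param voxel_size isotropic voxel size in micrometres.
#' @return An [volume()] object.
#' @export
read_volume <- function(path, voxel_size) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("input file does not exist: ", path)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L ||
      !is.finite(voxel_size) || voxel_size <= 0)
    stop("voxel_size must be a single positive finite value (um)")
  tf <- .read_tiff_stack(path)
  volume(tf$data, voxel_size,
         meta = list(source = normalizePath(path), bits = tf$bits,
                     sample_format = tf$sample_format))
}

#' Write a volume to a multi-page TIFF stack
#'
#' The inverse of [read_volume()]: `read_volume(write_volume(v, p), vs)`
#' reproduces `v`'s grid and shape. 32-bit float output (the default)
#' stores grey values exactly as held; integer output requires whole
#' values within range.
#'
#' @param volume an [volume()] object.
#' @param path output file path; the parent directory must exist.
#' @param bits bits per sample: 8 or 16 (unsigned integer) or 32 (float).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, bits = 32L) {
  stopifnot(inherits(volume, "ab_volume"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
  .write_tiff_stack(volume$data, path, bits = as.integer(bits))
  invisible(path)
}

.axis_chunk_starts <- function(n, chunk, overlap) {
  if (chunk > n) stop("chunk extent (", chunk, ") exceeds volume extent (",
                      n, ")")
  if (chunk == n) return(1L)
  step <- chunk - overlap
  if (step < 1L) stop("overlap (", overlap,
                      ") must be smaller than the chunk extent (", chunk, ")")
  starts <- seq.int(1L, n - chunk + 1L, by = step)
  if (starts[length(starts)] + chunk - 1L < n)
    starts <- c(starts, n - chunk + 1L)
  as.integer(starts)
}

#' Split a volume into overlapping chunks
#'
#' Large reconstructions are processed in sub-volumes for memory reasons;
#' chunks overlap so that every object of bounded extent fits entirely in
#' at least one chunk, and each chunk carries its voxel offset within the
#' parent. Consecutive chunks share exactly `overlap` planes along each
#' split axis (the final chunk of an axis may overlap more when the extent
#' is not an exact multiple of the step).
#'
#' @param volume an [volume()] object.
#' @param chunk_extents voxels per axis for each chunk; scalar or length-3
#'   (an axis equal to the volume extent is not split).
#' @param overlap non-negative number of shared planes between consecutive
#'   chunks.
#' @return List of [volume()] chunks, ordered plane-major, with correct
#'   `offset`s and a `manifest` attribute (a data.frame of offsets and
#'   extents).
#' @export
split_volume <- function(volume, chunk_extents, overlap = 0L) {
  stopifnot(inherits(volume, "ab_volume"))
  d <- dim(volume$data)
  if (length(chunk_extents) == 1L) chunk_extents <- rep(chunk_extents, 3L)
  if (length(chunk_extents) != 3L || any(chunk_extents < 1L))
    stop("chunk_extents must be 1 or 3 positive voxel counts")
  if (length(overlap) != 1L || overlap < 0 || overlap != round(overlap))
    stop("overlap must be a single non-negative integer")
  chunk_extents <- as.integer(chunk_extents)
  overlap <- as.integer(overlap)
  starts <- lapply(1:3, function(a)
    .axis_chunk_starts(d[a], chunk_extents[a], overlap))
  grid <- expand.grid(i = starts[[1]], j = starts[[2]], k = starts[[3]],
                      KEEP.OUT.ATTRS = FALSE)
  chunks <- lapply(seq_len(nrow(grid)), function(r) {
    s <- as.integer(grid[r, ])
    e <- s + chunk_extents - 1L
    volume(volume$data[s[1]:e[1], s[2]:e[2], s[3]:e[3], drop = FALSE],
           volume$voxel_size,
           offset = volume$offset + s - 1L,
           meta = c(volume$meta, list(chunk_of = d)))
  })
  manifest <- data.frame(
    chunk = seq_len(nrow(grid)),
    off_row = grid$i - 1L, off_col = grid$j - 1L, off_plane = grid$k - 1L,
    ext_row = chunk_extents[1], ext_col = chunk_extents[2],
    ext_plane = chunk_extents[3], overlap = overlap
  )
  attr(chunks, "manifest") <- manifest
  chunks
}

#' Write a chunk manifest as JSON
#'
#' @param chunks result of [split_volume()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_chunk_manifest <- function(chunks, path) {
  m <- attr(chunks, "manifest")
  if (is.null(m)) stop("chunks carry no manifest; use split_volume()")
  jsonlite::write_json(m, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Project a slab of a volume onto a plane
#'
#' Collapses a contiguous range of planes along one axis into a 2D image
#' for visual QC, the way tomograms are presented as projections of a few
#' hundred slices. Counting is never performed on projections.
#'
#' @param volume an [volume()] object.
#' @param axis axis to project along (1, 2 or 3).
#' @param slab integer vector of plane indices along `axis` (contiguous);
#'   default all planes.
#' @param mode `"max"`, `"mean"` or `"sum"`.
#' @return A 2D matrix with the two non-projected extents.
#' @export
project_volume <- function(volume, axis = 3L, slab = NULL, mode = "max") {
  stopifnot(inherits(volume, "ab_volume"))
  if (!axis %in% 1:3) stop("axis must be 1, 2 or 3")
  d <- dim(volume$data)
  if (is.null(slab)) slab <- seq_len(d[axis])
  if (length(slab) == 0L) stop("slab must contain at least one plane")
  if (any(slab < 1L) || any(slab > d[axis]))
    stop("slab indices out of bounds for axis ", axis)
  mode <- match.arg(mode, c("max", "mean", "sum"))
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  idx[[axis]] <- slab
  sub <- volume$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  fun <- switch(mode, max = max, mean = mean, sum = sum)
  apply(sub, setdiff(1:3, axis), fun)
}
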