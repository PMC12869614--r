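#' Dynamic 4D volume and ROI mask containers
#'
#' `dynamic_volume()` wraps a 4D (x, y, z, t) array of signal intensities
#' with its frame timing; `roi_mask()` wraps a congruent 3D logical array.
#'
#' @param data 4D numeric array (x, y, z, t) with at least two frames and
#'   non-negative intensities.
#' @param frame_interval seconds between frames.
#' @param bolus_frame index of the first post-injection frame (frames before
#'   it are pre-contrast baseline).
#' @return `dynamic_volume()`: an object of class `dynamic_volume`.
#' @export
dynamic_volume <- function(data, frame_interval, bolus_frame = 1L) {
  d <- dim(data)
  if (length(d) != 4L) stop("'data' must be a 4D (x, y, z, t) array")
  if (d[4L] < 2L) stop("dynamic series needs at least two time frames")
  if (any(data < 0)) stop("signal intensities must be non-negative")
  stopifnot(frame_interval > 0, bolus_frame >= 1, bolus_frame <= d[4L])
  structure(list(data = data, frame_interval = frame_interval,
                 bolus_frame = as.integer(bolus_frame)),
            class = "dynamic_volume")
}

#' @rdname dynamic_volume
#' @param mask 3D logical array, same spatial dims as the volume, with at
#'   least one `TRUE` voxel.
#' @param label organ or vessel name.
#' @return `roi_mask()`: an object of class `roi_mask`.
#' @export
roi_mask <- function(mask, label = "roi") {
  if (length(dim(mask)) != 3L) stop("'mask' must be a 3D array")
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stop("ROI mask has no voxels")
  structure(list(mask = mask, label = label), class = "roi_mask")
}

#' Temporal intensity projections of a dynamic series
#'
#' Computes per-voxel maximum, mean, and sample standard deviation along the
#' temporal dimension. Mean projections are used to draw parenchymal organ
#' ROIs (they suppress respiratory motion artifacts); maximum projections
#' accentuate vessels; SD projections highlight bile ducts and other
#' dynamically changing structures.
#'
#' @param vol a [dynamic_volume()].
#' @return A list of 3D arrays `max`, `mean`, `sd` (SD uses the n - 1
#'   denominator).
#' @export
temporal_projections <- function(vol) {
  stopifnot(inherits(vol, "dynamic_volume"))
  d <- dim(vol$data)
  nt <- d[4L]
  if (nt < 2L) stop("standard deviation projection undefined for a single frame")
  m <- matrix(vol$data, ncol = nt)    # voxels x time
  mu <- rowMeans(m)
  ss <- rowSums((m - mu)^2) / (nt - 1)
  list(max = array(apply(m, 1L, max), d[1:3]),
       mean = array(mu, d[1:3]),
       sd = array(sqrt(ss), d[1:3]))
}

# radius-1 face-connected (6-neighborhood) dilation of a 3D logical array
dilate6 <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift <- function(m, axis, by) {
    idx <- lapply(d, seq_len)
    src <- lapply(d, seq_len)
    if (by == 1L) { idx[[axis]] <- 2:d[axis]; src[[axis]] <- 1:(d[axis] - 1L) }
    else          { idx[[axis]] <- 1:(d[axis] - 1L); src[[axis]] <- 2:d[axis] }
    z <- array(FALSE, d)
    z[idx[[1]], idx[[2]], idx[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    z
  }
  for (axis in 1:3) {
    if (d[axis] > 1L) out <- out | shift(mask, axis, 1L) | shift(mask, axis, -1L)
  }
  out
}

#' Refine a vascular ROI by dilation and intensity ranking
#'
#' Vessel ROIs drawn on maximum intensity projections are refined to exclude
#' extraluminal voxels and partial-volume voxels: the mask is dilated by one
#' voxel (face-connected neighborhood), the dilated mask's voxels are ranked
#' by projection intensity, and only the brightest third (ceiling(n/3) of n
#' dilated voxels) is retained. Ties at the cut are broken by descending
#' intensity, then ascending linear voxel index, so the result is
#' reproducible.
#'
#' @param mask a [roi_mask()].
#' @param projection 3D array (typically the `max` temporal projection),
#'   congruent with the mask.
#' @return A refined [roi_mask()], always a subset of the dilated input mask.
#' @export
refine_vascular_roi <- function(mask, projection) {
  stopifnot(inherits(mask, "roi_mask"))
  if (!identical(dim(mask$mask), dim(projection)))
    stop("mask and projection dimensions differ")
  dil <- dilate6(mask$mask)
  idx <- which(dil)
  n_keep <- ceiling(length(idx) / 3)
  ord <- order(-projection[idx], idx)
  keep <- idx[ord[seq_len(n_keep)]]
  out <- array(FALSE, dim(mask$mask))
  out[keep] <- TRUE
  roi_mask(out, label = mask$label)
}

#' ROI-mean signal time course
#'
#' Averages the dynamic volume over the masked voxels at each frame and
#' builds the bolus-relative time axis (t = 0 at the bolus frame). The
#' baseline S(0) is the mean of the pre-bolus frames of the extracted
#' course.
#'
#' @param vol a [dynamic_volume()].
#' @param mask a [roi_mask()] congruent with the volume's spatial dims.
#' @return A [signal_series()].
#' @export
extract_roi_mean <- function(vol, mask) {
  stopifnot(inherits(vol, "dynamic_volume"), inherits(mask, "roi_mask"))
  d <- dim(vol$data)
  if (!identical(d[1:3], dim(mask$mask)))
    stop("mask and volume spatial dimensions differ")
  m <- matrix(vol$data, ncol = d[4L])
  vals <- colMeans(m[which(mask$mask), , drop = FALSE])
  times <- (seq_len(d[4L]) - vol$bolus_frame) * vol$frame_interval
  s0 <- if (vol$bolus_frame > 1L) mean(vals[seq_len(vol$bolus_frame - 1L)])
        else vals[1L]
  signal_series(times, vals, s0 = s0)
}

#' Read and write dynamic volumes and masks as NIfTI
#'
#' Thin wrappers over RNifti for the optional image-based input path. A 4D
#' NIfTI becomes a [dynamic_volume()]; a 3D NIfTI (non-zero = inside) becomes
#' a [roi_mask()].
#'
#' @param path NIfTI file path.
#' @param frame_interval,bolus_frame timing metadata for the dynamic series.
#' @return `read_dynamic_volume()`: a `dynamic_volume`;
#'   `read_roi_mask()`: a `roi_mask`.
#' @export
read_dynamic_volume <- function(path, frame_interval, bolus_frame = 1L) {
  img <- RNifti::readNifti(path)
  dynamic_volume(array(as.numeric(img), dim(img)), frame_interval, bolus_frame)
}

#' @rdname read_dynamic_volume
#' @param label organ/vessel label for the mask.
#' @export
read_roi_mask <- function(path, label = "roi") {
  img <- RNifti::readNifti(path)
  roi_mask(array(as.numeric(img) != 0, dim(img)), label = label)
}

#' @rdname read_dynamic_volume
#' @param x a `dynamic_volume` or `roi_mask` to write.
#' @export
write_nifti_volume <- function(x, path) {
  arr <- if (inherits(x, "dynamic_volume")) x$data
         else if (inherits(x, "roi_mask")) array(as.integer(x$mask), dim(x$mask))
         else stop("'x' must be a dynamic_volume or roi_mask")
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}
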