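#' Preprocessing configuration
#'
#' Parameters of the ROI-cropping pipeline: a bounding box is computed
#' once per subject from one axial slice of a reference modality, the
#' depth is restricted to a fixed slab, all five volumes are cropped with
#' the same box and resized in-plane, intensities are min-max normalized.
#' The defaults target the standard 240 x 240 x 155 geometry: reference
#' slice 77 (the middle of 0..154), depth slab `[13, 141)` (exactly 128
#' slices), in-plane size 128, giving `(128, 128, 128)` inputs.  All
#' indices are 0-based; intervals are half-open.
#'
#' @param reference_modality Modality used for the bounding box
#'   (default `"T1"`, which shows the brain/background edge well).
#' @param reference_slice 0-based axial slice index (default 77).
#' @param depth_range Half-open 0-based slice interval (default
#'   `c(13, 141)`).
#' @param target_inplane Output in-plane size (default 128).
#' @param foreground_threshold Pixels strictly above this intensity count
#'   as foreground for the bounding box (default 0).
#' @param normalize Whether to min-max normalize intensities (default
#'   `TRUE`).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(reference_modality = "T1",
                              reference_slice = 77L,
                              depth_range = c(13L, 141L),
                              target_inplane = 128L,
                              foreground_threshold = 0,
                              normalize = TRUE) {
  reference_modality <- match.arg(reference_modality, MODALITIES)
  reference_slice <- .check_count(reference_slice, "reference_slice")
  if (length(depth_range) != 2L || depth_range[1L] >= depth_range[2L] ||
      depth_range[1L] < 0)
    .stopf("'depth_range' must be a valid half-open interval (start < end)")
  target_inplane <- .check_count(target_inplane, "target_inplane", 8L)
  foreground_threshold <- .check_number(foreground_threshold,
                                        "foreground_threshold")
  structure(list(reference_modality = reference_modality,
                 reference_slice = reference_slice,
                 depth_range = as.integer(depth_range),
                 target_inplane = target_inplane,
                 foreground_threshold = foreground_threshold,
                 normalize = .check_flag(normalize, "normalize")),
            class = "preprocess_config")
}

#' Compute the ROI bounding box from a reference slice
#'
#' Extracts the axial slice `config$reference_slice` (0-based) from the
#' reference volume and returns the tight half-open bounding box of all
#' pixels with intensity strictly above `foreground_threshold`, plus the
#' configured depth range.  `x` indexes the first in-plane axis (rows),
#' `y` the second (columns).
#'
#' @param reference A `volume` or 3D array (the reference modality).
#' @param config A [preprocess_config()].
#' @return An object of class `roi_box`: `x1, x2, y1, y2` (0-based,
#'   half-open), `reference_slice`, `depth_range`.
#' @export
compute_roi_box <- function(reference, config = preprocess_config()) {
  v <- .as_volume(reference)
  d <- dim(v$data)
  if (d[3L] < config$reference_slice + 1L)
    .stopf("volume has %d slices; reference_slice %d out of range",
           d[3L], config$reference_slice)
  sl <- v$data[, , config$reference_slice + 1L]
  fg <- which(sl > config$foreground_threshold, arr.ind = TRUE)
  if (nrow(fg) == 0L)
    .stopf("NoForeground: no pixel exceeds threshold %g on reference slice %d",
           config$foreground_threshold, config$reference_slice)
  structure(list(x1 = min(fg[, 1L]) - 1L, x2 = max(fg[, 1L]),
                 y1 = min(fg[, 2L]) - 1L, y2 = max(fg[, 2L]),
                 reference_slice = config$reference_slice,
                 depth_range = config$depth_range),
            class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf(
    "ROI box: rows [%d, %d), cols [%d, %d) @ slice %d; depth [%d, %d)\n",
    x$x1, x$x2, x$y1, x$y2, x$reference_slice,
    x$depth_range[1L], x$depth_range[2L]))
  invisible(x)
}

#' Crop a volume to a depth slab
#'
#' @param volume A `volume` or 3D array.
#' @param depth_range Half-open 0-based `(start, end)` slice interval.
#' @return Cropped `volume` with `end - start` slices.
#' @export
crop_depth <- function(volume, depth_range = c(13L, 141L)) {
  v <- .as_volume(volume)
  d <- dim(v$data)
  s <- depth_range[1L]; e <- depth_range[2L]
  if (s >= e || s < 0 || e > d[3L])
    .stopf("depth_range [%d, %d) out of bounds for %d slices", s, e, d[3L])
  new_volume(v$data[, , (s + 1L):e, drop = FALSE], affine = v$affine,
             role = v$role)
}

#' Crop a volume in-plane with an ROI box
#'
#' Pure slicing (no resampling): every axial slice is restricted to rows
#' `[x1, x2)` and columns `[y1, y2)`.  The same box must be applied to
#' all modalities and the mask of a subject.
#'
#' @param volume A `volume` or 3D array.
#' @param box A [compute_roi_box()] result.
#' @return Cropped `volume`.
#' @export
apply_roi <- function(volume, box) {
  v <- .as_volume(volume)
  d <- dim(v$data)
  if (box$x1 < 0 || box$x2 > d[1L] || box$y1 < 0 || box$y2 > d[2L] ||
      box$x1 >= box$x2 || box$y1 >= box$y2)
    .stopf("ROI box exceeds volume extents (%d x %d)", d[1L], d[2L])
  new_volume(v$data[(box$x1 + 1L):box$x2, (box$y1 + 1L):box$y2, ,
                    drop = FALSE],
             affine = v$affine, role = v$role)
}

# 1D resampling maps: for each of `size` output centers, source index
# pair + linear weight under center alignment: src = (i+0.5)*n/size - 0.5
.resample_map <- function(n, size) {
  src <- (seq_len(size) - 0.5) * n / size - 0.5
  i0 <- pmin(pmax(floor(src), 0), n - 1)
  i1 <- pmin(i0 + 1, n - 1)
  f <- pmin(pmax(src - i0, 0), 1)
  near <- pmin(pmax(round(src), 0), n - 1)
  list(i0 = i0 + 1L, i1 = i1 + 1L, f = f, near = near + 1L)
}

#' Resize every axial slice of a volume
#'
#' Linear interpolation for intensity volumes; nearest-neighbor for
#' label volumes (so no new label values are invented).
#'
#' @param volume A `volume` or 3D array.
#' @param size Target in-plane size (output is `size x size` per slice).
#' @param is_label Force nearest-neighbor (defaults to the volume role).
#' @return Resized `volume` of shape `(size, size, nz)`.
#' @export
resize_inplane <- function(volume, size, is_label = NULL) {
  v <- .as_volume(volume)
  size <- .check_count(size, "size", 1L)
  if (is.null(is_label)) is_label <- v$role == "label"
  d <- dim(v$data)
  mx <- .resample_map(d[1L], size)
  my <- .resample_map(d[2L], size)
  out <- array(if (is_label) 0L else 0, c(size, size, d[3L]))
  for (z in seq_len(d[3L])) {
    s <- v$data[, , z]
    if (is_label) {
      out[, , z] <- s[mx$near, my$near]
    } else {
      rows <- s[mx$i0, , drop = FALSE] * (1 - mx$f) +
              s[mx$i1, , drop = FALSE] * mx$f
      out[, , z] <- rows[, my$i0, drop = FALSE] *
                      rep(1 - my$f, each = size) +
                    rows[, my$i1, drop = FALSE] * rep(my$f, each = size)
    }
  }
  if (is_label) out <- array(as.integer(out), dim(out))
  new_volume(out, affine = v$affine, role = v$role)
}

#' Min-max intensity normalization to [0, 1]
#'
#' The minimum and maximum are computed over suprathreshold (brain)
#' voxels only; the rescaled volume is clipped to `[0, 1]`.  Constant
#' volumes map to all zeros.
#'
#' @param volume An intensity `volume` or 3D array.
#' @param threshold Voxels strictly above this value enter the min/max
#'   statistics (default 0).
#' @return Normalized `volume` with values in `[0, 1]`.
#' @export
normalize_intensity <- function(volume, threshold = 0) {
  v <- .as_volume(volume)
  fg <- v$data[v$data > threshold]
  if (length(fg) == 0L || max(fg) == min(fg))
    return(new_volume(array(0, dim(v$data)), affine = v$affine,
                      role = v$role))
  mn <- min(fg); mx <- max(fg)
  out <- (v$data - mn) / (mx - mn)
  out[out < 0] <- 0; out[out > 1] <- 1
  new_volume(out, affine = v$affine, role = v$role)
}

#' Run the full preprocessing pipeline on one subject
#'
#' Pipeline order: bounding box on the reference modality's reference
#' slice, then for all four modalities and the mask: depth crop, ROI
#' crop (one shared box), in-plane resize (nearest for the mask), then
#' intensity normalization and label remapping to contiguous indices.
#' Fully deterministic.
#'
#' @param subject A `synthetic_subject`, a `subject_record`, or a list
#'   with `volumes` (named modality arrays) and `labels`/`seg`.
#' @param config A [preprocess_config()].
#' @return List of class `preprocessed_subject`: `subject_id`, `volumes`
#'   (named list of normalized 3D arrays), `mask` (integer array of
#'   class indices 0..3, or `NULL` if unlabeled), `roi` (the box),
#'   `config`.
#' @export
preprocess_subject <- function(subject, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  if (inherits(subject, "subject_record")) subject <- load_subject(subject)
  vols <- lapply(subject$volumes, function(v) .as_volume(v)$data)
  labels <- subject$labels
  if (is.null(labels) && !is.null(subject$seg))
    labels <- .as_volume(subject$seg, role = "label")$data
  shapes <- unique(lapply(vols, dim))
  if (length(shapes) != 1L ||
      (!is.null(labels) && !identical(dim(labels), shapes[[1L]])))
    .stopf("subject volumes do not share one shape")

  box <- compute_roi_box(vols[[config$reference_modality]], config)
  run1 <- function(arr, role) {
    v <- new_volume(arr, role = role)
    v <- crop_depth(v, config$depth_range)
    v <- apply_roi(v, box)
    v <- resize_inplane(v, config$target_inplane)
    v
  }
  out_vols <- lapply(vols, function(a) {
    v <- run1(a, "intensity")
    if (config$normalize) v <- normalize_intensity(v)
    v$data
  })
  mask <- NULL
  if (!is.null(labels))
    mask <- remap_labels(run1(array(as.integer(labels), dim(labels)),
                              "label"))$data

  structure(list(subject_id = subject$subject_id, volumes = out_vols,
                 mask = mask, roi = box, config = config),
            class = "preprocessed_subject")
}
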