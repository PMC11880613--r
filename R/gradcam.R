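#' Grad-CAM configuration for 3D segmentation models
#'
#' Segmentation has no single class score, so a scalar is formed by
#' reducing the per-voxel class logits: by default the mean logit of
#' `target_class` over the voxels *predicted* as that class (falling
#' back to the whole volume when the predicted region is empty).
#' Channel weights are spatial means of the score gradient at
#' `target_layer`; the ReLU-rectified weighted activation sum is
#' upsampled trilinearly to the input grid and min-max normalized.
#'
#' @param target_layer Named layer; `NULL` selects the last convolution
#'   before the output head (`"features"` for a U-Net, `"fusion"` for an
#'   ensemble).
#' @param target_class 0-based class index (default 3, the enhancing
#'   tumor class after remapping).
#' @param score_reduction `"predicted_region"` (default) or
#'   `"whole_volume"`.
#' @param colormap Only `"jet"` is built in.
#' @param alpha Default overlay opacity in `[0, 1]`.
#' @return Object of class `gradcam_config`.
#' @export
gradcam_config <- function(target_layer = NULL, target_class = 3L,
                           score_reduction = c("predicted_region",
                                               "whole_volume"),
                           colormap = "jet", alpha = 0.5) {
  structure(list(target_layer = target_layer,
                 target_class = .check_count(target_class, "target_class"),
                 score_reduction = match.arg(score_reduction),
                 colormap = match.arg(colormap, "jet"),
                 alpha = .check_number(alpha, "alpha", 0, 1)),
            class = "gradcam_config")
}

# trilinear resize of a 3D array (separable linear interpolation)
resize3d_linear <- function(arr, out_dims) {
  for (axis in 1:3) {
    n <- dim(arr)[1L]
    m <- .resample_map(n, out_dims[axis])
    W <- matrix(0, out_dims[axis], n)
    W[cbind(seq_len(out_dims[axis]), m$i0)] <-
      W[cbind(seq_len(out_dims[axis]), m$i0)] + (1 - m$f)
    W[cbind(seq_len(out_dims[axis]), m$i1)] <-
      W[cbind(seq_len(out_dims[axis]), m$i1)] + m$f
    d <- dim(arr)
    out <- W %*% matrix(arr, nrow = n)
    dim(out) <- c(out_dims[axis], d[2L], d[3L])
    arr <- aperm(out, c(2L, 3L, 1L))  # rotate axes: next axis to front
  }
  arr
}

#' Compute a Grad-CAM relevance volume
#'
#' @param model A `unet3d` or `ensemble3d` model (anything with an
#'   [nn_forward()] method and named layers).
#' @param x Input tensor matching the model's channel contract.
#' @param config A [gradcam_config()].
#' @return Object of class `heatmap`: `relevance` (3D array in `[0, 1]`
#'   on the input grid), `config`, `meta` (target layer, fallback flag,
#'   predicted-region size).
#' @export
compute_gradcam <- function(model, x, config = gradcam_config()) {
  stopifnot(inherits(config, "gradcam_config"))
  fw <- nn_forward(model, x, train = FALSE)
  tp <- fw$tape
  layer <- config$target_layer
  if (is.null(layer)) layer <- if (inherits(model, "ensemble3d")) "fusion"
                               else "features"
  tid <- tape_named_id(tp, layer)

  logits <- tape_value(tp, fw$logits)
  C <- dim(logits)[1L]
  if (config$target_class >= C)
    .stopf("target_class %d out of range [0, %d)", config$target_class, C)
  probs <- tape_value(tp, fw$out)
  pm <- matrix(probs, nrow = C)
  pred <- max.col(t(pm), ties.method = "first") - 1L
  mask <- pred == config$target_class
  fallback <- FALSE
  if (config$score_reduction == "whole_volume" || !any(mask)) {
    fallback <- !any(mask) && config$score_reduction == "predicted_region"
    mask <- rep(TRUE, length(pred))
  }

  # d(score)/d(logits): score = mean of target-class logits over mask
  seed <- array(0, dim(logits))
  sm <- matrix(seed, nrow = C)
  sm[config$target_class + 1L, mask] <- 1 / sum(mask)
  seed <- array(sm, dim(logits))

  bk <- tape_backward(tp, fw$logits, seed, keep_node_grads = TRUE)
  g <- bk$nodes[[tid]]
  if (is.null(g)) .stopf("no gradient reaches layer '%s'", layer)
  act <- tape_value(tp, tid)
  k <- dim(act)[1L]
  wts <- rowMeans(matrix(g, nrow = k))
  cam <- array(colSums(matrix(act, nrow = k) * wts), dim(act)[-1L])
  cam[cam < 0] <- 0

  in_sp <- dim(x)[-1L]
  if (!identical(dim(cam), in_sp)) cam <- resize3d_linear(cam, in_sp)
  cam[cam < 0] <- 0
  mx <- max(cam)
  if (mx > 0) cam <- cam / mx   # all-zero map stays zero

  structure(list(relevance = cam, config = config,
                 meta = list(target_layer = layer,
                             fallback_whole_volume = fallback,
                             predicted_region_voxels = sum(mask))),
            class = "heatmap")
}

#' @export
print.heatmap <- function(x, ...) {
  cat(sprintf("Grad-CAM heat map: shape (%s), layer '%s', class %d%s\n",
              paste(dim(x$relevance), collapse = ", "),
              x$meta$target_layer, x$config$target_class,
              if (x$meta$fallback_whole_volume)
                " [fallback: whole-volume score]" else ""))
  invisible(x)
}

#' Export a heat map as NIfTI aligned to the (preprocessed) input grid
#' @param heatmap A [compute_gradcam()] result.
#' @param path Output `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(heatmap, path) {
  stopifnot(inherits(heatmap, "heatmap"))
  RNifti::writeNifti(RNifti::asNifti(heatmap$relevance), path)
  invisible(path)
}

# jet colormap: v in [0,1] -> n x 3 rgb in [0,1]
.jet <- function(v) {
  r <- pmin(pmax(1.5 - abs(4 * v - 3), 0), 1)
  g <- pmin(pmax(1.5 - abs(4 * v - 2), 0), 1)
  b <- pmin(pmax(1.5 - abs(4 * v - 1), 0), 1)
  cbind(r, g, b)
}

.gray_rgb <- function(slice) {
  rng <- range(slice)
  gr <- if (diff(rng) > 0) (slice - rng[1L]) / diff(rng)
        else slice * 0
  array(rep(gr, 3L), c(dim(slice), 3L))
}

#' Render a heat-map overlay for one axial slice
#'
#' Blends the colormapped relevance over the grayscale background at
#' opacity `alpha` (`alpha = 0` reproduces the background exactly) and
#' writes a PNG.  `panels` may name additional modality volumes whose
#' raw slices are rendered beside the overlay.
#'
#' @param heatmap A [compute_gradcam()] result.
#' @param background Intensity volume (3D array) on the same grid.
#' @param slice_index 0-based axial slice index.
#' @param alpha Overlay opacity in `[0, 1]` (default from the heat map's
#'   config).
#' @param file Output PNG path.
#' @param panels Optional named list of additional 3D arrays rendered
#'   side by side before the overlay.
#' @return Invisibly, the rendered RGB array (rows x cols x 3).
#' @export
overlay <- function(heatmap, background, slice_index, alpha = NULL,
                    file = NULL, panels = NULL) {
  stopifnot(inherits(heatmap, "heatmap"))
  bg <- .as_volume(background)$data
  if (!identical(dim(bg), dim(heatmap$relevance)))
    .stopf("background shape (%s) does not match heat map (%s)",
           paste(dim(bg), collapse = ","),
           paste(dim(heatmap$relevance), collapse = ","))
  nz <- dim(bg)[3L]
  if (slice_index < 0 || slice_index >= nz)
    .stopf("slice_index %d out of range [0, %d)", slice_index, nz)
  if (is.null(alpha)) alpha <- heatmap$config$alpha
  alpha <- .check_number(alpha, "alpha", 0, 1)

  z <- slice_index + 1L
  gray <- .gray_rgb(bg[, , z])
  rel <- heatmap$relevance[, , z]
  col <- array(.jet(as.vector(rel)), c(dim(rel), 3L))
  img <- (1 - alpha) * gray + alpha * col

  if (!is.null(panels)) {
    strips <- lapply(panels, function(v) .gray_rgb(.as_volume(v)$data[, , z]))
    img <- do.call(cbind3, c(strips, list(img)))
  }
  if (!is.null(file)) png::writePNG(img, file)
  invisible(img)
}

# bind rgb arrays side by side
cbind3 <- function(...) {
  parts <- list(...)
  h <- dim(parts[[1L]])[1L]
  w <- sum(vapply(parts, function(p) dim(p)[2L], numeric(1)))
  out <- array(0, c(h, w, 3L))
  at <- 0L
  for (p in parts) {
    out[, at + seq_len(dim(p)[2L]), ] <- p
    at <- at + dim(p)[2L]
  }
  out
}
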