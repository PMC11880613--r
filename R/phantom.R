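#' Default tissue-contrast table for phantom subjects
#'
#' Mean intensities (arbitrary units) for each tissue class and modality.
#' The table encodes the clinically familiar contrast structure: T1 has
#' little tumor contrast, T2 and FLAIR make peritumoral edema bright,
#' T1ce makes the enhancing rim bright and the necrotic core dark.  It is
#' deliberately constructed so that *no single modality* separates all
#' tissue classes (T1ce confounds edema with normal brain; T2 and FLAIR
#' confound core with enhancing tumor), which makes multi-modality fusion
#' genuinely informative on these phantoms.
#'
#' @return 5x4 numeric matrix, rows `background, brain, core, edema,
#'   enhancing`, columns `T1, T1ce, T2, FLAIR`.
#' @export
default_contrast_table <- function() {
  m <- rbind(
    background = c(0,   0,   0,   0),
    brain      = c(100, 100, 80,  70),
    core       = c(90,  60,  120, 110),
    edema      = c(95,  100, 160, 150),
    enhancing  = c(95,  180, 120, 110))
  colnames(m) <- MODALITIES
  m
}

#' Specification of a synthetic multimodal phantom subject
#'
#' Defines the geometry, tumor layout, contrast and noise of a
#' BraTS-like phantom: an ellipsoidal brain centered in the grid with
#' `n_tumors` nested spheroid tumors (edema shell enclosing necrotic
#' core enclosing enhancing center, so the enhancing-within-core-within-
#' whole-tumor nesting of BraTS annotations holds by construction).
#'
#' @param grid_shape Integer triple `(nx, ny, nz)`; the default matches
#'   the standard 240 x 240 axial grid with 155 slices.
#' @param brain_semiaxes_frac Ellipsoid semi-axes as fractions of the
#'   grid half-extent, each in `(0, 1]`.
#' @param n_tumors Number of tumors, `>= 0`.
#' @param tumor_radius_frac_range `(min, max)` whole-tumor radius as a
#'   fraction of the smallest brain semi-axis.
#' @param contrast_table Tissue-by-modality mean intensity matrix; see
#'   [default_contrast_table()].
#' @param noise_sigma Additive Gaussian noise standard deviation, `>= 0`.
#' @param seed Integer seed; identical spec + seed gives bit-identical
#'   subjects.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(240L, 240L, 155L),
                         brain_semiaxes_frac = c(0.85, 0.85, 0.85),
                         n_tumors = 1L,
                         tumor_radius_frac_range = c(0.25, 0.40),
                         contrast_table = default_contrast_table(),
                         noise_sigma = 10,
                         seed = 1L) {
  if (length(grid_shape) != 3L || any(grid_shape < 4))
    .stopf("'grid_shape' must be three integers >= 4")
  grid_shape <- as.integer(grid_shape)
  if (length(brain_semiaxes_frac) != 3L ||
      any(brain_semiaxes_frac <= 0) || any(brain_semiaxes_frac > 1))
    .stopf("'brain_semiaxes_frac' must be three fractions in (0, 1]")
  n_tumors <- .check_count(n_tumors, "n_tumors")
  if (length(tumor_radius_frac_range) != 2L ||
      any(tumor_radius_frac_range <= 0) || any(tumor_radius_frac_range > 1) ||
      tumor_radius_frac_range[1L] > tumor_radius_frac_range[2L])
    .stopf("'tumor_radius_frac_range' must be 0 < min <= max <= 1")
  classes <- c("background", "brain", "core", "edema", "enhancing")
  if (!all(classes %in% rownames(contrast_table)) ||
      !all(MODALITIES %in% colnames(contrast_table)))
    .stopf("'contrast_table' must cover tissue classes {%s} x modalities {%s}",
           paste(classes, collapse = ", "), paste(MODALITIES, collapse = ", "))
  noise_sigma <- .check_number(noise_sigma, "noise_sigma", 0)
  seed <- .check_count(seed, "seed")
  structure(list(grid_shape = grid_shape,
                 brain_semiaxes_frac = brain_semiaxes_frac,
                 n_tumors = n_tumors,
                 tumor_radius_frac_range = tumor_radius_frac_range,
                 contrast_table = contrast_table[classes, MODALITIES],
                 noise_sigma = noise_sigma,
                 seed = seed),
            class = "phantom_spec")
}

#' Generate one synthetic multimodal subject
#'
#' Produces four modality volumes and a label volume in the raw BraTS
#' label dialect (0 background/normal brain, 1 necrotic core, 2 edema,
#' 4 enhancing tumor).  Each voxel's intensity is its tissue-class mean
#' from the contrast table plus Gaussian noise, clipped at zero.
#' Deterministic given `spec$seed` and `subject_id`.
#'
#' @param spec A [phantom_spec()].
#' @param subject_id Subject identifier (used in file names and to
#'   decorrelate subjects sharing one spec seed).
#' @return An object of class `synthetic_subject`: list with
#'   `subject_id`, `volumes` (named list of 3D arrays), `labels`
#'   (integer 3D array), and `spec`.
#' @export
generate_subject <- function(spec, subject_id = "phantom-001") {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.character(subject_id) || length(subject_id) != 1L ||
      !nzchar(subject_id))
    .stopf("'subject_id' must be a nonempty string")
  set.seed(derive_seed(spec$seed, paste0("subject:", subject_id)))

  g <- spec$grid_shape
  half <- (g - 1) / 2
  semi <- spec$brain_semiaxes_frac * half
  ctr <- half  # 0-based center

  # ellipsoid brain mask (scaled squared distance to center <= 1)
  dx2 <- ((seq_len(g[1L]) - 1 - ctr[1L]) / semi[1L])^2
  dy2 <- ((seq_len(g[2L]) - 1 - ctr[2L]) / semi[2L])^2
  dz2 <- ((seq_len(g[3L]) - 1 - ctr[3L]) / semi[3L])^2
  d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  brain <- d2 <= 1

  labels <- array(0L, g)
  rmin <- min(semi)
  for (t in seq_len(spec$n_tumors)) {
    placed <- FALSE
    for (try in 1:100) {
      r <- runif(1, spec$tumor_radius_frac_range[1L],
                 spec$tumor_radius_frac_range[2L]) * rmin
      # sample a center well inside the brain (conservative bound)
      u <- runif(3, -1, 1)
      cen <- ctr + u * (semi * max(0, 1 - r / rmin) * 0.9)
      if (sum(((cen - ctr) / semi)^2) + (r / rmin)^2 > 1) next
      # anisotropic nested ellipsoids with per-tumor random shell
      # fractions: sub-region boundaries are then not predictable from
      # outer shape alone, so resolving all three classes genuinely
      # requires the modality contrasts, not geometry
      ax <- runif(3, 0.7, 1.3)
      ax <- ax / max(ax)
      core_frac <- runif(1, 0.50, 0.80)
      enh_frac <- runif(1, 0.25, core_frac - 0.15)
      tx2 <- ((seq_len(g[1L]) - 1 - cen[1L]) / ax[1L])^2
      ty2 <- ((seq_len(g[2L]) - 1 - cen[2L]) / ax[2L])^2
      tz2 <- ((seq_len(g[3L]) - 1 - cen[3L]) / ax[3L])^2
      td <- sqrt(outer(outer(tx2, ty2, `+`), tz2, `+`))
      wt <- td <= r
      # the whole tumor must lie inside the brain mask; a placement
      # poking outside is rejected and retried
      if (!any(wt) || any(wt & !brain)) next
      labels[wt] <- 2L                       # edema (whole-tumor shell)
      labels[td <= core_frac * r] <- 1L      # necrotic core
      labels[td <= enh_frac * r] <- 4L       # enhancing center
      placed <- TRUE
      break
    }
    if (!placed)
      .stopf("could not place tumor %d inside the brain after 100 tries; reduce 'tumor_radius_frac_range'", t)
  }

  class_idx <- array(1L, g)                 # 1 = background row
  class_idx[brain] <- 2L                    # brain
  class_idx[labels == 1L] <- 3L             # core
  class_idx[labels == 2L] <- 4L             # edema
  class_idx[labels == 4L] <- 5L             # enhancing

  volumes <- lapply(MODALITIES, function(mod) {
    v <- spec$contrast_table[, mod][class_idx]
    if (spec$noise_sigma > 0)
      v <- v + rnorm(length(v), sd = spec$noise_sigma)
    v[v < 0] <- 0
    array(v, g)
  })
  names(volumes) <- MODALITIES

  structure(list(subject_id = subject_id, volumes = volumes,
                 labels = labels, spec = spec),
            class = "synthetic_subject")
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("Synthetic subject '%s': grid (%s), labels {%s}\n",
              x$subject_id, paste(dim(x$labels), collapse = ", "),
              paste(sort(unique(as.integer(x$labels))), collapse = ", ")))
  invisible(x)
}

#' Write a subject to disk in BraTS directory layout
#'
#' Creates `root/<subject_id>/` with five compressed NIfTI files named
#' `<subject_id>_{t1,t1ce,t2,flair,seg}.nii.gz` (identity affine).
#' Integer labels round-trip exactly.
#'
#' @param subject A [generate_subject()] result.
#' @param root Output directory (created if needed).
#' @return Invisibly, the five file paths written.
#' @export
write_brats_layout <- function(subject, root) {
  stopifnot(inherits(subject, "synthetic_subject"))
  dir <- file.path(root, subject$subject_id)
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) .stopf("cannot create directory '%s'", dir)
  paths <- character(0)
  for (mod in MODALITIES) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", subject$subject_id,
                                .modality_suffix[[mod]]))
    RNifti::writeNifti(RNifti::asNifti(subject$volumes[[mod]]), p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, sprintf("%s_seg.nii.gz", subject$subject_id))
  RNifti::writeNifti(RNifti::asNifti(subject$labels, datatype = "int16"), p)
  paths <- c(paths, p)
  invisible(paths)
}
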