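#' Discover BraTS-layout subjects under a directory
#'
#' Scans each subdirectory of `root` for the four modality files
#' `<id>_{t1,t1ce,t2,flair}` (`.nii` or `.nii.gz`) and the optional
#' `<id>_seg` mask.  Records are sorted by subject id.
#'
#' @param root Dataset directory.
#' @param strict If `TRUE`, a subdirectory missing any modality file is
#'   an error naming the missing file; otherwise it is reported via a
#'   warning and excluded.
#' @return List of `subject_record` objects, each with `subject_id`,
#'   `modality_paths` (named T1/T1ce/T2/FLAIR) and `seg_path`
#'   (`NA` if unlabeled).
#' @export
discover_subjects <- function(root, strict = FALSE) {
  if (!dir.exists(root)) .stopf("dataset root '%s' does not exist", root)
  dirs <- sort(list.dirs(root, recursive = FALSE))
  records <- list()
  for (d in dirs) {
    id <- basename(d)
    find1 <- function(suffix) {
      for (ext in c(".nii.gz", ".nii")) {
        p <- file.path(d, paste0(id, "_", suffix, ext))
        if (file.exists(p)) return(p)
      }
      NA_character_
    }
    paths <- vapply(.modality_suffix, find1, character(1))
    names(paths) <- MODALITIES
    if (anyNA(paths)) {
      missing <- .modality_suffix[is.na(paths)]
      if (strict)
        .stopf("subject '%s' is missing modality file(s): %s", id,
               paste(missing, collapse = ", "))
      warning(sprintf("excluding incomplete subject '%s' (missing: %s)",
                      id, paste(missing, collapse = ", ")), call. = FALSE)
      next
    }
    records[[length(records) + 1L]] <-
      structure(list(subject_id = id,
                     modality_paths = as.list(paths),
                     seg_path = find1("seg")),
                class = "subject_record")
  }
  records
}

#' Load a 3D NIfTI volume
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param as_label If `TRUE` the data must be integer-valued; the array
#'   is returned as integers and marked so downstream resampling uses
#'   nearest-neighbor interpolation only.
#' @return A `volume`: list with `data` (3D array), `affine` (4x4
#'   matrix) and `role` (`"intensity"` or `"label"`).
#' @export
load_volume <- function(path, as_label = FALSE) {
  if (!file.exists(path)) .stopf("cannot read NIfTI file '%s'", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) .stopf("corrupt NIfTI '%s': %s", path,
                                             conditionMessage(e)))
  a <- as.array(img)
  if (length(dim(a)) != 3L)
    .stopf("'%s' is %dD; only 3D volumes are supported", path,
           length(dim(a)))
  a <- array(as.numeric(a), dim(a))  # drop NIfTI header attributes
  affine <- tryCatch(unclass(RNifti::xform(img)),
                     error = function(e) diag(4))
  if (as_label) {
    if (any(a != round(a)))
      .stopf("label volume '%s' contains non-integer values", path)
    a <- array(as.integer(a), dim(a))
  }
  new_volume(a, affine = affine,
             role = if (as_label) "label" else "intensity")
}

#' Construct a volume container
#' @param data 3D numeric array.
#' @param affine 4x4 spatial transform (default identity).
#' @param role `"intensity"` or `"label"`.
#' @return An object of class `volume`.
#' @export
new_volume <- function(data, affine = diag(4), role = "intensity") {
  if (length(dim(data)) != 3L) .stopf("volume data must be a 3D array")
  role <- match.arg(role, c("intensity", "label"))
  if (role == "label" && any(data != round(data)))
    .stopf("label volume contains non-integer values")
  structure(list(data = data, affine = affine, role = role),
            class = "volume")
}

# accept plain arrays where a volume is expected
.as_volume <- function(x, role = "intensity") {
  if (inherits(x, "volume")) x else new_volume(x, role = role)
}

#' Remap raw BraTS labels to contiguous class indices
#'
#' The raw dialect uses `{0, 1, 2, 4}` (label 3 unused by convention); a
#' softmax head needs contiguous indices, so `4` is mapped to `3`.  The
#' inverse map is attached as the `inverse_map` attribute so predictions
#' can be exported back to the raw dialect with [unmap_labels()].
#'
#' @param labels A label `volume` or integer 3D array with values in
#'   `{0, 1, 2, 4}`.
#' @return A label `volume` with values in `{0, 1, 2, 3}` and an
#'   `inverse_map` attribute `c(0, 1, 2, 4)`.
#' @export
remap_labels <- function(labels) {
  v <- .as_volume(labels, role = "label")
  vals <- unique(as.integer(v$data))
  bad <- setdiff(vals, c(0L, 1L, 2L, 4L))
  if (length(bad))
    .stopf("unexpected label value(s): %s (expected subset of {0, 1, 2, 4})",
           paste(sort(bad), collapse = ", "))
  out <- v$data
  out[out == 4L] <- 3L
  res <- new_volume(array(as.integer(out), dim(out)), affine = v$affine,
                    role = "label")
  attr(res, "inverse_map") <- c(0L, 1L, 2L, 4L)
  res
}

#' Map contiguous class indices back to the raw BraTS dialect
#' @param labels Label `volume`/array with values in `{0, 1, 2, 3}`.
#' @return Label `volume` with values in `{0, 1, 2, 4}`.
#' @export
unmap_labels <- function(labels) {
  v <- .as_volume(labels, role = "label")
  bad <- setdiff(unique(as.integer(v$data)), 0:3)
  if (length(bad))
    .stopf("unexpected class index value(s): %s", paste(bad, collapse = ", "))
  out <- v$data
  out[out == 3L] <- 4L
  new_volume(array(as.integer(out), dim(out)), affine = v$affine,
             role = "label")
}

#' Subject-level train/validation/test split
#'
#' Ids are shuffled by a seeded RNG; sizes are
#' `floor(n * f_train)`, `floor(n * f_val)`, remainder to test.
#' Splitting is always at subject level (never slice level) to prevent
#' leakage between partitions.
#'
#' @param ids Character/atomic vector of unique subject ids.
#' @param fractions Length-3 positive fractions summing to 1 (default
#'   `c(0.70, 0.15, 0.15)`).
#' @param seed Integer seed.
#' @return An object of class `dataset_split`: list with `train_ids`,
#'   `val_ids`, `test_ids`, `fractions`, `seed`.
#' @export
split_dataset <- function(ids, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (anyDuplicated(ids)) .stopf("'ids' must be unique")
  if (length(fractions) != 3L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    .stopf("'fractions' must be three positive values summing to 1")
  seed <- .check_count(seed, "seed")
  n <- length(ids)
  set.seed(derive_seed(seed, "split"))
  shuffled <- sample(ids, n)
  n_train <- floor(n * fractions[1L])
  n_val <- floor(n * fractions[2L])
  structure(list(train_ids = shuffled[seq_len(n_train)],
                 val_ids = shuffled[n_train + seq_len(n_val)],
                 test_ids = shuffled[setdiff(seq_len(n),
                                             seq_len(n_train + n_val))],
                 fractions = fractions, seed = seed),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("Dataset split (seed %d): %d train / %d val / %d test\n",
              x$seed, length(x$train_ids), length(x$val_ids),
              length(x$test_ids)))
  invisible(x)
}

#' Persist a split manifest as JSON
#' @param split A [split_dataset()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_split <- function(split, path) {
  .write_json(unclass(split), path)
  invisible(path)
}

# load the five volumes of a subject record into memory
load_subject <- function(record) {
  vols <- lapply(record$modality_paths, load_volume)
  seg <- if (!is.na(record$seg_path)) load_volume(record$seg_path,
                                                  as_label = TRUE)
  list(subject_id = record$subject_id, volumes = vols, seg = seg)
}
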