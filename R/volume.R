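#' Voxel volume container
#'
#' A `voxel_volume` holds a 3-D binary mask together with its voxel spacing
#' in millimetres.  Foreground voxels are exactly 1, background exactly 0.
#' Fractal-dimension estimation assumes isotropic voxels: with anisotropic
#' spacing a cubic counting box has different physical extents along each
#' axis and the scale axis of the log-log plot loses its meaning, so the
#' constructor enforces a relative isotropy tolerance of `1e-3` unless
#' `strict = FALSE`.
#'
#' @param data 3-D array; any nonzero value is treated as foreground.
#' @param spacing voxel size in mm, length 1 (isotropic) or 3.
#' @param strict enforce isotropy (default `TRUE`).
#' @return An object of class `voxel_volume` with elements `data` (integer
#'   0/1 array), `spacing` (length-3 numeric, mm) and `shape`.
#' @examples
#' v <- voxel_volume(array(1, c(8, 8, 8)), spacing = 1)
#' sum(v$data)
#' @export
voxel_volume <- function(data, spacing = 1, strict = TRUE) {
  if (length(dim(data)) != 3L)
    stop("NotThreeDimensional: `data` must be a 3-D array, got ",
         length(dim(data)), " dimensions")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("InvalidSpacing: spacing must be 1 or 3 positive finite values (mm)")
  if (strict && max(spacing) / min(spacing) > 1 + 1e-3)
    stop("AnisotropicVoxels: spacing ", paste(signif(spacing, 6), collapse = "x"),
         " mm exceeds the 1e-3 relative isotropy tolerance")
  mask <- array(as.integer(data != 0), dim = dim(data))
  structure(
    list(data = mask, spacing = as.numeric(spacing), shape = dim(mask)),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("voxel_volume:", paste(x$shape, collapse = " x "), "voxels,",
      "spacing", paste(signif(x$spacing, 4), collapse = " x "), "mm\n")
  cat("  foreground voxels:", sum(x$data), "\n")
  invisible(x)
}

#' Read a binary mask from a NIfTI file
#'
#' Loads a 3-D volume, binarizes it with the nonzero rule (any value != 0
#' becomes foreground) and takes the voxel spacing from the header.  The
#' nonzero rule makes both label images and float probability masks usable
#' as input.
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param strict refuse anisotropic voxels (relative tolerance 1e-3);
#'   default `TRUE` because anisotropy silently distorts the scale axis.
#' @return A [voxel_volume].
#' @seealso [write_mask()]
#' @export
read_mask <- function(path, strict = TRUE) {
  if (!file.exists(path))
    stop("FileUnreadable: no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("FileUnreadable: ", conditionMessage(e)))
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1L]
  if (length(dim(arr)) != 3L)
    stop("NotThreeDimensional: expected a 3-D volume, got dims ",
         paste(dim(arr), collapse = "x"))
  sp <- RNifti::pixdim(img)[seq_len(3)]
  voxel_volume(arr, spacing = sp, strict = strict)
}

#' Write a binary mask to a NIfTI file
#'
#' Round-trips exactly: `read_mask(write_mask(vol, path))` reproduces the
#' voxel data and spacing.  Validity of the mask for estimation (e.g. a
#' nonempty foreground) is enforced at estimation time, not here.
#'
#' @param vol a [voxel_volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(vol, path) {
  stopifnot(inherits(vol, "voxel_volume"))
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0)
    stop("PathNotWritable: cannot write to ", path)
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a cohort table
#'
#' Reads a per-subject CSV (header row, comma separated) with at least a
#' `subject_id` column, and validates the columns a downstream model needs:
#' present, numeric where expected, no missing values, strictly positive
#' ages, unique subject ids.  Sex may be coded 0/1 or as strings
#' (`"M"`/`"F"`, mapped to 0/1).
#'
#' @param path CSV file.
#' @param required character vector of column names that must be present
#'   and complete (default `c("subject_id", "age")`).
#' @return A `data.frame` with one row per subject.
#' @export
read_cohort <- function(path, required = c("subject_id", "age")) {
  if (!file.exists(path))
    stop("FileUnreadable: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df, required)
}

# Shared validation so simulated cohorts obey the same contract as loaded ones.
validate_cohort <- function(df, required = c("subject_id", "age")) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("MissingColumn: ", paste(missing_cols, collapse = ", "))
  if ("sex" %in% names(df) && is.character(df$sex)) {
    up <- toupper(trimws(df$sex))
    if (!all(up %in% c("M", "F")))
      stop("NonNumericValue: sex must be 0/1 or M/F")
    df$sex <- as.integer(up == "F")
  }
  numeric_cols <- setdiff(intersect(required, names(df)), "subject_id")
  for (cl in numeric_cols) {
    if (!is.numeric(df[[cl]]))
      stop("NonNumericValue: column '", cl, "' is not numeric")
    if (anyNA(df[[cl]]))
      stop("MissingValues: column '", cl, "' contains NA")
  }
  if ("age" %in% names(df) && any(df$age <= 0, na.rm = TRUE))
    stop("InvalidParams: ages must be strictly positive")
  if (anyDuplicated(df$subject_id))
    stop("DuplicateSubjectId: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  df
}
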