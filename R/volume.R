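#' Construct a volume
#'
#' A `volume` is one subject's rank-3 array of voxel values together with its
#' voxel spacing and provenance. The array is indexed `(h, w, l)` and holds
#' arbitrary MR intensity units for `modality = "flair"` or strictly binary
#' values for `modality = "wmh_mask"`. All index conventions in this package
#' are 0-based and half-open.
#'
#' @param data rank-3 numeric array, indexed `(h, w, l)`.
#' @param spacing numeric length-3 vector of voxel edge lengths in mm
#'   (all strictly positive).
#' @param subject_id character scalar identifying the subject.
#' @param modality `"flair"` or `"wmh_mask"`. Masks must contain only 0/1.
#' @return An object of class `volume`.
#' @export
volume <- function(data, spacing = c(1, 1, 1), subject_id = "unknown",
                   modality = c("flair", "wmh_mask")) {
  modality <- match.arg(modality)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_wmh("wmh_format_error", "volume data must be a rank-3 array")
  if (any(dim(data) < 1L))
    stop_wmh("wmh_validation_error", "all volume dimensions must be >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_wmh("wmh_validation_error", "spacing must be 3 positive numbers")
  if (modality == "wmh_mask" && !all(data %in% c(0, 1)))
    stop_wmh("wmh_validation_error",
             "wmh_mask volume contains values other than {0, 1}")
  structure(list(data = data, spacing = spacing,
                 subject_id = as.character(subject_id), modality = modality),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<volume> %s [%s]  %s  spacing %s mm\n", x$subject_id,
              x$modality, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' @export
dim.volume <- function(x) dim(x$data)

#' Bundle a subject's paired volumes and label
#'
#' @param subject_id character scalar.
#' @param flair `volume` with modality `"flair"`.
#' @param mask `volume` with modality `"wmh_mask"`.
#' @param label class label (character scalar), e.g. `"MS"` or `"NMOSD"`.
#' @param meta optional list of generator/preprocessing metadata.
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, flair, mask, label, meta = list()) {
  stopifnot(inherits(flair, "volume"), inherits(mask, "volume"))
  structure(list(subject_id = as.character(subject_id), flair = flair,
                 mask = mask, label = as.character(label), meta = meta),
            class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s  label=%s  flair %s / mask %s\n",
              x$subject_id, x$label,
              paste(dim(x$flair$data), collapse = "x"),
              paste(dim(x$mask$data), collapse = "x")))
  invisible(x)
}

#' Read a NIfTI volume
#'
#' Reads a `.nii` / `.nii.gz` file in its stored orientation (no
#' reorientation is applied). A 4D file with a singleton trailing dimension
#' is squeezed to rank 3. Mask volumes are binarized at a threshold of 0.5
#' on the stored values, accommodating exports that encode lesions as 1 or
#' as 255; stored values must cluster at 0 and at the file maximum, anything
#' in between is rejected.
#'
#' @param path path to an existing NIfTI file.
#' @param modality `"flair"` or `"wmh_mask"`.
#' @param subject_id subject identifier to attach (defaults to file stem).
#' @param tol tolerance for deciding that a stored mask value sits at 0 or
#'   at the plateau maximum.
#' @return A [volume].
#' @export
read_volume <- function(path, modality = c("flair", "wmh_mask"),
                        subject_id = NULL, tol = 1e-3) {
  modality <- match.arg(modality)
  if (!file.exists(path))
    stop_wmh("wmh_io_error", "file not found: %s", path)
  img <- RNifti::readNifti(path)
  data <- as.array(img)
  d <- dim(data)
  if (length(d) == 4L && d[4] == 1L) {
    data <- array(data, d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L)
    stop_wmh("wmh_format_error",
             "%s: expected a rank-3 volume, got rank %d", path, length(d))
  spacing <- abs(RNifti::pixdim(img))[seq_len(3)]
  spacing[spacing == 0] <- 1
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  if (modality == "wmh_mask") {
    mx <- max(data)
    near0 <- abs(data) <= tol * max(1, mx)
    nearmx <- abs(data - mx) <= tol * max(1, mx)
    if (!all(near0 | nearmx))
      stop_wmh("wmh_validation_error",
               "%s: mask has values away from both 0 and its maximum", path)
    data <- array(as.numeric(data > 0.5), d)
  }
  volume(data, spacing = spacing, subject_id = subject_id,
         modality = modality)
}

#' Write a volume to NIfTI
#'
#' @param v a [volume].
#' @param path output path ending in `.nii` or `.nii.gz`; the parent
#'   directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume"))
  if (!dir.exists(dirname(path)))
    stop_wmh("wmh_io_error", "directory does not exist: %s", dirname(path))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest is a UTF-8 CSV with header
#' `subject_id,flair_path,mask_path,label`. Relative paths are resolved
#' against the manifest's own directory. Subject ids must be unique and
#' labels must come from exactly one or two classes; referenced files are
#' only touched when a subject is actually loaded.
#'
#' @param path path to the CSV file.
#' @return A `data.frame` of class `wmh_manifest`, row order preserved.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop_wmh("wmh_io_error", "manifest not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("subject_id", "flair_path", "mask_path", "label")
  if (!all(need %in% names(df)))
    stop_wmh("wmh_format_error", "manifest must have columns %s",
             paste(need, collapse = ","))
  df <- df[, need]
  validate_manifest(df)
  base <- dirname(normalizePath(path))
  for (col in c("flair_path", "mask_path")) {
    rel <- !grepl("^(/|~|[A-Za-z]:)", df[[col]])
    df[[col]][rel] <- file.path(base, df[[col]][rel])
  }
  class(df) <- c("wmh_manifest", "data.frame")
  df
}

validate_manifest <- function(df) {
  if (anyDuplicated(df$subject_id))
    stop_wmh("wmh_validation_error", "duplicate subject_id in manifest: %s",
             paste(unique(df$subject_id[duplicated(df$subject_id)]),
                   collapse = ", "))
  labs <- unique(df$label)
  if (length(labs) > 2L)
    stop_wmh("wmh_validation_error",
             "manifest has %d distinct labels (max 2): %s",
             length(labs), paste(labs, collapse = ", "))
  invisible(df)
}

#' Write a cohort manifest
#'
#' @param df data.frame with columns `subject_id,flair_path,mask_path,label`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(df, path) {
  validate_manifest(df)
  write.csv(as.data.frame(df)[, c("subject_id", "flair_path", "mask_path",
                                  "label")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load one subject of a manifest
#'
#' @param manifest a manifest from [read_manifest].
#' @param i row index or subject id.
#' @return A [subject_record].
#' @export
load_subject <- function(manifest, i) {
  if (is.character(i)) i <- match(i, manifest$subject_id)
  row <- manifest[i, ]
  flair <- read_volume(row$flair_path, "flair", subject_id = row$subject_id)
  mask <- read_volume(row$mask_path, "wmh_mask", subject_id = row$subject_id)
  subject_record(row$subject_id, flair, mask, row$label)
}

#' Load every subject of a manifest
#'
#' @inheritParams load_subject
#' @return List of [subject_record]s, in manifest order.
#' @export
load_cohort <- function(manifest) {
  lapply(seq_len(nrow(manifest)), function(i) load_subject(manifest, i))
}
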