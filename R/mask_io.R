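#' Read a 3D mask volume from NIfTI
#'
#' Reads a `.nii` / `.nii.gz` volume into a [voxel_grid()], taking the
#' voxel spacing from the header. Only 3D volumes are accepted.
#'
#' @param path path to a NIfTI file.
#' @param expect_binary if `TRUE`, any nonzero voxel is mapped to 1 (label
#'   volumes collapse to a binary mask); otherwise integer values are kept.
#' @return A `voxel_grid`.
#' @export
read_mask <- function(path, expect_binary = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1]
    d <- dim(img)
  }
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), "D: ", path,
         call. = FALSE)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("non-positive voxel spacing in header: ", path, call. = FALSE)
  vals <- array(as.integer(round(as.numeric(img))), d)
  if (expect_binary) vals <- array(as.integer(vals != 0L), d)
  voxel_grid(vals, sp, binary = expect_binary)
}

#' Write a voxel grid to NIfTI
#'
#' @param grid a `voxel_grid`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(grid, path) {
  stopifnot(is_voxel_grid(grid))
  img <- RNifti::asNifti(grid$values)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

manifest_required_cols <- c("subject_id", "epvs_mask", "wml_mask",
                            "region_source", "icv_mm3", "age", "sex",
                            "diagnosis")
manifest_optional_cols <- c("amyloid_suvr", "tracer", "apoe")

#' Read a cohort manifest
#'
#' The manifest is a UTF-8 CSV with one row per subject and columns
#' `subject_id, epvs_mask, wml_mask, region_source, icv_mm3, age, sex,
#' diagnosis, amyloid_suvr, tracer, apoe`. The last three are optional
#' (may be empty), but a tracer must be given whenever an amyloid SUVR is.
#' `sex` is `female`/`male`; `diagnosis` is `CU`/`MCI`/`AD`; `apoe` is a
#' slash-separated allele pair such as `e3/e4`.
#'
#' In strict mode (default) any invalid row aborts the read; in lenient
#' mode invalid rows are dropped with a warning naming the row. Silent
#' cohort shrinkage corrupts group statistics, hence the strict default.
#'
#' @param path CSV path.
#' @param strict abort on invalid rows (`TRUE`) or skip them (`FALSE`).
#' @return A data.frame with one validated row per subject and an
#'   attribute `skipped` (character vector of messages) in lenient mode.
#' @export
read_manifest <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = "character", check.names = FALSE)
  miss <- setdiff(manifest_required_cols, names(df))
  if (length(miss))
    stop("manifest missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in manifest_optional_cols)
    if (!col %in% names(df)) df[[col]] <- NA_character_
  df[df == ""] <- NA_character_

  problems <- character(0)
  bad <- logical(nrow(df))
  note <- function(i, msg) sprintf("row %d (%s): %s", i,
                                   df$subject_id[i] %||% "?", msg)
  icv <- suppressWarnings(as.numeric(df$icv_mm3))
  age <- suppressWarnings(as.numeric(df$age))
  suvr <- suppressWarnings(as.numeric(df$amyloid_suvr))
  for (i in seq_len(nrow(df))) {
    if (is.na(df$subject_id[i])) {
      problems <- c(problems, note(i, "missing subject_id")); bad[i] <- TRUE
    } else if (is.na(icv[i]) || icv[i] <= 0) {
      problems <- c(problems, note(i, sprintf(
        "column icv_mm3: '%s' is not a positive number", df$icv_mm3[i])))
      bad[i] <- TRUE
    } else if (is.na(age[i])) {
      problems <- c(problems, note(i, sprintf(
        "column age: '%s' is not numeric", df$age[i]))); bad[i] <- TRUE
    } else if (!df$sex[i] %in% c("female", "male")) {
      problems <- c(problems, note(i, sprintf(
        "column sex: unknown code '%s'", df$sex[i]))); bad[i] <- TRUE
    } else if (!df$diagnosis[i] %in% c("CU", "MCI", "AD")) {
      problems <- c(problems, note(i, sprintf(
        "column diagnosis: unknown code '%s'", df$diagnosis[i])))
      bad[i] <- TRUE
    } else if (!is.na(df$amyloid_suvr[i]) && is.na(suvr[i])) {
      problems <- c(problems, note(i, "column amyloid_suvr: not numeric"))
      bad[i] <- TRUE
    } else if (!is.na(suvr[i]) && is.na(df$tracer[i])) {
      problems <- c(problems, note(i, "amyloid_suvr given without tracer"))
      bad[i] <- TRUE
    } else if (!is.na(df$tracer[i]) && !df$tracer[i] %in% c("FBP", "FBB")) {
      problems <- c(problems, note(i, sprintf(
        "column tracer: unknown code '%s'", df$tracer[i]))); bad[i] <- TRUE
    }
  }
  dup <- duplicated(df$subject_id) & !is.na(df$subject_id)
  if (any(dup)) {
    problems <- c(problems, sprintf("duplicate subject_id '%s' at row %d",
                                    df$subject_id[dup], which(dup)))
    bad <- bad | dup
  }
  if (length(problems) && strict)
    stop("invalid manifest rows:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  if (any(bad)) {
    warning(length(problems), " manifest row(s) skipped", call. = FALSE)
    df <- df[!bad, , drop = FALSE]
    icv <- icv[!bad]; age <- age[!bad]; suvr <- suvr[!bad]
  }
  out <- data.frame(
    subject_id = df$subject_id,
    epvs_mask = df$epvs_mask,
    wml_mask = df$wml_mask,
    region_source = df$region_source,
    icv_mm3 = icv,
    age = age,
    sex = df$sex,
    diagnosis = df$diagnosis,
    amyloid_suvr = suvr,
    tracer = df$tracer,
    apoe = df$apoe,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "skipped") <- problems
  out
}

#' Write a cohort manifest
#'
#' Inverse of [read_manifest()]: a round trip reproduces all fields.
#'
#' @param records data.frame in the layout returned by [read_manifest()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(records, path) {
  out <- records[, c(manifest_required_cols, manifest_optional_cols)]
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a
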