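#' Read and write annotation masks
#'
#' Masks are stored as single-channel 8-bit PNG images whose pixel values are
#' mapped to grade codes through a palette. The default palette is the
#' identity on codes 0-4 (see [grade_codes()]); datasets that encode grades
#' with other pixel values (e.g. 255 for benign tissue) supply their own
#' palette, so the on-disk encoding never leaks past this reader.
#'
#' @param path Path to a PNG file.
#' @param palette Named integer vector: names are raw 8-bit pixel values (as
#'   decimal strings), values are grade codes. Defaults to [default_palette()].
#' @return `read_mask()`: an integer matrix of grade codes (rows x cols).
#' @examples
#' p <- tempfile(fileext = ".png")
#' m <- matrix(c(0L, 0L, 2L, 3L), 2, 2)
#' write_mask(m, p)
#' identical(read_mask(p), m)
#' @export
read_mask <- function(path, palette = default_palette()) {
  if (!file.exists(path)) abort(paste0("mask file not found: ", path))
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1L] # tolerate grey stored as RGB
  if (length(raw) == 0L) abort(paste0("size-zero mask image: ", path))
  vals <- as.integer(round(raw * 255))
  codes <- palette[as.character(vals)]
  if (anyNA(codes)) {
    bad <- sort(unique(vals[is.na(codes)]))
    abort(paste0(
      "mask pixel value(s) not in palette: ", paste(bad, collapse = ", "),
      " in ", path
    ))
  }
  matrix(unname(codes), nrow = nrow(raw), ncol = ncol(raw))
}

#' @rdname read_mask
#' @param mask Integer matrix of grade codes.
#' @return `write_mask()`: `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  if (any(mask < 0L | mask > 255L)) abort("mask codes must fit in 8 bits")
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname read_mask
#' @export
default_palette <- function() {
  gc <- grade_codes()
  setNames(gc, as.character(unname(gc)))
}

#' Read and write RGB patch images
#'
#' Patches are 8-bit RGB PNG images; values are returned in `[0, 1]`.
#' Greyscale files are expanded to three identical channels.
#'
#' @param path PNG file path.
#' @return `read_patch()`: an `H x W x 3` numeric array in `[0, 1]`.
#' @export
read_patch <- function(path) {
  if (!file.exists(path)) abort(paste0("patch file not found: ", path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3] # drop alpha
  img
}

#' @rdname read_patch
#' @param img `H x W x 3` numeric array in `[0, 1]`.
#' @export
write_patch <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Load and validate a patch manifest
#'
#' A manifest is the CSV table that binds a patch dataset together: one row
#' per patch with columns `patch_path`, `mask_path`, `patient_id`, `slide_id`
#' and `fold`. Folds are the five patient-exclusive partitions
#' `Val1`..`Val4` and `Test`; a patient appearing in two folds is an error
#' because patient-exclusive splitting is what keeps evaluation honest.
#'
#' @param path CSV file path. Relative `patch_path`/`mask_path` entries are
#'   resolved against the manifest's directory.
#' @param check_paths Verify that every referenced file exists (default TRUE).
#' @return A tibble with the manifest columns (paths resolved).
#' @export
load_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) abort(paste0("manifest not found: ", path))
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_manifest(m, dir = dirname(path), check_paths = check_paths)
}

#' @rdname load_manifest
#' @param manifest A manifest data frame to validate in place.
#' @param dir Directory against which relative paths are resolved.
#' @export
validate_manifest <- function(manifest, dir = ".", check_paths = TRUE) {
  required <- c("patch_path", "mask_path", "patient_id", "slide_id", "fold")
  missing <- setdiff(required, names(manifest))
  if (length(missing)) abort(paste0("manifest lacks column(s): ", paste(missing, collapse = ", ")))
  m <- tibble::as_tibble(manifest)
  if (anyDuplicated(m$patch_path)) {
    dup <- unique(m$patch_path[duplicated(m$patch_path)])
    abort(paste0("duplicate patch_path in manifest: ", paste(head(dup, 3), collapse = ", ")))
  }
  folds <- c("Val1", "Val2", "Val3", "Val4", "Test")
  bad_fold <- setdiff(unique(m$fold), folds)
  if (length(bad_fold)) abort(paste0("unknown fold(s): ", paste(bad_fold, collapse = ", ")))
  multi <- m %>%
    dplyr::distinct(.data$patient_id, .data$fold) %>%
    dplyr::count(.data$patient_id) %>%
    dplyr::filter(.data$n > 1L)
  if (nrow(multi)) {
    abort(paste0(
      "patient(s) present in more than one fold (folds must be patient-exclusive): ",
      paste(multi$patient_id, collapse = ", ")
    ))
  }
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(dir, p))
  m$patch_path <- resolve(m$patch_path)
  m$mask_path <- resolve(m$mask_path)
  if (check_paths) {
    gone <- c(m$patch_path[!file.exists(m$patch_path)], m$mask_path[!file.exists(m$mask_path)])
    if (length(gone)) abort(paste0("manifest references missing file(s): ", paste(head(gone, 3), collapse = ", ")))
  }
  m
}

#' @rdname load_manifest
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(manifest, path, progress = FALSE)
  invisible(path)
}
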