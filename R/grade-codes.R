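#' Grade codes for annotation masks
#'
#' Annotation masks are integer rasters over five mutually exclusive codes:
#' `BG` (0, non-tissue background), `NC` (1, benign tissue), and the Gleason
#' patterns `G3` (2), `G4` (3) and `G5` (4). `G5` is the most aggressive
#' pattern; `NC` marks tissue in which no Gleason pattern is present.
#'
#' @return A named integer vector mapping code names to code values.
#' @examples
#' grade_codes()
#' grade_name(2L)
#' @export
grade_codes <- function() {
  c(BG = 0L, NC = 1L, G3 = 2L, G4 = 3L, G5 = 4L)
}

#' @rdname grade_codes
#' @return `gleason_grades()`: the three Gleason grade names, lowest first.
#' @export
gleason_grades <- function() c("G3", "G4", "G5")

#' @rdname grade_codes
#' @param code Integer code(s) to translate.
#' @export
grade_name <- function(code) {
  gc <- grade_codes()
  out <- names(gc)[match(code, gc)]
  if (anyNA(out)) abort(paste0("unknown grade code: ", paste(code[is.na(out)], collapse = ", ")))
  out
}

#' @rdname grade_codes
#' @param name Grade name(s) such as `"G3"`.
#' @export
grade_code <- function(name) {
  gc <- grade_codes()
  out <- unname(gc[match(name, names(gc))])
  if (anyNA(out)) abort(paste0("unknown grade name: ", paste(name[is.na(out)], collapse = ", ")))
  out
}
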