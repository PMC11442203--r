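#' ATC code helpers
#'
#' WHO Anatomical Therapeutic Chemical (ATC) codes are hierarchical:
#' level 1 is one letter (anatomical main group), level 2 adds two digits
#' (therapeutic subgroup), level 3 one letter (pharmacological subgroup),
#' level 4 one letter (chemical subgroup) and level 5 two digits (substance).
#' A full code such as `"M01AB05"` therefore truncates to `"M01A"` at
#' level 3.
#'
#' @param codes Character vector of ATC codes (any level).
#' @param level Integer in 1..5, the classification level to keep.
#' @return `atc_truncate()`: character vector of codes cut to `level`
#'   (codes shorter than the requested level are kept as-is);
#'   `atc_valid()`: logical vector.
#' @examples
#' atc_truncate("M01AB05", level = 3)
#' atc_valid(c("M01AB05", "banana"))
#' @export
atc_truncate <- function(codes, level = 3) {
  stopifnot(length(level) == 1, level %in% 1:5)
  width <- c(1L, 3L, 4L, 5L, 7L)[level]
  substr(codes, 1L, width)
}

#' @rdname atc_truncate
#' @export
atc_valid <- function(codes) {
  stringr::str_detect(codes, "^[A-Z][0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?$")
}
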