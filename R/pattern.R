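#' Parse a binary spaced-seed pattern
#'
#' Builds a [SpacedPattern] from a string of `1` (match positions) and
#' `0` (don't-care positions).  The first character must be `1`; the
#' pattern length then equals the span of the seed window.
#'
#' @param text character string over `{"0","1"}`, e.g. `"1100101"`.
#' @return a [SpacedPattern].
#' @examples
#' p <- spacedPattern("1100101")
#' patternLength(p)   # 7
#' patternWeight(p)   # 4
#' matchOffsets(p)    # 0 1 4 6
#' @export
spacedPattern <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("pattern must be a single character string")
  new("SpacedPattern", mask = text)
}

#' The default spaced-seed pattern (length 72, weight 12)
#'
#' A fixed binary pattern with 12 match positions and 60 don't-care
#' positions spread over 72 columns, the geometry tuned for matching
#' 150 bp reads.  The layout was chosen once by minimising the seed's
#' overlap complexity (a Rasbhari-style objective) and is shipped as a
#' literal so results are reproducible; any other valid pattern can be
#' supplied wherever a [SpacedPattern] is accepted.
#'
#' @return a [SpacedPattern] with `patternLength()` 72 and
#'   `patternWeight()` 12; identical on every call.
#' @export
defaultPattern <- function() {
  spacedPattern(paste0("100100010000000000000001000001000000000001000001",
                       "000000011000000000101001"))
}

.mask_chars <- function(x) strsplit(x@mask, "", fixed = TRUE)[[1L]]

#' @rdname skimdist-accessors
#' @export
setMethod("patternLength", "SpacedPattern", function(x) nchar(x@mask))

#' @rdname skimdist-accessors
#' @export
setMethod("patternWeight", "SpacedPattern",
          function(x) sum(.mask_chars(x) == "1"))

#' @rdname skimdist-accessors
#' @export
setMethod("matchOffsets", "SpacedPattern",
          function(x) which(.mask_chars(x) == "1") - 1L)

#' @rdname skimdist-accessors
#' @export
setMethod("dontCareOffsets", "SpacedPattern",
          function(x) which(.mask_chars(x) == "0") - 1L)

#' @describeIn spacedPattern serialise back to the `0`/`1` string;
#'   `as.character(spacedPattern(t))` equals `t`.
#' @param x a [SpacedPattern].
#' @param ... ignored.
#' @export
setMethod("as.character", "SpacedPattern", function(x, ...) x@mask)

setMethod("show", "SpacedPattern", function(object) {
  cat("SpacedPattern: ", object@mask, "\n",
      "  length ", patternLength(object),
      ", weight ", patternWeight(object),
      ", don't-care ", patternLength(object) - patternWeight(object),
      "\n", sep = "")
})
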