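# Character-offset conventions used throughout the package:
# offsets are 0-based, half-open [start, end) over the document text (UTF-8),
# as in BioNLP-ST standoff annotation.

#' Extract the substring covered by a half-open character span
#'
#' @param text Document text (length-1 character).
#' @param start,end 0-based half-open character offsets.
#' @return The covered substring.
#' @keywords internal
span_text <- function(text, start, end) {
  substring(text, start + 1L, end)
}

#' @keywords internal
span_valid <- function(text, start, end) {
  is.finite(start) && is.finite(end) &&
    start >= 0L && start < end && end <= nchar(text)
}

# a strictly contains b (allowing shared boundaries but not identity)
span_contains <- function(a_start, a_end, b_start, b_end) {
  a_start <= b_start && b_end <= a_end && !(a_start == b_start && a_end == b_end)
}

span_overlaps <- function(a_start, a_end, b_start, b_end) {
  a_start < b_end && b_start < a_end
}

stop_parse <- function(path, line_no, msg) {
  stop(sprintf("%s:%d: %s", path, line_no, msg), call. = FALSE)
}
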