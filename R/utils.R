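#' @keywords internal
"_PACKAGE"

## HMMER amino-acid alphabet order (match-emission columns).
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## Classed error constructor so callers can condition on failure kind.
agm_stop <- function(message, class) {
  stop(structure(
    class = c(class, "agm_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x)
}

## Accept either a path to an existing file or a character vector of lines.
read_input_lines <- function(x) {
  if (is.character(x) && length(x) == 1L && !grepl("\n", x, fixed = TRUE) &&
      file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  if (is.character(x)) {
    return(unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE))
  }
  agm_stop("input must be a file path or a character vector of lines",
           "agm_invalid_argument")
}

## Format a number the way tab-separated outputs expect (no sci notation).
fmt_num <- function(x) format(x, scientific = FALSE, trim = TRUE, digits = 12)
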