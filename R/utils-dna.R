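# Low-level DNA string helpers used in hot loops. Biostrings handles file
# formats and alignment; these avoid XString overhead for per-read arithmetic.

#' Reverse-complement a DNA string
#'
#' @param x A character scalar over A/C/G/T/N.
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

# split into a character vector of single bases
.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

.check_dna <- function(x, allow_n = FALSE, what = "sequence") {
  alphabet <- if (allow_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  bad <- which(!.chars(x) %in% alphabet)
  if (length(bad) > 0L) {
    stop(sprintf("non-ACGT%s character in %s at position %d",
                 if (allow_n) "N" else "", what, bad[1L]), call. = FALSE)
  }
  invisible(x)
}

#' Longest common prefix of two DNA strings
#'
#' Length in bases of the longest shared prefix. `N` never matches, so reads
#' containing ambiguous base calls terminate the prefix there.
#'
#' @param a,b Character scalars over A/C/G/T (plus N when `allow_n`).
#' @param allow_n Tolerate `N` characters (they never match)?
#' @return Integer prefix length, `0 <= k <= min(nchar(a), nchar(b))`.
#' @export
longest_common_prefix <- function(a, b, allow_n = FALSE) {
  .check_dna(a, allow_n); .check_dna(b, allow_n)
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  ca <- .chars(a)[seq_len(n)]
  cb <- .chars(b)[seq_len(n)]
  neq <- ca != cb | ca == "N" | cb == "N"
  if (!any(neq)) n else which(neq)[1L] - 1L
}

#' Longest common suffix of two DNA strings
#'
#' @inheritParams longest_common_prefix
#' @return Integer suffix length.
#' @export
longest_common_suffix <- function(a, b, allow_n = FALSE) {
  .check_dna(a, allow_n); .check_dna(b, allow_n)
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  ca <- rev(.chars(a))[seq_len(n)]
  cb <- rev(.chars(b))[seq_len(n)]
  neq <- ca != cb | ca == "N" | cb == "N"
  if (!any(neq)) n else which(neq)[1L] - 1L
}

# substring with 0-based half-open coordinates: x[from, to)
.substr0 <- function(x, from, to) {
  if (to <= from) "" else substr(x, from + 1L, to)
}

# all match start positions (0-based) of pattern in subject, exact
.find_all <- function(pattern, subject) {
  if (nchar(pattern) == 0L || nchar(pattern) > nchar(subject)) return(integer(0))
  m <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}
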