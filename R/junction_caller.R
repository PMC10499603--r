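# Classification of CRISPR-cut amplicon repair products.
#
# Each Sanger-derived repair product is decomposed against the reference
# amplicon into a repair event (deletion, deletion with insertion, pure
# insertion, or unmodified contamination) using longest-common-prefix /
# longest-common-suffix arithmetic. Junction microhomology is the maximal
# exact homology between the two deletion-flanking sequences; because a
# microhomology of m bases makes m + 1 deletion placements equally
# consistent with the read, the ambiguity is reported as an interval and a
# canonical placement is fixed by convention.

#' Define a reference amplicon locus
#'
#' Describes the PCR amplicon around a CRISPR cut site: the amplicon
#' sequence, the between-base cut position, the primer pair, and the
#' restriction-enzyme recognition site whose survival marks unmodified
#' products. All coordinates are 0-based, half-open; `cut_position` is a
#' between-base index.
#'
#' @param name Locus label.
#' @param amplicon Amplicon sequence (A/C/G/T, case-folded to upper).
#' @param cut_position Integer between-base cut offset, `0 < cut < length`.
#' @param fwd_primer Forward primer; must be a prefix of the amplicon.
#' @param rev_primer Reverse primer as ordered for PCR, i.e. the reverse
#'   complement of the amplicon 3' end.
#' @param enzyme_recognition Recognition sequence checked for survival
#'   (default `"GGTGA"`, HphI).
#' @param recognition_site_span Half-open `c(start, end)` interval of the
#'   recognition site in amplicon coordinates.
#' @param recognition_strand `"+"` if the recognition sequence reads off the
#'   amplicon strand, `"-"` if off its reverse complement.
#' @return An object of class `reference_locus`.
#' @export
reference_locus <- function(name, amplicon, cut_position, fwd_primer,
                            rev_primer, enzyme_recognition = "GGTGA",
                            recognition_site_span,
                            recognition_strand = c("+", "-")) {
  recognition_strand <- match.arg(recognition_strand)
  amplicon <- toupper(amplicon)
  fwd_primer <- toupper(fwd_primer)
  rev_primer <- toupper(rev_primer)
  .check_dna(amplicon, what = "amplicon")
  .check_dna(fwd_primer, what = "fwd_primer")
  .check_dna(rev_primer, what = "rev_primer")
  R <- nchar(amplicon)
  cut_position <- as.integer(cut_position)
  if (!(cut_position > 0L && cut_position < R)) {
    stop("cut_position must satisfy 0 < cut_position < length(amplicon)")
  }
  if (!startsWith(amplicon, fwd_primer)) {
    stop("fwd_primer is not a prefix of the amplicon")
  }
  if (!endsWith(amplicon, revcomp(rev_primer))) {
    stop("reverse-complement of rev_primer is not a suffix of the amplicon")
  }
  span <- as.integer(recognition_site_span)
  if (length(span) != 2L || span[1] < 0L || span[2] > R || span[1] >= span[2]) {
    stop("recognition_site_span must be a half-open interval within the amplicon")
  }
  site_here <- .substr0(amplicon, span[1], span[2])
  expected <- if (recognition_strand == "+") enzyme_recognition
              else revcomp(enzyme_recognition)
  if (site_here != expected) {
    stop(sprintf(
      "amplicon[%d, %d) is %s, not the %s-strand recognition sequence %s",
      span[1], span[2], site_here, recognition_strand, expected))
  }
  structure(
    list(name = name, amplicon = amplicon, cut_position = cut_position,
         fwd_primer = fwd_primer, rev_primer = rev_primer,
         enzyme_recognition = enzyme_recognition,
         recognition_site_span = span,
         recognition_strand = recognition_strand),
    class = "reference_locus")
}

#' @export
print.reference_locus <- function(x, ...) {
  cat(sprintf("<reference_locus> %s: %d bp amplicon, cut at %d\n",
              x$name, nchar(x$amplicon), x$cut_position))
  cat(sprintf("  primers %s / %s\n", x$fwd_primer, x$rev_primer))
  cat(sprintf("  %s site at [%d, %d) on %s strand\n", x$enzyme_recognition,
              x$recognition_site_span[1], x$recognition_site_span[2],
              x$recognition_strand))
  invisible(x)
}

.junction_call <- function(event_class, p = NA_integer_, s = NA_integer_,
                           d = NA_integer_, i = NA_integer_,
                           insertion_seq = NA_character_, m = NA_integer_,
                           mh_seq = NA_character_,
                           junction_interval = c(NA_integer_, NA_integer_),
                           filter_verdict = "pass") {
  structure(
    list(event_class = event_class, p = p, s = s, d = d, i = i,
         insertion_seq = insertion_seq, m = m, mh_seq = mh_seq,
         junction_interval = junction_interval,
         filter_verdict = filter_verdict),
    class = "junction_call")
}

#' @export
print.junction_call <- function(x, ...) {
  cat(sprintf("<junction_call> %s", x$event_class))
  if (!is.na(x$d) && x$event_class != "unmodified") {
    cat(sprintf(": d=%d i=%d m=%d", x$d, x$i, x$m))
    if (!is.na(x$m) && x$m > 0) cat(sprintf(" (MH %s)", x$mh_seq))
  }
  cat(sprintf(" [%s]\n", x$filter_verdict))
  invisible(x)
}

# one mismatch-tolerant primer search via Biostrings; returns 0-based starts
.match_starts <- function(pattern, subject, max_mismatch) {
  if (max_mismatch == 0L) return(.find_all(pattern, subject))
  hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(subject),
                                   max.mismatch = max_mismatch)
  as.integer(Biostrings::start(hits)) - 1L
}

#' Orient a read and apply the exclusion filters
#'
#' Reads are excluded when a primer sequence is missing or when the
#' restriction recognition site survives at its homologous position (an
#' unrepaired or unmodified product). The read is searched on both strands
#' and oriented so the forward primer matches its start; the trimmed read
#' retains both primers so the amplicon coordinate frame is preserved.
#'
#' Site survival is assessed per sequence: the recognition site is retained
#' iff its span lies entirely within the read's unchanged prefix or
#' unchanged suffix relative to the amplicon.
#'
#' @param locus A [reference_locus()].
#' @param read Repair-product sequence, either orientation.
#' @param max_primer_mismatches Mismatch budget per primer (default 0,
#'   strict exclusion).
#' @return A list with `verdict` (one of `pass`, `missing_fwd_primer`,
#'   `missing_rev_primer`, `missing_both_primers`, `site_retained`), the
#'   oriented and primer-trimmed `read` (`NA` unless both primers found),
#'   and `strand` (`"+"`/`"-"`/`NA`).
#' @export
apply_filters <- function(locus, read, max_primer_mismatches = 0L) {
  stopifnot(inherits(locus, "reference_locus"))
  read <- toupper(read)
  .check_dna(read, allow_n = TRUE, what = "read")
  mm <- as.integer(max_primer_mismatches)
  rc_read <- revcomp(read)

  fwd_plus <- .match_starts(locus$fwd_primer, read, mm)
  fwd_minus <- .match_starts(locus$fwd_primer, rc_read, mm)
  if (length(fwd_plus) > 0L && length(fwd_minus) > 0L) {
    stop(sprintf("ambiguous orientation: fwd primer matches both strands of read %s...",
                 substr(read, 1, 20)))
  }

  if (length(fwd_plus) == 0L && length(fwd_minus) == 0L) {
    # no fwd primer on either strand; orient by rev primer to grade the verdict
    rp <- revcomp(locus$rev_primer)
    has_rev <- length(.match_starts(rp, read, mm)) > 0L ||
      length(.match_starts(rp, rc_read, mm)) > 0L
    verdict <- if (has_rev) "missing_fwd_primer" else "missing_both_primers"
    return(list(verdict = verdict, read = NA_character_, strand = NA_character_))
  }

  strand <- if (length(fwd_plus) > 0L) "+" else "-"
  oriented <- if (strand == "+") read else rc_read
  fstart <- if (strand == "+") fwd_plus[1L] else fwd_minus[1L]

  rp <- revcomp(locus$rev_primer)
  rhits <- .match_starts(rp, oriented, mm)
  rhits <- rhits[rhits > fstart]
  if (length(rhits) == 0L) {
    return(list(verdict = "missing_rev_primer", read = NA_character_,
                strand = strand))
  }
  rend <- rhits[length(rhits)] + nchar(rp)
  trimmed <- .substr0(oriented, fstart, rend)

  # recognition-site survival: span inside the unchanged prefix or suffix
  p <- longest_common_prefix(locus$amplicon, trimmed, allow_n = TRUE)
  s <- longest_common_suffix(locus$amplicon, trimmed, allow_n = TRUE)
  span <- locus$recognition_site_span
  R <- nchar(locus$amplicon)
  if (p >= span[2] || s >= R - span[1]) {
    return(list(verdict = "site_retained", read = trimmed, strand = strand))
  }
  list(verdict = "pass", read = trimmed, strand = strand)
}

#' Decompose one repair product into a junction call
#'
#' Computes the longest common prefix `p` and suffix `s` between the
#' amplicon (length `R`) and the oriented read (length `S`) and classifies:
#'
#' * `read == amplicon` — unmodified contamination;
#' * `S < R` and `p + s >= S` — pure deletion with `d = R - S` and
#'   microhomology `m = min(p + s - S, d)`; the canonical deleted segment is
#'   `amplicon[p, p + d)` and all placements in `junction_interval =
#'   [p - m, p + 1)` (width `m + 1`) reproduce the read;
#' * `p + s < S` and `p + s <= R` — deletion with insertion,
#'   `d = R - p - s`, `i = S - p - s`, `insertion_seq = read[p, S - s)`,
#'   with `m = 0` by convention; `d = 0` is a pure insertion;
#' * anything else (e.g. rearranged products) — unclassified.
#'
#' @param locus A [reference_locus()].
#' @param read Oriented repair-product sequence sharing the amplicon's
#'   primer-anchored coordinate frame (see [apply_filters()]).
#' @return A `junction_call`.
#' @export
call_junction <- function(locus, read) {
  stopifnot(inherits(locus, "reference_locus"))
  read <- toupper(read)
  amp <- locus$amplicon
  R <- nchar(amp)
  S <- nchar(read)

  if (S < nchar(locus$fwd_primer) + nchar(locus$rev_primer)) {
    warning(sprintf("read of %d bases is shorter than the combined primers; unclassified", S))
    return(.junction_call("unclassified"))
  }
  if (read == amp) {
    return(.junction_call("unmodified", p = R, s = R, d = 0L, i = 0L,
                          insertion_seq = "", m = 0L, mh_seq = "",
                          junction_interval = c(locus$cut_position,
                                                locus$cut_position + 1L)))
  }
  p <- longest_common_prefix(amp, read, allow_n = TRUE)
  s <- longest_common_suffix(amp, read, allow_n = TRUE)

  if (S < R && p + s >= S) {
    d <- R - S
    m <- min(p + s - S, d)
    return(.junction_call("deletion", p = p, s = s, d = d, i = 0L,
                          insertion_seq = "", m = as.integer(m),
                          mh_seq = .substr0(amp, p - m, p),
                          junction_interval = c(p - as.integer(m), p + 1L)))
  }
  if (p + s < S && p + s <= R) {
    d <- R - p - s
    i <- S - p - s
    cls <- if (d == 0L) "pure_insertion" else "deletion_with_insertion"
    return(.junction_call(cls, p = p, s = s, d = as.integer(d),
                          i = as.integer(i),
                          insertion_seq = .substr0(read, p, S - s),
                          m = 0L, mh_seq = "",
                          junction_interval = c(p, p + 1L)))
  }
  # remaining decompositions (e.g. S >= R with p + s > R: duplications or
  # rearranged products) have no single-junction representation
  if (p + s > R && p + s > S) {
    warning("p + s exceeds both amplicon and read length; rearranged product?")
  }
  .junction_call("unclassified", p = p, s = s)
}

# maximal left/right placement shifts for deletion [j, j+d) of amp;
# used to recanonicalise an alignment-derived gap to the call_junction
# convention: canonical p is the rightmost placement, s spans back to the
# leftmost, and m = min(left + right, d)
.placement_shifts <- function(amp, j, d) {
  ca <- .chars(amp)
  R <- length(ca)
  left <- 0L
  while (j - left - 1L >= 0L &&
         ca[j - left] == ca[j + d - left]) left <- left + 1L
  right <- 0L
  while (j + d + right + 1L <= R &&
         ca[j + right + 1L] == ca[j + d + right + 1L]) right <- right + 1L
  c(left = left, right = right)
}

#' Alignment-based fallback junction caller
#'
#' Sanger base-call errors break exact prefix/suffix arithmetic: a single
#' substitution turns a clean deletion into an apparent
#' deletion-with-insertion. This fallback globally aligns the read to the
#' amplicon, takes the largest contiguous gap in the read as the deletion,
#' and recomputes microhomology on the exact flanking sequences using the
#' [call_junction()] placement convention (ties between equal-score
#' alignments resolve to the leftmost gap, then the canonical rightmost
#' placement is restored from the flank homology).
#'
#' @param locus A [reference_locus()].
#' @param read Oriented read.
#' @param match,mismatch,gap_open,gap_extend Alignment scores (defaults
#'   +1/-4/-8/-1).
#' @return A `junction_call`; products with more than one gap of 3+ bases
#'   are returned unclassified (complex product).
#' @export
align_fallback <- function(locus, read, match = 1, mismatch = -4,
                           gap_open = -8, gap_extend = -1) {
  stopifnot(inherits(locus, "reference_locus"))
  read <- toupper(read)
  amp <- locus$amplicon
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(read),
    subject = Biostrings::DNAString(amp),
    type = "global", substitutionMatrix = mat,
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend))

  # gaps in the read (deleted amplicon segments), amplicon coordinates
  del <- Biostrings::deletion(aln)[[1]]
  ins <- Biostrings::insertion(aln)[[1]]
  dstart <- as.integer(Biostrings::start(del)) - 1L
  dwidth <- as.integer(Biostrings::width(del))
  iwidth <- as.integer(Biostrings::width(ins))

  big_gaps <- sum(dwidth >= 3L) + sum(iwidth >= 3L)
  if (big_gaps > 1L) return(.junction_call("unclassified"))
  if (length(iwidth) > 0L && length(dwidth) > 0L) {
    return(.junction_call("unclassified"))
  }
  if (length(dwidth) == 0L) {
    # no deletion gap: unmodified length (substitutions only) or an insertion
    if (length(iwidth) == 0L) {
      return(.junction_call("unmodified", p = nchar(amp), s = nchar(amp),
                            d = 0L, i = 0L, insertion_seq = "", m = 0L,
                            mh_seq = ""))
    }
    return(.junction_call("unclassified"))
  }

  k <- which.max(dwidth)
  # amplicon coordinate of the gap: deletion() is in pattern-aligned
  # coordinates; map via the subject alignment start of the gap
  j <- dstart[k]
  d <- dwidth[k]
  # deletion() reports positions in subject coordinates already offset by
  # preceding insertions in the pattern; with no insertions tolerated the
  # subject start is the amplicon position.
  sh <- .placement_shifts(amp, j, d)
  m <- min(sh[["left"]] + sh[["right"]], d)
  p <- j + sh[["right"]]
  s <- nchar(amp) - (j - sh[["left"]]) - d
  .junction_call("deletion", p = as.integer(p), s = as.integer(s),
                 d = as.integer(d), i = 0L, insertion_seq = "",
                 m = as.integer(m), mh_seq = .substr0(amp, p - m, p),
                 junction_interval = c(as.integer(p - m), as.integer(p + 1L)))
}

#' Junction call with alignment fallback for noisy reads
#'
#' Runs [call_junction()]; when the exact decomposition is unclassified,
#' [align_fallback()] is consulted. A `deletion_with_insertion` call is
#' also re-examined when its apparent insertion closely matches the
#' reference at the same position (Hamming distance at most half its
#' length) — the signature of isolated base-call errors inside a deletion
#' or unmodified product, not of a genuine junction insertion. The
#' fallback call is preferred when it resolves to a clean single-gap
#' deletion or an unmodified read.
#'
#' @inheritParams call_junction
#' @param ... Passed to [align_fallback()].
#' @return A `junction_call`.
#' @export
call_junction_robust <- function(locus, read, ...) {
  exact <- call_junction(locus, read)
  consult <- exact$event_class == "unclassified"
  if (exact$event_class == "deletion_with_insertion") {
    consult <- .insertion_is_noise_like(locus$amplicon, exact)
  }
  if (consult) {
    fb <- align_fallback(locus, read, ...)
    if (fb$event_class %in% c("deletion", "unmodified")) return(fb)
  }
  exact
}

# Would the apparent insertion be better explained as substitution noise
# inside a pure deletion? Base-call errors in the unchanged prefix shift p
# left, errors in the suffix shift s, so the apparent insertion matches the
# reference start-aligned at p, end-aligned at p + d, or split between the
# two; a genuine junction insertion matches neither. Minimum Hamming
# distance over all splits at most half the insertion length counts as
# noise-like.
.insertion_is_noise_like <- function(amp, call) {
  i <- call$i; d <- call$d; p <- call$p
  if (i < 2L || d < 1L) return(FALSE)
  ins <- .chars(call$insertion_seq)
  ca <- .chars(amp)
  k_range <- max(0L, i - d):min(i, d)
  if (length(k_range) == 0L || k_range[1] > k_range[length(k_range)]) {
    return(FALSE)
  }
  best <- i + 1L
  for (k in k_range) {
    mm <- 0L
    if (k > 0L) {
      ref <- ca[(p + 1L):(p + k)]
      mm <- mm + sum(ins[1:k] != ref)
    }
    if (k < i) {
      ref <- ca[(p + d - (i - k) + 1L):(p + d)]
      mm <- mm + sum(ins[(k + 1L):i] != ref)
    }
    best <- min(best, mm)
  }
  best <= i / 2
}

#' Deletion-size bin label
#'
#' Bins pure-deletion sizes into the three ranges used to summarise repair
#' spectra: below 10 bp, the 10-60 bp range characteristic of
#' microhomology-mediated end joining, and above 60 bp.
#'
#' @param d Integer vector of deletion sizes in bases (`d >= 1`).
#' @return Character vector over `"<10"`, `"10-60"`, `">60"`.
#' @export
classify_deletion_bin <- function(d) {
  if (any(d <= 0)) stop("deletion size must be >= 1")
  ifelse(d < 10, "<10", ifelse(d <= 60, "10-60", ">60"))
}

.filter_levels <- c("pass", "missing_fwd_primer", "missing_rev_primer",
                    "missing_both_primers", "site_retained")

#' Summarise junction calls for one sample
#'
#' Counts filter exclusions, tabulates the deletion-size histogram over the
#' `<10` / `10-60` / `>60` bins, and reports the fraction of pure deletions
#' using microhomology of at least `mh_min` bases.
#'
#' @param calls List of `junction_call` objects from one sample/locus.
#' @param mh_min Minimum microhomology length counted as "uses
#'   microhomology" (default 2; single-base overlaps are chance-level).
#' @return A list of class `sample_summary`: `n_reads_in`,
#'   `n_excluded_by_filter` (named counts), `n_events`,
#'   `deletion_size_histogram`, `fraction_mh`, `median_deletion`.
#' @export
summarize_sample <- function(calls, mh_min = 2L) {
  verdicts <- vapply(calls, function(x) x$filter_verdict, character(1))
  excl <- table(factor(verdicts, levels = .filter_levels))
  passing <- calls[verdicts == "pass"]
  classes <- vapply(passing, function(x) x$event_class, character(1))
  events <- passing[!classes %in% c("unmodified", "unclassified")]
  pure_del <- events[vapply(events, function(x) x$event_class == "deletion",
                            logical(1))]
  dsz <- vapply(pure_del, function(x) x$d, integer(1))
  hist <- table(factor(if (length(dsz)) classify_deletion_bin(dsz) else character(0),
                       levels = c("<10", "10-60", ">60")))
  mvals <- vapply(pure_del, function(x) x$m, integer(1))
  structure(
    list(n_reads_in = length(calls),
         n_excluded_by_filter = as.integer(excl[-1]) |>
           stats::setNames(.filter_levels[-1]),
         n_events = length(events),
         deletion_size_histogram = stats::setNames(as.integer(hist), names(hist)),
         fraction_mh = if (length(pure_del)) mean(mvals >= mh_min) else NA_real_,
         median_deletion = if (length(dsz)) stats::median(dsz) else NA_real_),
    class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("<sample_summary> %d reads in, %d events\n",
              x$n_reads_in, x$n_events))
  cat("  excluded:", paste(names(x$n_excluded_by_filter),
                           x$n_excluded_by_filter, collapse = ", "), "\n")
  cat("  deletion bins:", paste(names(x$deletion_size_histogram),
                                x$deletion_size_histogram, collapse = ", "), "\n")
  cat(sprintf("  fraction MH: %s, median deletion: %s\n",
              format(x$fraction_mh), format(x$median_deletion)))
  invisible(x)
}

#' Call junctions for a set of reads
#'
#' Full per-sample pipeline: orient and filter each read, decompose passing
#' reads (with alignment fallback for noisy ones), and return one row per
#' read.
#'
#' @param locus A [reference_locus()].
#' @param reads Named character vector of read sequences.
#' @param max_primer_mismatches Passed to [apply_filters()].
#' @param use_fallback Use [call_junction_robust()] (default) rather than
#'   the exact caller alone.
#' @return A `data.frame` with columns `read_id`, `filter_verdict`,
#'   `event_class`, `p`, `s`, `d`, `i`, `m`, `insertion_seq`, `mh_seq`,
#'   `junction_start`, `junction_end`, plus the list of `junction_call`
#'   objects as attribute `"calls"`.
#' @export
call_junctions <- function(locus, reads, max_primer_mismatches = 0L,
                           use_fallback = TRUE) {
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%04d", seq_along(reads))
  calls <- vector("list", length(reads))
  for (k in seq_along(reads)) {
    fl <- apply_filters(locus, reads[[k]], max_primer_mismatches)
    if (fl$verdict != "pass") {
      calls[[k]] <- .junction_call(
        if (fl$verdict == "site_retained") "unmodified" else "unclassified",
        filter_verdict = fl$verdict)
      next
    }
    cl <- if (use_fallback) call_junction_robust(locus, fl$read)
          else call_junction(locus, fl$read)
    cl$filter_verdict <- "pass"
    calls[[k]] <- cl
  }
  df <- data.frame(
    read_id = ids,
    filter_verdict = vapply(calls, function(x) x$filter_verdict, character(1)),
    event_class = vapply(calls, function(x) x$event_class, character(1)),
    p = vapply(calls, function(x) x$p, integer(1)),
    s = vapply(calls, function(x) x$s, integer(1)),
    d = vapply(calls, function(x) x$d, integer(1)),
    i = vapply(calls, function(x) x$i, integer(1)),
    m = vapply(calls, function(x) x$m, integer(1)),
    insertion_seq = vapply(calls, function(x) x$insertion_seq, character(1)),
    mh_seq = vapply(calls, function(x) x$mh_seq, character(1)),
    junction_start = vapply(calls, function(x) x$junction_interval[1], integer(1)),
    junction_end = vapply(calls, function(x) x$junction_interval[2], integer(1)),
    stringsAsFactors = FALSE)
  attr(df, "calls") <- calls
  df
}
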