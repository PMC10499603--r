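# Sequence-level model of the extrachromosomal end-joining substrate.
#
# The substrate mimics resected DNA ends: a double-stranded core (a GFP PCR
# product) carries, at each end, an oligonucleotide duplex whose long
# strand extends into a ~70-nt 3' single-stranded overhang. In cells, two
# such fragments anneal head-to-tail through a short microhomology carried
# near the 3' termini of the two overhangs; flap trimming and fill-in then
# create a covalent end-joining junction that a dedicated qPCR detects,
# normalised against a qPCR on the core.

#' Segment an oligonucleotide duplex into overhang regions
#'
#' The long strand of each duplex is laid out 5'-to-3' as: a short ligation
#' overhang (compatible with the restriction-cut core, default 4 nt), the
#' double-stranded region (paired with the reverse complement of the short
#' strand), and the 3' single-stranded overhang that mimics a resected end.
#'
#' @param oligo_short Short strand (fully paired).
#' @param oligo_long Long strand.
#' @param ligation_overhang_len Bases of 5' ligation overhang preceding the
#'   duplex region (default 4).
#' @return An `oligo_duplex` with `ds_len`, `ss_len`, `ss_seq`,
#'   `ligation_overhang`.
#' @export
anneal_duplex <- function(oligo_short, oligo_long, ligation_overhang_len = 4L) {
  oligo_short <- toupper(oligo_short)
  oligo_long <- toupper(oligo_long)
  .check_dna(oligo_short, what = "oligo_short")
  .check_dna(oligo_long, what = "oligo_long")
  lo <- as.integer(ligation_overhang_len)
  rc <- revcomp(oligo_short)
  hits <- .find_all(rc, oligo_long)
  if (length(hits) == 0L) {
    stop("reverse complement of the short oligo does not occur in the long oligo")
  }
  if (length(hits) > 1L) {
    stop("reverse complement of the short oligo occurs more than once in the long oligo")
  }
  if (hits != lo) {
    stop(sprintf(
      "duplex region found at offset %d, not adjacent to the %d-nt ligation overhang",
      hits, lo))
  }
  ds_len <- nchar(oligo_short)
  ss_len <- nchar(oligo_long) - lo - ds_len
  structure(
    list(oligo_short = oligo_short, oligo_long = oligo_long,
         ligation_overhang = .substr0(oligo_long, 0L, lo),
         ligation_overhang_len = lo, ds_len = ds_len, ss_len = ss_len,
         ss_seq = .substr0(oligo_long, lo + ds_len, nchar(oligo_long))),
    class = "oligo_duplex")
}

#' @export
print.oligo_duplex <- function(x, ...) {
  cat(sprintf("<oligo_duplex> %d nt ligation overhang, %d nt dsDNA, %d nt ssDNA\n",
              x$ligation_overhang_len, x$ds_len, x$ss_len))
  invisible(x)
}

#' Find the annealing microhomology between two 3' overhangs
#'
#' Searches the 3'-terminal `window` of each single-stranded overhang for
#' the longest k-mer (`k >= k_min`) in the left overhang whose reverse
#' complement occurs in the 3'-terminal window of the right overhang. Ties
#' at the maximal k are broken by the smallest combined unannealed 3'-flap
#' length, then by the leftmost position in the left overhang.
#'
#' @param ss_left,ss_right Single-stranded 3' overhang sequences, each
#'   written 5'-to-3'.
#' @param window Search region size from each 3' terminus (default 10).
#' @param k_min Minimal annealing length reported (default 3).
#' @return A list with `mh_len` (0 when no annealing is possible),
#'   `mh_seq` (as read on the left overhang), and `flap_left`/`flap_right`
#'   (unannealed 3'-terminal bases on each side).
#' @export
find_annealing_microhomology <- function(ss_left, ss_right, window = 10L,
                                         k_min = 3L) {
  ss_left <- toupper(ss_left); ss_right <- toupper(ss_right)
  .check_dna(ss_left, what = "ss_left"); .check_dna(ss_right, what = "ss_right")
  nl <- nchar(ss_left); nr <- nchar(ss_right)
  wl <- min(window, nl); wr <- min(window, nr)
  left_win <- .substr0(ss_left, nl - wl, nl)
  right_win <- .substr0(ss_right, nr - wr, nr)
  if (min(wl, wr) < k_min) {
    return(list(mh_len = 0L, mh_seq = "", flap_left = NA_integer_,
                flap_right = NA_integer_))
  }
  best <- NULL
  for (k in rev(seq(k_min, min(wl, wr)))) {
    for (i in 0:(wl - k)) {              # offset within left window
      kmer <- .substr0(left_win, i, i + k)
      for (j in .find_all(revcomp(kmer), right_win)) {
        flap_left <- wl - (i + k)
        flap_right <- wr - (j + k)
        cand <- list(mh_len = k, mh_seq = kmer,
                     flap_left = flap_left, flap_right = flap_right)
        if (is.null(best) ||
            (flap_left + flap_right < best$flap_left + best$flap_right) ||
            (flap_left + flap_right == best$flap_left + best$flap_right &&
             i < best$i)) {
          best <- c(cand, list(i = i))
        }
      }
    }
    if (!is.null(best)) break            # maximal k found
  }
  if (is.null(best)) {
    return(list(mh_len = 0L, mh_seq = "", flap_left = NA_integer_,
                flap_right = NA_integer_))
  }
  best$i <- NULL
  best
}

#' Assemble the end-joining substrate from its parts
#'
#' Builds the duplex 1 - core - duplex 2 fragment model and locates the
#' annealing microhomology between the two single-stranded overhangs.
#'
#' The fragment is represented by its "sense" strand, running
#' 5'-short-strand-of-duplex-2, through the core, into the full long
#' strand of duplex 1 whose 3' single-stranded overhang terminates the
#' strand; duplex 2's overhang is the 3' terminus of the complementary
#' strand.
#'
#' @param core_insert Core (GFP) top-strand sequence between the two
#'   ligation junctions.
#' @param left_duplex,right_duplex [anneal_duplex()] results; the left
#'   duplex's overhang carries the microhomology, the right duplex's its
#'   reverse complement.
#' @param window,k_min Passed to [find_annealing_microhomology()].
#' @return An `ej_substrate` with the annealing solution and the fragment
#'   sense strand.
#' @export
ej_substrate <- function(core_insert, left_duplex, right_duplex,
                         window = 10L, k_min = 3L) {
  stopifnot(inherits(left_duplex, "oligo_duplex"),
            inherits(right_duplex, "oligo_duplex"))
  core_insert <- toupper(core_insert)
  .check_dna(core_insert, what = "core_insert")
  mh <- find_annealing_microhomology(left_duplex$ss_seq, right_duplex$ss_seq,
                                     window = window, k_min = k_min)
  sense <- paste0(right_duplex$oligo_short, core_insert,
                  left_duplex$oligo_long)
  structure(
    list(core_insert = core_insert, left_duplex = left_duplex,
         right_duplex = right_duplex, mh_len = mh$mh_len,
         mh_seq = mh$mh_seq, flap_left = mh$flap_left,
         flap_right = mh$flap_right, fragment_sense = sense),
    class = "ej_substrate")
}

#' @export
print.ej_substrate <- function(x, ...) {
  cat(sprintf("<ej_substrate> core %d bp; overhangs %d/%d nt; annealing MH %s (%d nt), flaps %s/%s nt\n",
              nchar(x$core_insert), x$left_duplex$ss_len,
              x$right_duplex$ss_len,
              if (x$mh_len > 0) x$mh_seq else "none", x$mh_len,
              format(x$flap_left), format(x$flap_right)))
  invisible(x)
}

# does the primer pair amplify template? fwd on top strand strictly
# upstream of the reverse primer's binding site (revcomp on top strand)
.amplifiable <- function(template, fwd, rev) {
  f <- .find_all(toupper(fwd), template)
  r <- .find_all(revcomp(toupper(rev)), template)
  length(f) > 0L && length(r) > 0L && any(outer(f, r, `<`))
}

#' Predict the end-joining repair product and validate junction primers
#'
#' Two substrate fragments anneal head-to-tail through the overhang
#' microhomology; the unannealed 3' flaps are trimmed and gaps filled,
#' producing a double-stranded junction. The junction's top strand is the
#' left overhang (flap removed) merged, over the microhomology, with the
#' reverse complement of the right overhang (flap removed).
#'
#' @param substrate An [ej_substrate()].
#' @param fwd_primer,rev_primer Junction qPCR primer pair.
#' @return A list with `junction_seq` (junction top strand),
#'   `product_seq` (full two-fragment product top strand: sense strand of
#'   one fragment joined through the junction into the reverse complement
#'   of the next fragment's sense strand), and `primers_valid` (both
#'   primers match the junction region in amplifiable orientation).
#' @export
predict_ej_product <- function(substrate, fwd_primer, rev_primer) {
  stopifnot(inherits(substrate, "ej_substrate"))
  if (substrate$mh_len == 0L) {
    stop("no annealing solution: the overhangs share no microhomology")
  }
  left_ss <- substrate$left_duplex$ss_seq
  right_ss <- substrate$right_duplex$ss_seq
  left_trim <- .substr0(left_ss, 0L, nchar(left_ss) - substrate$flap_left)
  right_trim <- .substr0(right_ss, 0L, nchar(right_ss) - substrate$flap_right)
  # left_trim ends with the MH; revcomp(right_trim) begins with it
  junction_seq <- paste0(left_trim,
                         .substr0(revcomp(right_trim), substrate$mh_len,
                                  nchar(right_trim)))
  sense <- substrate$fragment_sense
  # head-to-tail join: fragment A's sense strand up to its overhang, the
  # filled junction, then fragment B's sense strand (the fill-in across
  # B's duplex-2 overhang and duplex region reads as B's sense sequence)
  upstream <- .substr0(sense, 0L, nchar(sense) - nchar(left_ss))
  product_seq <- paste0(upstream, junction_seq, sense)
  list(junction_seq = junction_seq, product_seq = product_seq,
       primers_valid = .amplifiable(product_seq, fwd_primer, rev_primer))
}

#' Relative end-joining efficiency by delta-delta-Ct
#'
#' Per sample, `dCt = ct_target - ct_norm`; `ddCt` subtracts the mean dCt
#' of the reference condition; efficiency is `amp_eff^(-ddCt)` (perfect
#' doubling, `amp_eff = 2`, by default). The reference condition averages
#' to efficiency 1 on the log scale.
#'
#' @param records `data.frame` with columns `sample`, `condition`,
#'   `ct_target` (end-joining junction qPCR) and `ct_norm` (core/GFP qPCR).
#' @param reference_condition Condition label used as the baseline.
#' @param amp_eff Per-cycle amplification factor (default 2).
#' @return The input with `dct`, `ddct` and `efficiency` columns; samples
#'   with missing Ct values are dropped with a warning.
#' @export
ddct_efficiency <- function(records, reference_condition, amp_eff = 2) {
  req <- c("sample", "condition", "ct_target", "ct_norm")
  if (!all(req %in% names(records))) {
    stop("records must have columns: ", paste(req, collapse = ", "))
  }
  ok <- stats::complete.cases(records[, c("ct_target", "ct_norm")]) &
    is.finite(records$ct_target) & is.finite(records$ct_norm)
  if (any(!ok)) {
    warning(sprintf("dropping %d sample(s) with missing Ct values", sum(!ok)))
    records <- records[ok, , drop = FALSE]
  }
  if (!reference_condition %in% records$condition) {
    stop(sprintf("reference condition '%s' not present", reference_condition))
  }
  records$dct <- records$ct_target - records$ct_norm
  ref_dct <- mean(records$dct[records$condition == reference_condition])
  records$ddct <- records$dct - ref_dct
  records$efficiency <- amp_eff^(-records$ddct)
  records
}

#' The published end-joining substrate oligonucleotides and qPCR primers
#'
#' Returns the printed sequences of the two substrate duplex oligo pairs
#' (duplex 1: 17 nt dsDNA / 69 nt ssDNA; duplex 2: 15 nt dsDNA / 71 nt
#' ssDNA; both long oligos carry a 4-nt ligation overhang), the core PCR
#' primers, and the junction (EJ) and core (GFP) qPCR primers.
#'
#' @return A named list of character scalars.
#' @export
ej_substrate_oligos <- function() {
  list(
    oligo_1a = "CATCGCTTAGCTGTATA",
    oligo_1b = paste0("TGACTATACAGCTAAGCGATGCTCTCACCGAGCGTATCTGCTGGG",
                      "TTGTGGATGAATTACATATGCTGGGAGAACCAAGATTGGGCAGTT"),
    oligo_2a = "CTCACACCCATCTCA",
    oligo_2b = paste0("AGTCTGAGATGGGTGTGAGAGTGAAGATCCTCACCTTCGGAGTAC",
                      "TCCTTCTTTTGACCATTGATACGATACTTCTCAGCCGAGCTGCTT"),
    fwd_core = "CAAGTGGTCTCAGACTGTGAGCAAGGGCGAGGAGCTG",
    rev_core = "GCCGAGGTCTCCGTCAGCTTGTACAGCTCGTCCATGCCGAG",
    fwd_qpcr_ej = "GGGTTGTGGATGAATTACATATGCTGG",
    rev_qpcr_ej = "CGGAGTACTCCTTCTTTTGACCATTGATAC",
    fwd_qpcr_core = "CTCACACCCATCTCAGACTGTGAGCAA",
    rev_qpcr_gfp = "CAGCTTGCCGTAGGTGGCATCG")
}

#' Build the published substrate with a synthetic core
#'
#' Assembles [ej_substrate()] from the printed duplex oligos around a
#' synthetic stand-in for the 747-bp GFP core: the core's ends are fixed by
#' the printed core PCR primers (after restriction trimming) and the
#' GFP-qPCR reverse-primer site is planted inside; the interior filler is
#' seeded random sequence, so core-internal analyses are illustrative while
#' all duplex, overhang and junction sequence is as printed.
#'
#' @param core_length Core length in bp (default 747, the printed PCR
#'   product size).
#' @param seed Seed for the synthetic filler.
#' @return An `ej_substrate`.
#' @export
build_published_substrate <- function(core_length = 747L, seed = 1L) {
  ol <- ej_substrate_oligos()
  d1 <- anneal_duplex(ol$oligo_1a, ol$oligo_1b)
  d2 <- anneal_duplex(ol$oligo_2a, ol$oligo_2b)
  # top strand of the cut core: begins after the BsaI cut of the fwd
  # primer, ends before the cut of the rev primer (both printed)
  head_seq <- sub("^CAAGTGGTCTCA", "", ol$fwd_core)
  tail_seq <- revcomp(sub("^GCCGAGGTCTCC", "", ol$rev_core))
  rev_site <- revcomp(ol$rev_qpcr_gfp)
  filler_n <- core_length - nchar(head_seq) - nchar(tail_seq) -
    nchar(rev_site)
  set.seed(seed)
  filler <- paste(sample(c("A", "C", "G", "T"), filler_n, replace = TRUE),
                  collapse = "")
  fill1 <- .substr0(filler, 0L, 150L)
  fill2 <- .substr0(filler, 150L, nchar(filler))
  core <- paste0(head_seq, fill1, rev_site, fill2, tail_seq)
  ej_substrate(core, left_duplex = d1, right_duplex = d2)
}
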