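# Independent brute-force oracles. These enumerate candidate solutions
# directly and never share code with the decomposition/search paths they
# check.

# All deletion placements j such that removing amp[j, j+d) reproduces the
# read; returns d, the homology m (= number of placements - 1, capped at
# d) and the canonical (rightmost) placement.
oracle_deletion_call <- function(amp, read) {
  R <- nchar(amp)
  S <- nchar(read)
  d <- R - S
  if (d <= 0) stop("oracle expects a strict deletion")
  placements <- integer(0)
  for (j in 0:S) {
    candidate <- paste0(substr(amp, 1, j), substr(amp, j + d + 1, R))
    if (candidate == read) placements <- c(placements, j)
  }
  if (length(placements) == 0) return(NULL)
  list(d = d, m = min(length(placements) - 1L, d),
       p = max(placements))
}

# Brute-force annealing search: all (i, j, k) triples with the k-mer at
# offset i of the left 3'-window equal to the reverse complement of the
# k-mer at offset j of the right 3'-window; maximal k, then minimal
# combined flap, then leftmost i.
oracle_annealing <- function(ss_left, ss_right, window = 10, k_min = 3) {
  rc <- function(x) paste(rev(strsplit(chartr("ACGT", "TGCA", x),
                                       "")[[1]]), collapse = "")
  nl <- nchar(ss_left); nr <- nchar(ss_right)
  wl <- min(window, nl); wr <- min(window, nr)
  lw <- substr(ss_left, nl - wl + 1, nl)
  rw <- substr(ss_right, nr - wr + 1, nr)
  best <- NULL
  for (k in k_min:min(wl, wr)) {
    for (i in 0:(wl - k)) {
      for (j in 0:(wr - k)) {
        if (substr(lw, i + 1, i + k) == rc(substr(rw, j + 1, j + k))) {
          cand <- list(mh_len = k, mh_seq = substr(lw, i + 1, i + k),
                       flap_left = wl - i - k, flap_right = wr - j - k,
                       i = i)
          if (is.null(best) || cand$mh_len > best$mh_len ||
              (cand$mh_len == best$mh_len &&
               (cand$flap_left + cand$flap_right <
                  best$flap_left + best$flap_right ||
                (cand$flap_left + cand$flap_right ==
                   best$flap_left + best$flap_right && cand$i < best$i)))) {
            best <- cand
          }
        }
      }
    }
  }
  best
}

# Minimal locus around an arbitrary amplicon, for exercising the junction
# decomposition without designed primers: 1-base primers, the recognition
# "site" is just the first base.
tiny_locus <- function(amp, cut = NULL) {
  if (is.null(cut)) cut <- nchar(amp) %/% 2
  reference_locus(
    name = "tiny", amplicon = amp, cut_position = cut,
    fwd_primer = substr(amp, 1, 1),
    rev_primer = revcomp(substr(amp, nchar(amp), nchar(amp))),
    enzyme_recognition = substr(amp, 1, 1),
    recognition_site_span = c(0L, 1L))
}

rand_amp <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")
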