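test_that("longest common prefix/suffix handle equality, divergence and empties", {
  expect_identical(longest_common_prefix("ACGT", "ACCT"), 2L)
  expect_identical(longest_common_prefix("ACGT", "ACGT"), 4L)
  expect_identical(longest_common_prefix("", "ACGT"), 0L)
  expect_identical(longest_common_suffix("TACGT", "GT"), 2L)
  expect_identical(longest_common_suffix("ACGT", "ACGT"), 4L)
  expect_error(longest_common_prefix("ACXT", "ACGT"), "non-ACGT")
  # N never matches, even to itself
  expect_identical(longest_common_prefix("ANGT", "ANGT", allow_n = TRUE), 1L)
})

test_that("call_junction decomposes the worked deletion example", {
  loc <- reference_locus("ex", "ACGGTTACGGCA", cut_position = 6,
                         fwd_primer = "AC", rev_primer = "TG",
                         enzyme_recognition = "GGTT",
                         recognition_site_span = c(2, 6))
  cl <- call_junction(loc, "ACGGCA")
  expect_identical(cl$event_class, "deletion")
  expect_identical(cl$d, 6L)
  expect_identical(cl$m, 4L)
  expect_identical(cl$p, 4L)
  expect_identical(cl$mh_seq, "ACGG")
  expect_identical(cl$junction_interval, c(0L, 5L))  # width m + 1
  orc <- oracle_deletion_call(loc$amplicon, "ACGGCA")
  expect_identical(cl$d, orc$d)
  expect_identical(cl$m, orc$m)
})

test_that("call_junction identifies unmodified reads and junction insertions", {
  loc <- reference_locus("ex2", "AAAACCCCGGGG", cut_position = 6,
                         fwd_primer = "AA", rev_primer = "CC",
                         enzyme_recognition = "CCCC",
                         recognition_site_span = c(4, 8))
  same <- call_junction(loc, loc$amplicon)
  expect_identical(same$event_class, "unmodified")
  expect_identical(same$d, 0L)
  expect_identical(same$m, 0L)

  ins <- call_junction(loc, "AAAATTGGGG")
  expect_identical(ins$event_class, "deletion_with_insertion")
  expect_identical(ins$d, 4L)
  expect_identical(ins$i, 2L)
  expect_identical(ins$insertion_seq, "TT")
  expect_identical(ins$m, 0L)
})

test_that("exhaustive single-segment deletions agree with the brute-force oracle", {
  set.seed(101)
  n_amp <- 25
  n_cases <- 0L
  n_agree <- 0L
  for (a in seq_len(n_amp)) {
    amp <- rand_amp(sample(10:40, 1))
    loc <- tiny_locus(amp)
    R <- nchar(amp)
    for (d in 1:(R - 4)) {
      for (j in 0:(R - d)) {
        read <- paste0(substr(amp, 1, j), substr(amp, j + d + 1, R))
        cl <- call_junction(loc, read)
        orc <- oracle_deletion_call(amp, read)
        n_cases <- n_cases + 1L
        n_agree <- n_agree + (cl$event_class == "deletion" &&
                                identical(cl$d, orc$d) &&
                                identical(cl$m, orc$m) &&
                                identical(cl$p, orc$p))
      }
    }
  }
  expect_gt(n_cases, 5000)
  expect_identical(n_agree, n_cases)
})

test_that("pure-deletion calls reconstruct the read from the canonical placement", {
  set.seed(202)
  for (rep in 1:40) {
    amp <- rand_amp(sample(20:60, 1))
    loc <- tiny_locus(amp)
    R <- nchar(amp)
    d <- sample(1:(R %/% 2), 1)
    j <- sample(0:(R - d), 1)
    read <- paste0(substr(amp, 1, j), substr(amp, j + d + 1, R))
    cl <- call_junction(loc, read)
    rebuilt <- paste0(substr(amp, 1, cl$p),
                      substr(amp, cl$p + cl$d + 1, R))
    expect_identical(rebuilt, read)
    expect_identical(cl$junction_interval[2] - cl$junction_interval[1],
                     cl$m + 1L)
  }
})

test_that("apply_filters grades primers, orientation and site survival", {
  loc <- gen_reference_locus(300, 0.5, seed = 5)
  amp <- loc$amplicon
  R <- nchar(amp)

  # intact amplicon retains the recognition site
  expect_identical(apply_filters(loc, amp)$verdict, "site_retained")
  # read arriving on the opposite strand is oriented back
  rc <- apply_filters(loc, revcomp(amp))
  expect_identical(rc$verdict, "site_retained")
  expect_identical(rc$strand, "-")
  # reverse primer gone
  expect_identical(apply_filters(loc, substr(amp, 1, R - 30))$verdict,
                   "missing_rev_primer")
  # forward primer gone
  expect_identical(apply_filters(loc, substr(amp, 31, R))$verdict,
                   "missing_fwd_primer")
  expect_identical(apply_filters(loc, substr(amp, 31, R - 30))$verdict,
                   "missing_both_primers")
  # a 20-base deletion destroying the site passes
  cut <- loc$cut_position
  del_read <- paste0(substr(amp, 1, cut - 10),
                     substr(amp, cut + 11, R))
  expect_identical(apply_filters(loc, del_read)$verdict, "pass")
  # restoring the recognition sequence flips the verdict back
  expect_identical(apply_filters(loc, amp)$verdict, "site_retained")
  # ambiguous orientation errors
  both <- paste0(loc$fwd_primer, "ACGTACGT", revcomp(loc$fwd_primer))
  expect_error(apply_filters(loc, both), "ambiguous orientation")
})

test_that("calls are invariant to read orientation", {
  loc <- gen_reference_locus(300, 0.5, seed = 8)
  amp <- loc$amplicon
  cut <- loc$cut_position
  read <- paste0(substr(amp, 1, cut - 12), substr(amp, cut + 13, nchar(amp)))
  fw <- apply_filters(loc, read)
  rv <- apply_filters(loc, revcomp(read))
  expect_identical(fw$verdict, "pass")
  expect_identical(rv$verdict, "pass")
  cf <- call_junction(loc, fw$read)
  cr <- call_junction(loc, rv$read)
  expect_identical(cf$d, cr$d)
  expect_identical(cf$i, cr$i)
  expect_identical(cf$m, cr$m)
})

test_that("align_fallback recovers deletions through substitutions and flags complex products", {
  loc <- gen_reference_locus(300, 0.5, seed = 13)
  amp <- loc$amplicon
  R <- nchar(amp)
  cut <- loc$cut_position
  clean <- paste0(substr(amp, 1, cut - 15), substr(amp, cut + 16, R))
  ref_call <- call_junction(loc, clean)

  # error-free deletion: identical call
  fb <- align_fallback(loc, clean)
  expect_identical(fb[c("event_class", "p", "s", "d", "i", "m", "mh_seq")],
                   ref_call[c("event_class", "p", "s", "d", "i", "m", "mh_seq")])

  # one substitution in the prefix: same d and m
  noisy <- clean
  pos <- 40L
  old <- substr(noisy, pos, pos)
  substr(noisy, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1]
  nf <- align_fallback(loc, noisy)
  expect_identical(nf$d, ref_call$d)
  expect_identical(nf$m, ref_call$m)
  rb <- call_junction_robust(loc, noisy)
  expect_identical(rb$d, ref_call$d)
  expect_identical(rb$m, ref_call$m)

  # two separated gaps of 3+ bases: complex product
  two_gap <- paste0(substr(amp, 1, 60), substr(amp, 66, cut),
                    substr(amp, cut + 21, R))
  expect_identical(align_fallback(loc, two_gap)$event_class, "unclassified")
})

test_that("deletion bins follow the <10 / 10-60 / >60 boundaries", {
  expect_identical(classify_deletion_bin(c(1, 9, 10, 35, 60, 61, 200)),
                   c("<10", "<10", "10-60", "10-60", "10-60", ">60", ">60"))
  expect_error(classify_deletion_bin(0), ">= 1")
})

test_that("summarize_sample tabulates exclusions, bins and microhomology use", {
  mk <- function(class, d = 0L, m = 0L, verdict = "pass") {
    cl <- mitorepair:::.junction_call(class, d = as.integer(d),
                                      m = as.integer(m), i = 0L)
    cl$filter_verdict <- verdict
    cl
  }
  calls <- c(
    lapply(c(5, 12, 25, 40, 61), function(d) mk("deletion", d, m = 3L)),
    lapply(c(8, 15, 33, 55, 70), function(d) mk("deletion", d, m = 0L)),
    list(mk("unmodified", verdict = "site_retained"),
         mk("unclassified", verdict = "missing_fwd_primer")))
  sm <- summarize_sample(calls, mh_min = 2)
  expect_identical(sm$n_reads_in, 12L)
  expect_identical(sm$n_events, 10L)
  expect_identical(unname(sm$deletion_size_histogram), c(2L, 6L, 2L))
  expect_equal(sm$fraction_mh, 0.5)
  expect_identical(unname(sm$n_excluded_by_filter["site_retained"]), 1L)

  empty <- summarize_sample(list())
  expect_identical(empty$n_events, 0L)
  expect_identical(empty$n_reads_in, 0L)
  all_kept <- summarize_sample(lapply(1:3, function(i)
    mk("unmodified", verdict = "site_retained")))
  expect_identical(all_kept$n_events, 0L)
})
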