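test_that("the published duplex oligos segment into the printed ds/ss lengths", {
  ol <- ej_substrate_oligos()
  d1 <- anneal_duplex(ol$oligo_1a, ol$oligo_1b)
  expect_identical(d1$ds_len, 17L)
  expect_identical(d1$ss_len, 69L)
  expect_identical(d1$ligation_overhang_len, 4L)
  d2 <- anneal_duplex(ol$oligo_2a, ol$oligo_2b)
  expect_identical(d2$ds_len, 15L)
  expect_identical(d2$ss_len, 71L)
  # segmentation conservation
  expect_identical(d1$ligation_overhang_len + d1$ds_len + d1$ss_len,
                   nchar(d1$oligo_long))
  expect_identical(d2$ligation_overhang_len + d2$ds_len + d2$ss_len,
                   nchar(d2$oligo_long))
})

test_that("anneal_duplex validates placement and uniqueness", {
  x <- "GATCCGTA"
  long <- paste0("AAAA", x)
  dup <- anneal_duplex(revcomp(x), long, 4)
  expect_identical(dup$ds_len, 8L)
  expect_identical(dup$ss_len, 0L)
  expect_error(anneal_duplex("ACGT", "GGGGGGGG"), "does not occur")
  expect_error(anneal_duplex(revcomp(x), paste0("AA", x, "TT")),
               "not adjacent")
  expect_error(anneal_duplex("AT", paste0("AAAA", "AT", "ATCC")),
               "more than once")
})

test_that("annealing search finds the printed 4-nt microhomology with 2-nt flaps", {
  ol <- ej_substrate_oligos()
  d1 <- anneal_duplex(ol$oligo_1a, ol$oligo_1b)
  d2 <- anneal_duplex(ol$oligo_2a, ol$oligo_2b)
  mh <- find_annealing_microhomology(d1$ss_seq, d2$ss_seq)
  expect_identical(mh$mh_len, 4L)
  expect_identical(mh$mh_seq, "GCAG")
  expect_identical(mh$flap_left, 2L)
  expect_identical(mh$flap_right, 2L)
})

test_that("annealing search agrees with exhaustive enumeration", {
  set.seed(77)
  for (rep in 1:30) {
    left <- rand_amp(40)
    right <- rand_amp(40)
    # plant a 6-mer / reverse-complement pair at flap distance 0
    mer <- rand_amp(6)
    left <- paste0(substr(left, 1, 34), mer)
    right <- paste0(substr(right, 1, 34), revcomp(mer))
    got <- find_annealing_microhomology(left, right)
    orc <- oracle_annealing(left, right)
    expect_gte(got$mh_len, 6L)
    expect_identical(got$mh_len, orc$mh_len)
    expect_identical(got$mh_seq, orc$mh_seq)
    expect_equal(got$flap_left, orc$flap_left)
    expect_equal(got$flap_right, orc$flap_right)
  }
  # poly-A overhangs can never anneal to each other
  pa <- strrep("A", 30)
  expect_identical(find_annealing_microhomology(pa, pa)$mh_len, 0L)
})

test_that("the predicted end-joining product is amplifiable by the junction primers only", {
  ol <- ej_substrate_oligos()
  sub <- build_published_substrate()
  pr <- predict_ej_product(sub, ol$fwd_qpcr_ej, ol$rev_qpcr_ej)
  expect_true(pr$primers_valid)
  # junction sequence carries the microhomology exactly once at the seam
  expect_identical(sub$mh_seq, "GCAG")
  # control (GFP) primers amplify within a single fragment
  ctrl <- predict_ej_product(sub, ol$fwd_qpcr_core, ol$rev_qpcr_gfp)
  expect_true(ctrl$primers_valid)
  expect_true(mitorepair:::.amplifiable(sub$fragment_sense,
                                        ol$fwd_qpcr_core, ol$rev_qpcr_gfp))
  # junction primers cannot amplify a single fragment
  expect_false(mitorepair:::.amplifiable(sub$fragment_sense,
                                         ol$fwd_qpcr_ej, ol$rev_qpcr_ej))
  # no annealing -> error
  d1 <- sub$left_duplex
  polyt <- anneal_duplex("GATCCGTA",
                         paste0("AAAA", revcomp("GATCCGTA"), strrep("T", 30)))
  broken <- ej_substrate(sub$core_insert, d1, polyt)
  expect_error(predict_ej_product(broken, ol$fwd_qpcr_ej, ol$rev_qpcr_ej),
               "no annealing")
})

test_that("ddct_efficiency satisfies its identities and invariances", {
  rec <- data.frame(
    sample = c("r1", "r2", "s1", "s2"),
    condition = c("ref", "ref", "mut", "mut"),
    ct_target = c(28, 28, 29, 29),
    ct_norm = c(20, 20, 20, 20))
  eff <- ddct_efficiency(rec, "ref")
  expect_equal(mean(eff$efficiency[eff$condition == "ref"]), 1)
  # one extra cycle halves the efficiency
  expect_equal(eff$efficiency[eff$condition == "mut"], c(0.5, 0.5))
  # invariance to a common Ct shift
  rec2 <- rec
  rec2$ct_target <- rec2$ct_target + 3.7
  rec2$ct_norm <- rec2$ct_norm + 3.7
  eff2 <- ddct_efficiency(rec2, "ref")
  expect_equal(eff2$efficiency, eff$efficiency)
  # missing Ct dropped with warning
  rec3 <- rec
  rec3$ct_target[3] <- NA
  expect_warning(e3 <- ddct_efficiency(rec3, "ref"), "dropping 1")
  expect_identical(nrow(e3), 3L)
  expect_error(ddct_efficiency(rec, "nope"), "not present")
})

test_that("programmed qPCR deficits are recovered by ddCt", {
  q <- simulate_qpcr(c(ctrl = 1, deficit = 0.25), sd = 0.1, n = 6,
                     seed = 11)
  eff <- ddct_efficiency(q, "ctrl")
  est <- mean(eff$efficiency[eff$condition == "deficit"])
  expect_lt(abs(est - 0.25), 0.05)
})
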