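test_that("median polish satisfies the residual-median property and reconstructs the matrix", {
  m <- matrix(c(1, 3, 2, 4), 2, 2)       # [[1,2],[3,4]]
  mp <- median_polish(m, max_iter = 50)
  expect_lt(max(abs(apply(mp$residuals, 1, stats::median))), 1e-9)
  expect_lt(max(abs(apply(mp$residuals, 2, stats::median))), 1e-9)
  rebuilt <- mp$overall + outer(mp$row_effects, mp$col_effects, `+`) +
    mp$residuals
  expect_equal(rebuilt, m)

  const <- matrix(5, 4, 6)
  mpc <- median_polish(const)
  expect_equal(mpc$residuals, matrix(0, 4, 6))
  expect_equal(mpc$corrected, matrix(5, 4, 6))
})

test_that("median polish removes a planted additive row gradient", {
  set.seed(30)
  base <- matrix(rnorm(16 * 24, 20, 1), 16, 24)
  gradient <- matrix(rep(seq(-6, 6, length.out = 16), 24), 16, 24)
  mp <- median_polish(base + gradient, max_iter = 100)
  raw_rowvar <- stats::var(rowMeans(base + gradient))
  cor_rowvar <- stats::var(rowMeans(mp$corrected))
  expect_lt(cor_rowvar, raw_rowvar / 10)
  # idempotent on its own output: a second polish finds effects that are
  # negligible against the unit noise scale (convergence is on the change
  # in total absolute residual, so effects are zero only to that order)
  mp2 <- median_polish(mp$corrected, max_iter = 100)
  expect_lt(max(abs(mp2$row_effects)), 1e-2)
  expect_lt(max(abs(mp2$col_effects)), 1e-2)
})

test_that("median polish tolerates missing wells and warns on empty rows", {
  m <- matrix(rnorm(24, 10, 2), 4, 6)
  m[2, 3] <- NA
  mp <- median_polish(m, max_iter = 50)
  expect_true(is.na(mp$corrected[2, 3]))
  expect_false(anyNA(mp$corrected[-2, ]))

  m2 <- m
  m2[3, ] <- NA
  expect_warning(mp2 <- median_polish(m2, max_iter = 50), "fully missing")
  expect_identical(mp2$row_effects[3], 0)
})

test_that("rz_score centres, scales and flips as a robust Z-score must", {
  ref <- c(0, 1, 2, 3, 4, 1, 3, 2)      # median 2, raw MAD 1
  expect_equal(rz_score(2, ref), 0)
  expect_equal(rz_score(2 + 1.4826, ref), 1)
  # antisymmetry around the reference median
  x <- 3.7
  expect_equal(rz_score(2 * 2 - x, ref), -rz_score(x, ref))
  # an alternative scaling constant is usable as configuration
  expect_equal(rz_score(2 + 1.14826, ref, mad_constant = 1.14826), 1)
  # reference population of the reference itself has median 0
  expect_equal(stats::median(rz_score(ref, ref)), 0)
  expect_error(rz_score(1, rep(5, 10)), "MAD")
  expect_error(rz_score(1, c(1, 2, 3)), "at least 8")
})

test_that("call_hits implements the two-siRNA / two-replicate same-direction rule", {
  rz <- function(gene, sirna, reps, scores) {
    data.frame(gene = gene, sirna = sirna, replicate = reps, rz = scores)
  }
  tab <- rbind(
    rz("GA", "GA_s1", 1:3, c(-3, -3, -0.5)),
    rz("GA", "GA_s2", 1:3, c(-4, -2.5, -3)),
    rz("GA", "GA_s3", 1:3, c(0, 1, -1)),
    rz("GB", "GB_s1", 1:3, c(3, 3, 3)),
    rz("GB", "GB_s2", 1:3, c(-3, -3, -3)),   # opposite directions
    rz("GC", "GC_s1", 1:3, c(5, 5, 5)))      # single siRNA
  res <- call_hits(tab)
  ga <- res$genes[res$genes$gene == "GA", ]
  expect_true(ga$hit)
  expect_identical(ga$direction, "negative")
  gb <- res$genes[res$genes$gene == "GB", ]
  expect_false(gb$hit)
  gc <- res$genes[res$genes$gene == "GC", ]
  expect_false(gc$hit)
  expect_true(gc$underpowered)
  # median RZ per siRNA is the median of its replicate scores
  expect_equal(res$sirnas$median_rz[res$sirnas$sirna == "GA_s2"], -3)

  # monotonicity: strengthening a supporting siRNA never un-calls a hit
  tab2 <- tab
  tab2$rz[tab2$sirna == "GA_s2"] <- c(-8, -8, -8)
  expect_true(call_hits(tab2)$genes$hit[res$genes$gene == "GA"])
})

test_that("multi-foci fraction matches direct arithmetic and the Poisson tail", {
  expect_equal(multi_foci_fraction(c(0, 0, 5, 7)), 50)
  expect_equal(multi_foci_fraction(c(0, 1, 4, 4)), 0)
  expect_error(multi_foci_fraction(integer(0)), "no cells")
  set.seed(99)
  counts <- rpois(1e4, 2)
  got <- multi_foci_fraction(counts)
  expected <- 100 * ppois(4, 2, lower.tail = FALSE)
  # binomial error: 3 sd of a proportion estimated from 1e4 cells
  tol <- 300 * sqrt(expected / 100 * (1 - expected / 100) / 1e4)
  expect_lt(abs(got - expected), tol)
})

test_that("planted screen hits are recovered and require positional correction", {
  wells <- simulate_plate(genes = 200, hit_fraction = 0.05, seed = 17)
  truth <- attr(wells, "truth")
  planted <- truth$gene[truth$is_hit]
  # the last plate is only partially filled, so its empty columns warn
  res <- suppressWarnings(score_screen(wells))
  hits <- res$genes$gene[res$genes$hit]
  expect_gte(mean(planted %in% hits), 0.9)
  # skipping the polish costs sensitivity
  res0 <- score_screen(wells, correct_positional = FALSE)
  hits0 <- res0$genes$gene[res0$genes$hit]
  expect_lt(mean(planted %in% hits0), mean(planted %in% hits))
})
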