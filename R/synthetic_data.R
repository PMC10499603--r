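# Seeded synthetic-data generators.
#
# Every assay in the package has a generator that emulates the statistical
# structure the analysis assumes: repair-product reads with known
# (deletion, insertion, microhomology) truth, screen plates with additive
# positional effects and planted hit genes, qPCR Ct tables with programmed
# efficiencies, and noisy one-site binding isotherms. Each generator is a
# pure function of its arguments and seed.

.BASES <- c("A", "C", "G", "T")

.rand_dna <- function(n) paste(sample(.BASES, n, replace = TRUE),
                               collapse = "")

#' Event-class mixture profile for simulated repair products
#'
#' Mixture weights over event classes and the distributions used to draw
#' deletion sizes and microhomology lengths. The `wt` profile is dominated
#' by 10-60 bp microhomology-flanked deletions; `polq_ko` lacks that class
#' entirely and shifts weight to small and large deletions.
#'
#' @param name `"wt"` or `"polq_ko"`.
#' @param sub_rate Per-base substitution error rate (default 0.002,
#'   typical Sanger tail noise), applied outside the 10 bases flanking the
#'   junction and outside the primer landing sites.
#' @param trunc_frac Fraction of reads truncated into a primer
#'   (default 0.05).
#' @return A `repair_profile`.
#' @export
repair_profile <- function(name = c("wt", "polq_ko"), sub_rate = 0.002,
                           trunc_frac = 0.05) {
  name <- match.arg(name)
  weights <- switch(name,
    wt = c(unmodified = 0.10, small_del = 0.15, mmej_del = 0.55,
           large_del = 0.10, junction_insertion = 0.10),
    polq_ko = c(unmodified = 0.15, small_del = 0.55, mmej_del = 0.00,
                large_del = 0.20, junction_insertion = 0.10))
  stopifnot(abs(sum(weights) - 1) < 1e-12)
  structure(
    list(name = name, weights = weights,
         mh_dist = c("2" = 0.2, "3" = 0.3, "4" = 0.3, "5" = 0.15,
                     "6" = 0.05),
         small_del_range = c(1L, 9L), mmej_del_range = c(10L, 60L),
         large_del_range = c(61L, 120L),
         sub_rate = sub_rate, trunc_frac = trunc_frac),
    class = "repair_profile")
}

#' Generate a random reference locus
#'
#' A random amplicon with unique 20-base primer landing sites at both
#' ends, the enzyme recognition sequence planted once straddling the cut
#' position, and (to give microhomology-mediated deletions something to
#' use) a set of direct-repeat pairs planted flanking the cut: each pair
#' is a random 2-6-mer written at two positions 10-60 bp apart so that
#' deleting between the copies removes the cut site and leaves that
#' repeat as junction microhomology.
#'
#' @param length Amplicon length in bases (>= 200).
#' @param cut_fraction Cut position as a fraction of the length.
#' @param seed Integer seed.
#' @param n_repeat_pairs Direct-repeat pairs to plant (default 10).
#' @param enzyme_recognition Recognition sequence (default GGTGA, HphI).
#' @param max_tries Locus-level constraint-satisfaction retries.
#' @return A [reference_locus()] with attribute `"repeat_pairs"`: a
#'   `data.frame` of planted pairs (`start1`, `start2`, `mh_len`; the
#'   MMEJ deletion for a pair is `[start1 + mh_len, start2 + mh_len)`).
#' @export
gen_reference_locus <- function(length = 400L, cut_fraction = 0.5,
                                seed = 1L, n_repeat_pairs = 10L,
                                enzyme_recognition = "GGTGA",
                                max_tries = 50L) {
  length <- as.integer(length)
  if (length < 200L) stop("amplicon length must be >= 200")
  set.seed(seed)
  prof <- repair_profile("wt")
  cut <- as.integer(round(length * cut_fraction))
  site_len <- nchar(enzyme_recognition)
  span <- c(cut - 2L, cut - 2L + site_len)

  for (try in seq_len(max_tries)) {
    amp <- .chars(.rand_dna(length))
    amp[(span[1] + 1L):span[2]] <- .chars(enzyme_recognition)
    pairs <- data.frame(start1 = integer(0), start2 = integer(0),
                        mh_len = integer(0))
    occupied <- span[1]:(span[2] - 1L)   # planted intervals, 0-based
    for (k in seq_len(n_repeat_pairs)) {
      for (attempt in 1:10) {
        m <- as.integer(sample(names(prof$mh_dist), 1L,
                               prob = prof$mh_dist))
        d <- sample(prof$mmej_del_range[1]:prof$mmej_del_range[2], 1L)
        l_max <- min(45L, d - m - 3L)
        if (l_max < 3L) next
        l <- sample(3L:l_max, 1L)
        a1 <- cut - l - m               # left copy [a1, a1 + m)
        a2 <- a1 + d                    # right copy [a2, a2 + m)
        if (a1 < 25L || a2 + m > length - 25L) next
        copy_pos <- c(a1:(a1 + m - 1L), a2:(a2 + m - 1L))
        if (any(copy_pos %in% occupied)) next
        mer <- sample(.BASES, m, replace = TRUE)
        amp[(a1 + 1L):(a1 + m)] <- mer
        amp[(a2 + 1L):(a2 + m)] <- mer
        occupied <- c(occupied, copy_pos)
        pairs <- rbind(pairs, data.frame(start1 = a1, start2 = a2,
                                         mh_len = m))
        break
      }
    }
    amp_str <- paste(amp, collapse = "")
    fwd <- .substr0(amp_str, 0L, 20L)
    rev_landing <- .substr0(amp_str, length - 20L, length)
    ok <- length(.find_all(enzyme_recognition, amp_str)) == 1L &&
      length(.find_all(fwd, amp_str)) == 1L &&
      length(.find_all(rev_landing, amp_str)) == 1L &&
      nrow(pairs) >= max(1L, n_repeat_pairs %/% 2L)
    if (ok) {
      locus <- reference_locus(
        name = sprintf("synthetic_locus_seed%d", seed),
        amplicon = amp_str, cut_position = cut, fwd_primer = fwd,
        rev_primer = revcomp(rev_landing),
        enzyme_recognition = enzyme_recognition,
        recognition_site_span = span, recognition_strand = "+")
      attr(locus, "repeat_pairs") <- pairs
      return(locus)
    }
  }
  stop(sprintf("could not satisfy locus constraints in %d tries", max_tries))
}

# truth measurement for a pure deletion [j, j+d): canonical (p, s, m)
# by direct placement-shift enumeration on the amplicon
.deletion_truth <- function(amp, j, d) {
  sh <- .placement_shifts(amp, j, d)
  m <- min(sh[["left"]] + sh[["right"]], d)
  p <- j + sh[["right"]]
  list(p = as.integer(p), s = as.integer(nchar(amp) - (j - sh[["left"]]) - d),
       m = as.integer(m))
}

# expected filter verdict for an intact-primer read with prefix p, suffix s
.site_verdict <- function(locus, p, s) {
  span <- locus$recognition_site_span
  R <- nchar(locus$amplicon)
  if (p >= span[2] || s >= R - span[1]) "site_retained" else "pass"
}

#' Simulate repair-product reads with a truth table
#'
#' Draws `n` reads from the profile's event-class mixture. Deletions
#' straddle the cut position (destroying the recognition site);
#' microhomology-class deletions run between the locus's planted repeat
#' pairs so the emitted read carries genuine junction homology. Truth
#' `(d, i, m)` is measured on the emitted read by placement enumeration,
#' so chance homology extensions are part of the recorded truth.
#' Substitution noise and primer truncations are applied after the truth
#' is fixed; substitutions avoid the 10 bases flanking the junction and
#' the primer landing sites.
#'
#' @param locus A locus from [gen_reference_locus()].
#' @param profile A [repair_profile()].
#' @param n Number of reads.
#' @param seed Integer seed.
#' @return A list with `reads` (named character vector) and `truth`
#'   (`data.frame`: `read_id`, `class` (generator class), `event_class`
#'   (expected caller class), `expected_verdict`, `d`, `i`, `m`, `noisy`,
#'   `truncated`).
#' @export
simulate_repair_reads <- function(locus, profile, n, seed = 1L) {
  stopifnot(inherits(locus, "reference_locus"),
            inherits(profile, "repair_profile"))
  set.seed(seed)
  amp <- locus$amplicon
  R <- nchar(amp)
  cut <- locus$cut_position
  pairs <- attr(locus, "repeat_pairs")
  classes <- sample(names(profile$weights), n, replace = TRUE,
                    prob = profile$weights)
  n_resampled <- 0L

  reads <- character(n)
  truth <- vector("list", n)
  for (k in seq_len(n)) {
    cls <- classes[k]
    if (cls == "unmodified") {
      reads[k] <- amp
      truth[[k]] <- list(class = cls, event_class = "unmodified",
                         expected_verdict = "site_retained",
                         d = 0L, i = 0L, m = 0L)
      next
    }
    if (cls == "mmej_del") {
      pk <- pairs[sample.int(nrow(pairs), 1L), ]
      j <- pk$start1 + pk$mh_len
      d <- pk$start2 - pk$start1
    } else if (cls %in% c("small_del", "large_del")) {
      rng <- if (cls == "small_del") profile$small_del_range
             else profile$large_del_range
      repeat {
        d <- sample(rng[1]:rng[2], 1L)
        j_lo <- max(21L, cut - d)
        j_hi <- min(cut, R - 21L - d)
        if (j_lo <= j_hi) break
        n_resampled <- n_resampled + 1L
      }
      j <- if (j_lo == j_hi) j_lo else sample(j_lo:j_hi, 1L)
    } else {                             # junction_insertion
      d <- sample(0:8, 1L)
      i_len <- sample(1:10, 1L)
      j <- if (d == 0L) cut else {
        j_lo <- max(21L, cut - d); j_hi <- min(cut, R - 21L - d)
        if (j_lo == j_hi) j_lo else sample(j_lo:j_hi, 1L)
      }
      # inserted bases are drawn to differ from the reference both
      # start-aligned and end-aligned across the deleted segment, so an
      # insertion is never confusable with substitution noise inside a
      # deletion (and prefix/suffix arithmetic stops exactly at the
      # intended junction)
      ca <- .chars(amp)
      ins <- character(i_len)
      for (t in seq_len(i_len)) {
        clash <- c(ca[j + t], ca[j + d - i_len + t])
        if (t == i_len && d > 0L) clash <- c(clash, ca[j + d])
        if (t == 1L && d == 0L) clash <- c(clash, ca[j])
        clash <- clash[!is.na(clash)]
        ins[t] <- sample(setdiff(.BASES, clash), 1L)
      }
      reads[k] <- paste0(.substr0(amp, 0L, j), paste(ins, collapse = ""),
                         .substr0(amp, j + d, R))
      truth[[k]] <- list(
        class = cls,
        event_class = if (d == 0L) "pure_insertion"
                      else "deletion_with_insertion",
        expected_verdict = .site_verdict(locus, j, R - j - d),
        d = as.integer(d), i = i_len, m = 0L)
      next
    }
    # pure deletion [j, j + d)
    reads[k] <- paste0(.substr0(amp, 0L, j), .substr0(amp, j + d, R))
    tr <- .deletion_truth(amp, j, d)
    truth[[k]] <- list(class = cls, event_class = "deletion",
                       expected_verdict = .site_verdict(locus, tr$p, tr$s),
                       d = as.integer(d), i = 0L, m = tr$m)
  }

  truth <- do.call(rbind, lapply(truth, as.data.frame))
  truth$read_id <- sprintf("read%04d", seq_len(n))
  truth <- truth[, c("read_id", "class", "event_class", "expected_verdict",
                     "d", "i", "m")]

  # substitution noise, avoiding junction +/- 10 and the primer sites
  truth$noisy <- FALSE
  if (profile$sub_rate > 0) {
    for (k in seq_len(n)) {
      S <- nchar(reads[k])
      # eligible read positions: inside the primers, outside a generous
      # window around any possible junction placement
      lo <- 21L; hi <- S - 20L
      if (hi <= lo) next
      elig <- setdiff(lo:hi, max(lo, cut - truth$d[k] - truth$m[k] - 10L):
                               min(hi, cut + 10L))
      hitn <- stats::rbinom(1L, length(elig), profile$sub_rate)
      if (hitn == 0L) next
      pos <- sample(elig, hitn)
      ch <- .chars(reads[k])
      for (p0 in pos) ch[p0] <- sample(setdiff(.BASES, ch[p0]), 1L)
      reads[k] <- paste(ch, collapse = "")
      truth$noisy[k] <- TRUE
    }
  }

  # primer truncations (override the expected verdict)
  truth$truncated <- FALSE
  if (profile$trunc_frac > 0) {
    tr_idx <- which(stats::runif(n) < profile$trunc_frac)
    for (k in tr_idx) {
      S <- nchar(reads[k])
      cut_len <- sample(1:10, 1L)
      if (stats::runif(1) < 0.5) {
        reads[k] <- .substr0(reads[k], cut_len, S)
        truth$expected_verdict[k] <- "missing_fwd_primer"
      } else {
        reads[k] <- .substr0(reads[k], 0L, S - cut_len)
        truth$expected_verdict[k] <- "missing_rev_primer"
      }
      truth$truncated[k] <- TRUE
    }
  }

  names(reads) <- truth$read_id
  attr(truth, "n_resampled") <- n_resampled
  list(reads = reads, truth = truth)
}

#' Simulate a plate-based siRNA screen
#'
#' Lays a library of `genes` x `sirnas_per_gene` siRNAs onto 16 x 24
#' (384-well) plates, with reference (transfection-reagent-only) wells
#' scattered across every plate. Well values are a baseline plus additive
#' per-plate row and column effects plus Gaussian noise; planted hit genes
#' shift all of their siRNAs by `effect_rz` reference-scale units
#' (negative direction: loss of foci).
#'
#' @param genes Number of genes (default 582).
#' @param sirnas_per_gene siRNAs per gene (default 3).
#' @param hit_fraction Fraction of genes planted as hits (default 0.01).
#' @param effect_rz Planted effect size in reference-scale (RZ) units
#'   (default 4).
#' @param row_effect_sd,col_effect_sd SDs of the additive positional
#'   effects (default 3 each).
#' @param replicates Replicate experiments (default 3).
#' @param noise_sd Well-level Gaussian noise SD (default 3).
#' @param baseline Mean % multi-foci of unperturbed wells (default 20).
#' @param seed Integer seed.
#' @return A `data.frame` of wells (`plate`, `row`, `col`, `replicate`,
#'   `gene`, `sirna`, `role`, `value`) with attribute `"truth"`
#'   (`data.frame`: `gene`, `is_hit`, `direction`).
#' @export
simulate_plate <- function(genes = 582L, sirnas_per_gene = 3L,
                           hit_fraction = 0.01, effect_rz = 4,
                           row_effect_sd = 3, col_effect_sd = 3,
                           replicates = 3L, noise_sd = 3, baseline = 20,
                           seed = 1L) {
  if (hit_fraction < 0 || hit_fraction > 1) {
    stop("hit_fraction must be in [0, 1]")
  }
  set.seed(seed)
  gene_ids <- sprintf("G%04d", seq_len(genes))
  sirna <- data.frame(
    gene = rep(gene_ids, each = sirnas_per_gene),
    sirna = paste0(rep(gene_ids, each = sirnas_per_gene), "_s",
                   rep(seq_len(sirnas_per_gene), genes)),
    stringsAsFactors = FALSE)
  n_hits <- round(hit_fraction * genes)
  hit_genes <- if (n_hits > 0) sample(gene_ids, n_hits) else character(0)
  truth <- data.frame(gene = gene_ids, is_hit = gene_ids %in% hit_genes,
                      direction = ifelse(gene_ids %in% hit_genes,
                                         "negative", "none"),
                      stringsAsFactors = FALSE)
  shift <- -effect_rz * noise_sd

  n_rows <- 16L; n_cols <- 24L
  ref_wells <- unique(data.frame(
    row = rep(1:n_rows, 2L),
    col = c(((2 * (1:n_rows) - 1) %% n_cols) + 1L,
            ((2 * (1:n_rows) + 9) %% n_cols) + 1L)))
  sample_slots <- expand.grid(row = 1:n_rows, col = 1:n_cols)
  sample_slots <- sample_slots[!interaction(sample_slots$row, sample_slots$col)
                               %in% interaction(ref_wells$row, ref_wells$col), ]
  per_plate <- nrow(sample_slots)
  n_plates <- ceiling(nrow(sirna) / per_plate)

  out <- list()
  for (rep_id in seq_len(replicates)) {
    for (pl in seq_len(n_plates)) {
      row_eff <- stats::rnorm(n_rows, 0, row_effect_sd)
      col_eff <- stats::rnorm(n_cols, 0, col_effect_sd)
      plate_id <- sprintf("P%02d", pl)
      idx <- ((pl - 1L) * per_plate + 1L):min(pl * per_plate, nrow(sirna))
      slots <- sample_slots[seq_along(idx), ]
      smp <- data.frame(
        plate = plate_id, row = slots$row, col = slots$col,
        replicate = rep_id, gene = sirna$gene[idx],
        sirna = sirna$sirna[idx], role = "sample",
        stringsAsFactors = FALSE)
      smp$value <- baseline + row_eff[smp$row] + col_eff[smp$col] +
        ifelse(smp$gene %in% hit_genes, shift, 0) +
        stats::rnorm(nrow(smp), 0, noise_sd)
      ref <- data.frame(
        plate = plate_id, row = ref_wells$row, col = ref_wells$col,
        replicate = rep_id, gene = NA_character_, sirna = NA_character_,
        role = "reference", stringsAsFactors = FALSE)
      ref$value <- baseline + row_eff[ref$row] + col_eff[ref$col] +
        stats::rnorm(nrow(ref), 0, noise_sd)
      out[[length(out) + 1L]] <- rbind(smp, ref)
    }
  }
  wells <- do.call(rbind, out)
  wells$value <- pmin(pmax(wells$value, 0), 100)
  rownames(wells) <- NULL
  attr(wells, "truth") <- truth
  wells
}

#' Simulate a qPCR Ct table with programmed efficiencies
#'
#' `ct_target = ct_norm + dCt_ref - log2(efficiency) + noise`, so that
#' [ddct_efficiency()] recovers the programmed per-condition efficiency.
#'
#' @param true_efficiencies Named numeric vector of relative end-joining
#'   efficiencies per condition (the reference condition should be 1).
#' @param reference_condition Name of the reference condition (default
#'   the first element).
#' @param ct_norm_mean Mean normaliser Ct (default 20).
#' @param sd Gaussian noise SD on each Ct (default 0.1).
#' @param n Samples per condition (default 6).
#' @param dct_ref Baseline target-minus-normaliser Ct offset (default 8).
#' @param seed Integer seed.
#' @return A `data.frame` with `sample`, `condition`, `ct_target`,
#'   `ct_norm`.
#' @export
simulate_qpcr <- function(true_efficiencies,
                          reference_condition = names(true_efficiencies)[1],
                          ct_norm_mean = 20, sd = 0.1, n = 6L,
                          dct_ref = 8, seed = 1L) {
  if (sd < 0) stop("sd must be non-negative")
  if (any(true_efficiencies <= 0)) stop("efficiencies must be positive")
  if (is.null(names(true_efficiencies))) {
    stop("true_efficiencies must be a named vector of conditions")
  }
  set.seed(seed)
  out <- lapply(names(true_efficiencies), function(cond) {
    ct_norm <- stats::rnorm(n, ct_norm_mean, sd)
    ct_target <- ct_norm + dct_ref - log2(true_efficiencies[[cond]]) +
      stats::rnorm(n, 0, sd)
    data.frame(sample = sprintf("%s_%d", cond, seq_len(n)),
               condition = cond, ct_target = ct_target, ct_norm = ct_norm,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a steady-state binding series
#'
#' One-site isotherm responses `rmax * C / (kd + C)` with additive
#' Gaussian noise.
#'
#' @param kd Dissociation constant (nM).
#' @param rmax Saturating response.
#' @param concentrations Analyte concentrations (nM).
#' @param noise_sd Gaussian noise SD (sensor units).
#' @param seed Integer seed.
#' @return A `data.frame` with `concentration_nM` and `response`.
#' @export
simulate_bli <- function(kd, rmax, concentrations, noise_sd = 0,
                         seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (kd <= 0 || rmax <= 0 || any(concentrations <= 0)) {
    stop("kd, rmax and concentrations must be positive")
  }
  set.seed(seed)
  data.frame(
    concentration_nM = concentrations,
    response = rmax * concentrations / (kd + concentrations) +
      stats::rnorm(length(concentrations), 0, noise_sd))
}
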