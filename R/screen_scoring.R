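# Robust scoring of plate-based high-content screens.
#
# Raw per-well values (% cells with multiple foci) carry additive row and
# column artefacts from liquid handling and imaging; these are removed by
# Tukey's two-way median polish per plate. Corrected values are expressed
# as robust Z-scores (RZ) against the plate's reference population
# (transfection-reagent-only wells), and genes are called as hits when at
# least `min_sirnas` independent siRNAs score beyond the threshold in the
# same direction in at least `min_replicates` replicate experiments.

#' Two-way median polish of a plate matrix
#'
#' Iteratively subtracts row and column medians (Tukey's procedure, via
#' [stats::medpolish()]) until the change in the sum of absolute residuals
#' falls below `tol`. Corrected values are residuals plus the overall
#' effect, so positional (row/column) trends are removed while the plate's
#' typical level is retained. Missing wells are ignored in the medians and
#' stay missing; a fully missing row or column keeps effect 0 with a
#' warning.
#'
#' @param plate_matrix Numeric rows x columns matrix, `NA` for missing
#'   wells.
#' @param max_iter Maximum polish iterations (default 10).
#' @param tol Convergence tolerance on the sum of absolute residuals
#'   (default 1e-6).
#' @return A list with `corrected` (residuals + overall), `residuals`,
#'   `row_effects`, `col_effects`, `overall`.
#' @export
median_polish <- function(plate_matrix, max_iter = 10L, tol = 1e-6) {
  stopifnot(is.matrix(plate_matrix), is.numeric(plate_matrix))
  all_na_row <- apply(plate_matrix, 1, function(r) all(is.na(r)))
  all_na_col <- apply(plate_matrix, 2, function(c) all(is.na(c)))
  if (any(all_na_row) || any(all_na_col)) {
    warning(sprintf("%d fully missing row(s) and %d column(s): effects set to 0",
                    sum(all_na_row), sum(all_na_col)))
  }
  work <- plate_matrix[!all_na_row, !all_na_col, drop = FALSE]
  mp <- stats::medpolish(work, eps = tol, maxiter = max_iter,
                         na.rm = TRUE, trace.iter = FALSE)
  row_effects <- rep(0, nrow(plate_matrix))
  col_effects <- rep(0, ncol(plate_matrix))
  row_effects[!all_na_row] <- mp$row
  col_effects[!all_na_col] <- mp$col
  residuals <- matrix(NA_real_, nrow(plate_matrix), ncol(plate_matrix),
                      dimnames = dimnames(plate_matrix))
  residuals[!all_na_row, !all_na_col] <- mp$residuals
  list(corrected = residuals + mp$overall, residuals = residuals,
       row_effects = row_effects, col_effects = col_effects,
       overall = mp$overall)
}

#' Robust Z-scores against a reference population
#'
#' `RZ = (x - median(ref)) / (mad_constant * MAD(ref))` with
#' `MAD(ref) = median(|ref - median(ref)|)` (the raw, unscaled MAD). The
#' default scaling constant 1.4826 makes the denominator a consistent
#' estimate of the standard deviation under normality; it is configurable.
#'
#' @param values Numeric vector of (position-corrected) well values.
#' @param reference_population Numeric vector of corrected reference-well
#'   values (>= 8 wells required).
#' @param mad_constant MAD scaling constant (default 1.4826).
#' @return Numeric vector of RZ scores.
#' @export
rz_score <- function(values, reference_population, mad_constant = 1.4826) {
  reference_population <- reference_population[!is.na(reference_population)]
  if (length(reference_population) < 8L) {
    stop("reference population must contain at least 8 wells")
  }
  med <- stats::median(reference_population)
  mad_raw <- stats::median(abs(reference_population - med))
  if (mad_raw == 0) {
    stop(paste("MAD of the reference population is 0;",
               "use a fallback scale (e.g. pooled plate MAD) instead of RZ"))
  }
  (values - med) / (mad_constant * mad_raw)
}

#' Replicate-aware gene-level hit calling
#'
#' A siRNA supports a direction in a replicate iff its RZ exceeds
#' `threshold` (positive) or falls below `-threshold` (negative). A siRNA
#' supports the direction overall iff it does so in at least
#' `min_replicates` replicates; a gene is a hit in a direction iff at
#' least `min_sirnas` of its siRNAs support that same direction. Genes
#' assayed with a single siRNA can never be hits and are flagged
#' underpowered.
#'
#' @param rz_results `data.frame` with columns `gene`, `sirna`,
#'   `replicate`, `rz`.
#' @param threshold Absolute RZ threshold (default 2).
#' @param min_sirnas Minimum supporting siRNAs per gene (default 2).
#' @param min_replicates Minimum supporting replicates per siRNA
#'   (default 2).
#' @return A list with `genes` (gene, hit, direction,
#'   `n_sirnas_supporting` per direction, underpowered flag) and `sirnas`
#'   (per-siRNA median RZ across replicates and supported direction).
#' @export
call_hits <- function(rz_results, threshold = 2, min_sirnas = 2L,
                      min_replicates = 2L) {
  req <- c("gene", "sirna", "replicate", "rz")
  if (!all(req %in% names(rz_results))) {
    stop("rz_results must have columns: ", paste(req, collapse = ", "))
  }
  sir_split <- split(rz_results, rz_results$sirna)
  sirnas <- do.call(rbind, lapply(sir_split, function(df) {
    pos <- sum(df$rz > threshold, na.rm = TRUE)
    neg <- sum(df$rz < -threshold, na.rm = TRUE)
    dir <- if (pos >= min_replicates && pos >= neg) "positive"
           else if (neg >= min_replicates) "negative" else "none"
    data.frame(gene = df$gene[1], sirna = df$sirna[1],
               median_rz = stats::median(df$rz, na.rm = TRUE),
               n_rep_pos = pos, n_rep_neg = neg, direction = dir,
               stringsAsFactors = FALSE)
  }))
  rownames(sirnas) <- NULL
  gene_split <- split(sirnas, sirnas$gene)
  genes <- do.call(rbind, lapply(gene_split, function(df) {
    n_pos <- sum(df$direction == "positive")
    n_neg <- sum(df$direction == "negative")
    underpowered <- nrow(df) < min_sirnas
    hit <- !underpowered && (n_pos >= min_sirnas || n_neg >= min_sirnas)
    direction <- if (!hit) "none"
                 else if (n_pos >= min_sirnas && n_pos >= n_neg) "positive"
                 else "negative"
    data.frame(gene = df$gene[1], hit = hit, direction = direction,
               n_sirnas_pos = n_pos, n_sirnas_neg = n_neg,
               n_sirnas = nrow(df), underpowered = underpowered,
               stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  list(genes = genes, sirnas = sirnas)
}

#' Percentage of cells with at least a threshold number of foci
#'
#' @param foci_counts Non-negative integer vector, one count per cell.
#' @param threshold Foci count defining "multi-foci" (default 5).
#' @return Percentage in `[0, 100]`.
#' @export
multi_foci_fraction <- function(foci_counts, threshold = 5L) {
  if (length(foci_counts) == 0L) stop("no cells")
  if (any(foci_counts < 0)) stop("foci counts must be non-negative")
  100 * mean(foci_counts >= threshold)
}

#' Score a full screen: polish, RZ, hit calling
#'
#' For each replicate and plate, the well values are arranged by row and
#' column, positional effects are removed by [median_polish()] (unless
#' `correct_positional = FALSE`), and RZ scores are computed against that
#' plate's reference wells. Gene-level hits are then called across
#' replicates with [call_hits()].
#'
#' @param wells `data.frame` with columns `plate`, `row`, `col`,
#'   `replicate`, `gene`, `sirna`, `role`, `value`; `role` is `sample`,
#'   `reference`, or a control label. Reference wells define the RZ null.
#' @param mad_constant Passed to [rz_score()].
#' @param threshold,min_sirnas,min_replicates Passed to [call_hits()].
#' @param correct_positional Apply median polish first (default TRUE)?
#' @param polish_max_iter Iteration cap for the per-plate polish (default
#'   100; plates are small, so full convergence is cheap).
#' @return A list with `wells` (input plus `corrected` and `rz`),
#'   `rz_table` (sample wells only), `genes` and `sirnas` from
#'   [call_hits()].
#' @export
score_screen <- function(wells, mad_constant = 1.4826, threshold = 2,
                         min_sirnas = 2L, min_replicates = 2L,
                         correct_positional = TRUE, polish_max_iter = 100L) {
  req <- c("plate", "row", "col", "replicate", "gene", "sirna", "role",
           "value")
  if (!all(req %in% names(wells))) {
    stop("wells must have columns: ", paste(req, collapse = ", "))
  }
  wells$corrected <- NA_real_
  wells$rz <- NA_real_
  for (rep_id in unique(wells$replicate)) {
    for (plate_id in unique(wells$plate[wells$replicate == rep_id])) {
      idx <- which(wells$replicate == rep_id & wells$plate == plate_id)
      sub <- wells[idx, ]
      nr <- max(sub$row); nc <- max(sub$col)
      mat <- matrix(NA_real_, nr, nc)
      mat[cbind(sub$row, sub$col)] <- sub$value
      corrected_mat <- if (correct_positional) {
        median_polish(mat, max_iter = polish_max_iter)$corrected
      } else {
        mat
      }
      corrected <- corrected_mat[cbind(sub$row, sub$col)]
      wells$corrected[idx] <- corrected
      ref <- corrected[sub$role == "reference"]
      wells$rz[idx] <- rz_score(corrected, ref, mad_constant)
    }
  }
  samples <- wells[wells$role == "sample", ]
  rz_table <- samples[, c("gene", "sirna", "replicate", "rz")]
  hits <- call_hits(rz_table, threshold = threshold,
                    min_sirnas = min_sirnas,
                    min_replicates = min_replicates)
  list(wells = wells, rz_table = rz_table, genes = hits$genes,
       sirnas = hits$sirnas)
}
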