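# Readers and writers for the plain-text formats the pipeline consumes:
# FASTA for amplicons and reads, CSV for calls, wells, Ct and binding
# tables, and a simple key: value locus configuration file.

#' Read a FASTA file into a named character vector
#'
#' Wrapped or single-line FASTA; sequences are case-folded to uppercase
#' and validated against the IUPAC DNA alphabet. Record order is
#' preserved.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop(sprintf(
                    "failed to read FASTA '%s': %s", path,
                    conditionMessage(e)), call. = FALSE))
  if (length(set) == 0L) stop(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate FASTA id: %s", dup[1]))
  }
  out <- toupper(as.character(set))
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

#' Read a locus configuration file
#'
#' A small `key: value` text format with fields `name`, `amplicon_file`
#' (FASTA with one record) or `amplicon`, `cut_position`, `fwd_primer`,
#' `rev_primer`, `enzyme_recognition`, `recognition_site_start`,
#' `recognition_site_end`, `recognition_strand`. All coordinates 0-based,
#' half-open.
#'
#' @param path Config file path.
#' @return A [reference_locus()].
#' @export
read_locus_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_]+)\\s*:\\s*(.*?)\\s*$",
                                  lines))
  cfg <- stats::setNames(vapply(kv, `[`, character(1), 3L),
                         vapply(kv, `[`, character(1), 2L))
  amplicon <- if ("amplicon" %in% names(cfg)) cfg[["amplicon"]] else {
    afile <- cfg[["amplicon_file"]]
    if (!file.exists(afile)) {
      afile <- file.path(dirname(path), afile)
    }
    read_fasta(afile)[[1]]
  }
  reference_locus(
    name = cfg[["name"]], amplicon = amplicon,
    cut_position = as.integer(cfg[["cut_position"]]),
    fwd_primer = cfg[["fwd_primer"]], rev_primer = cfg[["rev_primer"]],
    enzyme_recognition = if ("enzyme_recognition" %in% names(cfg))
      cfg[["enzyme_recognition"]] else "GGTGA",
    recognition_site_span = c(as.integer(cfg[["recognition_site_start"]]),
                              as.integer(cfg[["recognition_site_end"]])),
    recognition_strand = if ("recognition_strand" %in% names(cfg))
      cfg[["recognition_strand"]] else "+")
}

#' Write a locus configuration file
#'
#' @param locus A [reference_locus()].
#' @param path Output path.
#' @export
write_locus_config <- function(locus, path) {
  stopifnot(inherits(locus, "reference_locus"))
  writeLines(c(
    "# locus configuration; coordinates 0-based, half-open",
    paste0("name: ", locus$name),
    paste0("amplicon: ", locus$amplicon),
    paste0("cut_position: ", locus$cut_position),
    paste0("fwd_primer: ", locus$fwd_primer),
    paste0("rev_primer: ", locus$rev_primer),
    paste0("enzyme_recognition: ", locus$enzyme_recognition),
    paste0("recognition_site_start: ", locus$recognition_site_span[1]),
    paste0("recognition_site_end: ", locus$recognition_site_span[2]),
    paste0("recognition_strand: ", locus$recognition_strand)), path)
  invisible(path)
}

#' Write per-read calls and a sample summary as CSV reports
#'
#' Emits `calls.csv` (one row per read, deterministic column order) and
#' `summary.csv` into `out_dir`, each with run metadata (package version,
#' seed, configuration hash) as leading `#` comment lines. Coordinates in
#' the outputs are 0-based, half-open.
#'
#' @param calls Per-read call `data.frame` from [call_junctions()].
#' @param summary A `sample_summary` from [summarize_sample()].
#' @param out_dir Output directory (created if needed).
#' @param seed Seed recorded in the header (optional).
#' @param overwrite Overwrite existing report files (default FALSE)?
#' @return Invisibly, the paths written.
#' @export
write_report <- function(calls, summary, out_dir, seed = NA,
                         overwrite = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("calls.csv", "summary.csv"))
  if (!overwrite && any(file.exists(paths))) {
    stop("report files already exist; use overwrite = TRUE")
  }
  version <- as.character(utils::packageVersion("mitorepair"))
  cfg_hash <- sum(utf8ToInt(paste(names(calls), collapse = ","))) %% 100000L
  header <- c(
    sprintf("# mitorepair %s", version),
    sprintf("# seed: %s", seed),
    sprintf("# config_hash: %05d", cfg_hash),
    "# coordinates: 0-based, half-open")

  writeLines(header, paths[1])
  suppressWarnings(utils::write.table(
    calls, paths[1], sep = ",", row.names = FALSE, quote = FALSE,
    append = TRUE))

  sm <- data.frame(
    metric = c("n_reads_in", paste0("excluded_", names(summary$n_excluded_by_filter)),
               "n_events",
               paste0("del_bin_", names(summary$deletion_size_histogram)),
               "fraction_mh", "median_deletion"),
    value = c(summary$n_reads_in, summary$n_excluded_by_filter,
              summary$n_events, summary$deletion_size_histogram,
              summary$fraction_mh, summary$median_deletion))
  writeLines(header, paths[2])
  suppressWarnings(utils::write.table(
    sm, paths[2], sep = ",", row.names = FALSE, quote = FALSE,
    append = TRUE))
  invisible(paths)
}

#' Read a report CSV written by [write_report()]
#'
#' @param path CSV path.
#' @return A `data.frame` (header comment lines skipped).
#' @export
read_report_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
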