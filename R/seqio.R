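#' Read amplicon reads from FASTA or FASTQ
#'
#' Parses a (pre-merged, single-end) read file into a read-set data frame.
#' Lowercase sequence is uppercased; records containing characters outside
#' the IUPAC nucleotide alphabet are rejected with a warning reporting the
#' count. Qualities (Phred+33) are carried along for FASTQ input but are
#' not used in classification.
#'
#' @param path Path to the reads file.
#' @param format `"fastq"`, `"fasta"`, or `"auto"` (first non-empty
#'   character: `@` means FASTQ, `>` means FASTA).
#' @return A data frame with columns `read_id`, `sequence` and (FASTQ)
#'   `quality`, in file order.
#' @export
read_sequences <- function(path, format = c("auto", "fastq", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("reads file not found: ", path)
  if (format == "auto") {
    con <- file(path, "r")
    on.exit(close(con))
    first <- ""
    while (TRUE) {
      line <- readLines(con, n = 1L)
      if (length(line) == 0L) break
      if (nzchar(trimws(line))) {
        first <- substr(trimws(line), 1L, 1L)
        break
      }
    }
    close(con)
    on.exit()
    if (first == "@") format <- "fastq"
    else if (first == ">") format <- "fasta"
    else if (first == "") {
      warning("empty reads file: ", path, call. = FALSE)
      return(data.frame(read_id = character(0), sequence = character(0),
                        quality = character(0), stringsAsFactors = FALSE))
    } else stop_input("cannot auto-detect format of ", path)
  }
  rec <- tryCatch({
    parsed <- Biostrings::readBStringSet(path, format = format,
                                         with.qualities = (format == "fastq"))
    seqs <- toupper(as.character(parsed))
    quals <- if (format == "fastq")
      as.character(S4Vectors::mcols(parsed)$qualities)
      else rep(NA_character_, length(seqs))
    if (format == "fastq") {
      if (any(nchar(quals, type = "bytes") != nchar(seqs, type = "bytes")))
        stop("record with quality length != sequence length")
      # Phred+33 qualities are printable ASCII; anything else marks a
      # record whose quality line did not cover the sequence
      if (!all(grepl("^[!-~]*$", quals, useBytes = TRUE)))
        stop("record with quality length != sequence length")
    }
    list(ids = names(parsed) %||% as.character(seq_along(parsed)),
         seqs = seqs, quals = quals)
  }, error = function(e) stop_input("failed to parse ", path, " as ", format,
                                    ": ", conditionMessage(e)))
  ids <- vapply(strsplit(rec$ids, "[ \t]"), `[`, "", 1L)
  seqs <- rec$seqs
  quals <- rec$quals
  ok <- nchar(seqs) > 0L & is_iupac(seqs)
  if (any(!ok))
    warning(sum(!ok), " record(s) with non-IUPAC characters rejected",
            call. = FALSE)
  out <- data.frame(read_id = ids[ok], sequence = seqs[ok],
                    quality = quals[ok], stringsAsFactors = FALSE)
  if (nrow(out) == 0L) warning("no usable records in ", path, call. = FALSE)
  out
}

#' Write a read set to FASTQ
#'
#' @param reads Read-set data frame (`read_id`, `sequence`, optionally
#'   `quality`; missing qualities become constant Q30).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  qual <- reads$quality
  if (is.null(qual) || anyNA(qual))
    qual <- strrep("?", nchar(reads$sequence))   # Phred+33 Q30
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Write the tabular and JSON outputs of an editing profile
#'
#' Writes `<sample>_summary.tsv` (read accounting and efficiencies),
#' `<sample>_spectrum.tsv` (one row per canonical indel variant) and
#' `<sample>_profile.json` (the same content machine-readable, with the
#' full configuration echoed and a configuration hash). Missing
#' percentages are written as `"."`.
#'
#' @param profile An `editing_profile`.
#' @param out_dir Output directory (created if absent).
#' @return Named character vector of the files written, invisibly.
#' @export
write_profile_tables <- function(profile, out_dir) {
  stopifnot(inherits(profile, "editing_profile"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_input("cannot create output directory ", out_dir)
  }
  if (file.access(out_dir, 2L) != 0L)
    stop_input("output directory not writable: ", out_dir)
  stem <- file.path(out_dir, profile$sample_id)
  fmt <- function(x) ifelse(is.na(x), ".", format(x, digits = 10))
  acc <- profile$counts
  summary_df <- data.frame(
    metric = c(names(acc)[names(acc) != "sample_id"],
               "efficiency_all_alleles_pct", "efficiency_within_target_pct",
               "non_target_editing_pct"),
    value = c(vapply(acc[names(acc) != "sample_id"], as.character, ""),
              fmt(profile$efficiency_all_alleles),
              fmt(profile$efficiency_within_target),
              fmt(profile$non_target_editing)),
    stringsAsFactors = FALSE)
  f_summary <- paste0(stem, "_summary.tsv")
  write.table(summary_df, f_summary, sep = "\t", quote = FALSE,
              row.names = FALSE)
  sp <- profile$spectrum
  sp_out <- data.frame(variant_key = sp$variant_key,
                       mutation_class = sp$mutation_class,
                       display_label = sp$display_label,
                       net_delta = sp$net_delta, count = sp$count,
                       pct_of_filtered = fmt(sp$pct_filtered),
                       pct_of_edited_target = fmt(sp$pct_edited),
                       stringsAsFactors = FALSE)
  f_spectrum <- paste0(stem, "_spectrum.tsv")
  write.table(sp_out, f_spectrum, sep = "\t", quote = FALSE,
              row.names = FALSE)
  payload <- list(
    sample_id = profile$sample_id,
    counts = profile$counts[names(profile$counts) != "sample_id"],
    efficiency_all_alleles = profile$efficiency_all_alleles,
    efficiency_within_target = profile$efficiency_within_target,
    non_target_editing = profile$non_target_editing,
    spectrum = profile$spectrum,
    warnings = profile$warnings %||% character(0),
    config = profile$config,
    config_hash = config_hash(profile$config))
  f_json <- paste0(stem, "_profile.json")
  jsonlite::write_json(payload, f_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(summary = f_summary, spectrum = f_spectrum, json = f_json))
}

#' Read a sample sheet (TSV or YAML)
#'
#' A sample sheet lists one record per sample: `sample_id`, `reads` (path),
#' optional `format`, `replicate` and `predicted_profile` columns.
#'
#' @param path Path to a tab-separated (`.tsv`/`.txt`) or YAML
#'   (`.yml`/`.yaml`) sample sheet.
#' @return A data frame of sample records.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop_input("sample sheet not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    lst <- yaml::read_yaml(path)
    if (!is.null(lst$samples)) lst <- lst$samples
    sheet <- do.call(rbind, lapply(lst, function(s)
      data.frame(sample_id = s$sample_id,
                 reads = s$reads,
                 format = s$format %||% "auto",
                 replicate = s$replicate %||% NA_character_,
                 predicted_profile = s$predicted_profile %||% NA_character_,
                 stringsAsFactors = FALSE)))
  } else {
    sheet <- read.delim(path, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    if (is.null(sheet$format)) sheet$format <- "auto"
    if (is.null(sheet$replicate)) sheet$replicate <- NA_character_
    if (is.null(sheet$predicted_profile))
      sheet$predicted_profile <- NA_character_
  }
  if (is.null(sheet$sample_id) || is.null(sheet$reads))
    stop_input("sample sheet needs sample_id and reads columns")
  if (anyDuplicated(sheet$sample_id))
    stop_input("duplicate sample_id in sample sheet")
  sheet
}
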