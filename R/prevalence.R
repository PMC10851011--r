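#' Read a variant-prevalence table
#'
#' Parses a tab-separated table of population variant frequencies across
#' three gnomAD datasets (exomes v2, genomes v2, genomes v3). Decimal
#' commas (as printed in many European tables) are normalized to decimal
#' points; `"not detected"`, a dash or an empty cell become missing.
#'
#' @param path Path to the TSV; required columns `variant`,
#'   `freq_exome_v2`, `freq_genome_v2`, `freq_genome_v3`; `protein`,
#'   `inheritance` and others are carried through.
#' @return A data frame with the three frequency columns numeric in
#'   `[0, 1]` (`NA` for not detected).
#' @export
read_prevalence_table <- function(path) {
  if (!file.exists(path)) stop_input("prevalence table not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = TRUE)
  freq_cols <- c("freq_exome_v2", "freq_genome_v2", "freq_genome_v3")
  missing_cols <- setdiff(c("variant", freq_cols), names(tab))
  if (length(missing_cols))
    stop_input("prevalence table lacks column(s): ",
               paste(missing_cols, collapse = ", "))
  for (cc in freq_cols) tab[[cc]] <- parse_frequency(tab[[cc]])
  tab
}

parse_frequency <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("not detected", "nd", "-", "–", "—", "", "NA")] <- NA
  x <- gsub(",", ".", x, fixed = TRUE)
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) stop_input("unparseable frequency value: ", x[bad][1])
  if (any(out < 0 | out > 1, na.rm = TRUE))
    stop_input("frequencies must lie in [0, 1]")
  out
}

#' Mean population frequency across the three gnomAD datasets
#'
#' Computes the arithmetic mean of the exome-v2, genome-v2 and genome-v3
#' frequencies with "not detected" counted as zero, rounded to 8 decimal
#' places (the precision such tables are printed at). Rows where all three
#' datasets are missing stay missing (reported as a dash, not zero).
#'
#' @param rec A data frame with columns `freq_exome_v2`, `freq_genome_v2`,
#'   `freq_genome_v3` (one row per variant), or a numeric vector of the
#'   three frequencies for a single variant.
#' @return Numeric vector of mean frequencies (`NA` where all slots are
#'   missing).
#' @examples
#' mean_frequency(c(0.00004073, 0.0001597, 0.00007911))  # 0.00009318
#' @export
mean_frequency <- function(rec) {
  if (is.numeric(rec)) {
    m <- matrix(rec, ncol = 3, byrow = TRUE)
  } else {
    m <- as.matrix(rec[, c("freq_exome_v2", "freq_genome_v2",
                           "freq_genome_v3")])
    mode(m) <- "numeric"
  }
  all_missing <- rowSums(!is.na(m)) == 0L
  m[is.na(m)] <- 0
  out <- round(rowMeans(m), 8)
  out[all_missing] <- NA_real_
  out
}

#' Rank variants by mean population frequency
#'
#' Orders a prevalence table by descending mean frequency; variants never
#' detected in any dataset (missing mean) sort last, and ties break by
#' variant label.
#'
#' @param records A prevalence data frame (see [read_prevalence_table()]).
#' @return The data frame with `mean_freq` and `rank` columns, ordered.
#' @export
rank_variants <- function(records) {
  records$mean_freq <- mean_frequency(records)
  key <- records$mean_freq
  ord <- order(-ifelse(is.na(key), -Inf, key), records$variant,
               na.last = TRUE)
  # missing means must come after every present mean
  ord <- c(ord[!is.na(key[ord])], ord[is.na(key[ord])])
  out <- records[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
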