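#' Aggregate per-read edit calls into an editing profile
#'
#' Computes the per-sample read accounting, the three headline editing
#' percentages and the canonical indel spectrum. Two denominators are kept:
#' `efficiency_all_alleles` divides edited target reads by all filtered
#' reads ("out of all sequenced alleles"), `efficiency_within_target` by
#' target-allele reads only. Spectrum percentages are reported both of
#' filtered reads and of edited target reads.
#'
#' @param calls An `edit_calls` object from [call_sample()] (or its `calls`
#'   data frame plus an `accounting` list).
#' @param sample_id Optional sample label override.
#' @return An object of class `editing_profile`; see
#'   [quantify_editing()] for the methods it supports.
#' @export
summarize_calls <- function(calls, sample_id = NULL) {
  if (inherits(calls, "edit_calls")) {
    df <- calls$calls
    acc <- calls$accounting
    warnings <- calls$warnings
    sample_id <- sample_id %||% calls$sample_id
  } else {
    stop_input("summarize_calls expects an edit_calls object")
  }
  pct <- function(num, den) if (den > 0L) 100 * num / den else NA_real_
  edited_target <- df$passed_filter & !is.na(df$allele) &
    df$allele == "target" & df$mutation_class != "WT"
  spec_df <- df[edited_target, c("variant_key", "mutation_class",
                                 "display_label", "net_delta")]
  if (nrow(spec_df)) {
    agg <- aggregate(list(count = rep(1L, nrow(spec_df))),
                     by = spec_df[c("variant_key", "mutation_class",
                                    "display_label", "net_delta")],
                     FUN = sum)
    agg <- agg[order(-agg$count, agg$variant_key), , drop = FALSE]
    rownames(agg) <- NULL
    agg$pct_filtered <- 100 * agg$count / acc$n_filtered
    agg$pct_edited <- 100 * agg$count / acc$n_edited_target
  } else {
    agg <- data.frame(variant_key = character(0),
                      mutation_class = character(0),
                      display_label = character(0), net_delta = integer(0),
                      count = integer(0), pct_filtered = numeric(0),
                      pct_edited = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(
    sample_id = sample_id,
    counts = acc,
    efficiency_all_alleles = pct(acc$n_edited_target, acc$n_filtered),
    efficiency_within_target = pct(acc$n_edited_target, acc$n_target),
    non_target_editing = pct(acc$n_edited_non_target, acc$n_filtered),
    spectrum = agg,
    warnings = warnings,
    config = NULL,
    calls = df), class = "editing_profile")
}

#' Edited-cell fraction implied by an allele-level editing efficiency
#'
#' Under the diploid, uni-allelic-target assumption, each edited target
#' allele marks one edited cell, so the implied fraction of genetically
#' modified cells is twice the editing efficiency measured over all
#' sequenced alleles, capped at 100 percent: 21 percent allele-level
#' editing implies 42 percent edited cells, 30 percent implies 60 percent.
#'
#' @param efficiency_all_alleles Editing percentage in `[0, 100]`.
#' @return The implied edited-cell percentage, with the modelling assumption
#'   attached as attribute `assumption`.
#' @examples
#' implied_cell_fraction(21)  # 42
#' implied_cell_fraction(30)  # 60
#' @export
implied_cell_fraction <- function(efficiency_all_alleles) {
  x <- as.numeric(efficiency_all_alleles)
  if (any(is.na(x) | x < 0 | x > 100))
    stop_input("efficiency must be a percentage in [0, 100]")
  structure(pmin(100, 2 * x),
            assumption = "diploid locus, single targeted allele")
}

# extract a named percentage vector (pct of edited reads) from spectra
as_spectrum <- function(x) {
  if (inherits(x, "editing_profile")) {
    v <- setNames(x$spectrum$pct_edited, x$spectrum$variant_key)
  } else if (is.numeric(x) && !is.null(names(x))) {
    v <- x
  } else if (is.data.frame(x) && all(c("variant_key", "pct_edited") %in% names(x))) {
    v <- setNames(x$pct_edited, x$variant_key)
  } else {
    stop_input("cannot interpret object as an indel spectrum")
  }
  v <- v[!is.na(v)]
  if (length(v) == 0L || sum(v) <= 0)
    stop_input("spectrum has zero mass - nothing to compare")
  v
}

#' Compare two indel spectra
#'
#' Takes the union of canonical variant keys (missing keys contribute zero),
#' and reports the Pearson correlation of the percentage vectors, the total
#' variation distance `0.5 * sum(|a - b|) / 100`, and whether the top
#' variant agrees.
#'
#' @param a,b Editing profiles, or named percentage vectors keyed by
#'   canonical variant key (percentages of edited reads).
#' @return An object of class `profile_comparison` with fields `keys`,
#'   `freq` (two-column matrix), `pearson_r`, `total_variation_distance`,
#'   `top_variant_match`.
#' @examples
#' compare_profiles(c(del9 = 60, insA = 40), c(del9 = 40, insA = 60))
#' @export
compare_profiles <- function(a, b) {
  va <- as_spectrum(a)
  vb <- as_spectrum(b)
  keys <- sort(union(names(va), names(vb)))
  fa <- setNames(rep(0, length(keys)), keys)
  fb <- fa
  fa[names(va)] <- va
  fb[names(vb)] <- vb
  r <- if (length(keys) >= 2L && stats::sd(fa) > 0 && stats::sd(fb) > 0)
    cor(fa, fb) else NA_real_
  tvd <- 0.5 * sum(abs(fa - fb)) / 100
  top <- names(fa)[which.max(fa)] == names(fb)[which.max(fb)]
  structure(list(keys = keys, freq = cbind(a = fa, b = fb),
                 pearson_r = r, total_variation_distance = tvd,
                 top_variant_match = top),
            class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat(sprintf("spectrum comparison over %d variant keys: r = %s, TVD = %.3f, top variant %s\n",
              length(x$keys),
              if (is.na(x$pearson_r)) "NA" else sprintf("%.3f", x$pearson_r),
              x$total_variation_distance,
              if (x$top_variant_match) "matches" else "differs"))
  invisible(x)
}

#' Pairwise concordance of replicate editing profiles
#'
#' @param profiles A list of two or more editing profiles (or spectra).
#' @return A list of class `replicate_concordance` with the pairwise
#'   comparison table and the mean Pearson correlation.
#' @export
replicate_concordance <- function(profiles) {
  if (!is.list(profiles) || length(profiles) < 2L)
    stop_input("need at least two profiles")
  n <- length(profiles)
  ids <- names(profiles) %||% paste0("replicate", seq_len(n))
  if (is.null(names(profiles))) names(profiles) <- ids
  pairs <- utils::combn(n, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    cmp <- compare_profiles(profiles[[i]], profiles[[j]])
    data.frame(a = ids[i], b = ids[j], pearson_r = cmp$pearson_r,
               total_variation_distance = cmp$total_variation_distance,
               top_variant_match = cmp$top_variant_match,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  structure(list(pairs = tab, mean_r = mean(tab$pearson_r)),
            class = "replicate_concordance")
}

#' @export
print.replicate_concordance <- function(x, ...) {
  cat(sprintf("replicate concordance over %d pairs: mean r = %.3f\n",
              nrow(x$pairs), x$mean_r))
  print(x$pairs)
  invisible(x)
}

#' Load a predicted indel profile (inDelphi-style export)
#'
#' Reads a two-column tab-separated table (variant descriptor, frequency in
#' percent, header row) and converts the descriptors into canonical variant
#' keys relative to the cut site. The descriptor grammar is
#' `del{n}@{offset}` for deletions of `n` bases starting `offset` bases from
#' the cut, and `ins{BASES}@{offset}` for insertions at inter-base offset
#' `offset`. Frequencies are renormalized to sum to 100.
#'
#' @param path Path to the TSV file.
#' @return A named numeric vector of percentages keyed by canonical variant
#'   key, with descriptor labels in attribute `labels`.
#' @export
load_predicted_profile <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop_input("predicted profile needs two columns")
  desc <- as.character(tab[[1]])
  freq <- suppressWarnings(as.numeric(tab[[2]]))
  if (any(is.na(freq)))
    stop_input("non-numeric frequency at line ",
               which(is.na(freq))[1] + 1L)
  if (any(freq < 0)) stop_input("negative frequency in predicted profile")
  keys <- character(length(desc))
  for (i in seq_along(desc)) {
    d <- trimws(desc[i])
    m <- regmatches(d, regexec("^del([0-9]+)@(-?[0-9]+)$", d))[[1]]
    if (length(m) == 3L) {
      keys[i] <- sprintf("del|%s|%s|", m[3], m[2])
      next
    }
    m <- regmatches(d, regexec("^ins([ACGT]+)@(-?[0-9]+)$", d))[[1]]
    if (length(m) == 3L) {
      keys[i] <- sprintf("ins|%s|0|%s", m[3], m[2])
      next
    }
    stop_input("unparseable variant descriptor '", d, "' at line ", i + 1L)
  }
  if (sum(freq) <= 0) stop_input("predicted profile has zero total mass")
  out <- setNames(100 * freq / sum(freq), keys)
  attr(out, "labels") <- setNames(desc, keys)
  out
}
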