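#' Read filtering policy
#'
#' A read qualifies for analysis when it carries both indicator sequences —
#' the first and last `indicator_len` bases of the reference window — in
#' order, guaranteeing a full-span amplicon, and is at least `min_read_len`
#' long (reference length minus 30 by default, guarding degenerate
#' fragments). Samples whose filtered read count falls below
#' `min_reads_per_sample` are flagged with a warning but still processed.
#'
#' @param indicator_len Indicator k-mer length (default 15).
#' @param indicator_mode `"exact"` or `"max_1_mismatch"` occurrence test.
#' @param min_reads_per_sample Minimum filtered reads expected per sample.
#' @param min_read_len Minimum read length; `NULL` means reference length - 30.
#' @return An object of class `filter_policy`.
#' @export
filter_policy <- function(indicator_len = 15L,
                          indicator_mode = c("exact", "max_1_mismatch"),
                          min_reads_per_sample = 10000L,
                          min_read_len = NULL) {
  indicator_mode <- match.arg(indicator_mode)
  indicator_len <- as.integer(indicator_len)
  if (indicator_len < 5L) stop_config("indicator_len must be >= 5")
  structure(list(indicator_len = indicator_len,
                 indicator_mode = indicator_mode,
                 min_reads_per_sample = as.integer(min_reads_per_sample),
                 min_read_len = if (is.null(min_read_len)) NULL
                                else as.integer(min_read_len)),
            class = "filter_policy")
}

# first occurrence (1-based) of pattern in read at or after `from`,
# allowing up to max_mm mismatches; -1 if absent
find_approx <- function(read, pattern, max_mm = 0L, from = 1L) {
  if (max_mm == 0L) {
    p <- regexpr(pattern, substr(read, from, nchar(read)), fixed = TRUE)
    return(if (p < 0L) -1L else from + as.integer(p) - 1L)
  }
  k <- nchar(pattern)
  pc <- seq_chars(pattern)
  rc <- seq_chars(read)
  last <- nchar(read) - k + 1L
  if (last < from) return(-1L)
  for (s in from:last) {
    if (sum(rc[s:(s + k - 1L)] != pc) <= max_mm) return(s)
  }
  -1L
}

#' Test whether a read contains both indicator sequences
#'
#' @param read Read sequence (character) or read-set row.
#' @param target An `allele_reference` supplying the indicator k-mers (both
#'   alleles share them whenever the flank is positive).
#' @param policy A [filter_policy()].
#' @return `TRUE` if both terminal indicators occur in the read in order.
#' @export
passes_indicator_filter <- function(read, target, policy = filter_policy()) {
  seq <- if (is.list(read) || is.data.frame(read)) read$sequence else read
  seq <- toupper(as.character(seq))
  k <- policy$indicator_len
  ref_seq <- as_ref_sequence(target)
  if (2L * k >= nchar(ref_seq))
    stop_config("indicator_len too large for the reference window")
  left <- substr(ref_seq, 1L, k)
  right <- substr(ref_seq, nchar(ref_seq) - k + 1L, nchar(ref_seq))
  mm <- if (policy$indicator_mode == "exact") 0L else 1L
  p1 <- find_approx(seq, left, mm)
  if (p1 < 0L) return(FALSE)
  p2 <- find_approx(seq, right, mm, from = p1 + k)
  p2 > 0L
}

# canonical spectrum key for a set of within-window ops
variant_key <- function(ops, cut_site) {
  if (nrow(ops) == 0L) return("WT")
  paste(sprintf("%s|%d|%d|%s", ops$kind, ops$ref_start - cut_site,
                ops$ref_len, ops$alt), collapse = ";")
}

# human-readable label: del9, insA, delins9+A, subG, ...
display_label <- function(ops) {
  if (nrow(ops) == 0L) return("WT")
  del_n <- sum(ops$ref_len[ops$kind == "del"])
  ins_b <- paste(ops$alt[ops$kind == "ins"], collapse = "")
  sub_b <- paste(ops$alt[ops$kind == "sub"], collapse = "")
  if (del_n > 0L && nzchar(ins_b)) sprintf("delins%d+%s", del_n, ins_b)
  else if (del_n > 0L) sprintf("del%d", del_n)
  else if (nzchar(ins_b)) sprintf("ins%s", ins_b)
  else sprintf("sub%s", sub_b)
}

#' Classify an aligned read into an editing-outcome class
#'
#' Partitions the (normalized) edit operations into within-window edits and
#' out-of-window changes. Substitutions and deletions count as within-window
#' when they overlap the window's base range; insertions when they fall at
#' an inter-base position within the insertion range. The substitution at
#' the discriminating variant position is allele signal, never an edit.
#' Out-of-window substitutions are tallied as sequencing artifacts;
#' out-of-window indels are tallied separately and leave the read classified
#' WT (flagged, excluded from edited counts).
#'
#' @param aln An `edit_alignment` (or a raw ops data frame).
#' @param window An [editing_window()].
#' @param variant_index 0-based discriminating-base position, or `NULL`.
#' @param ref Reference the ops refer to (used to normalize raw ops).
#' @return A list of class `edit_call` with `mutation_class` (one of `WT`,
#'   `base_pair_exchange`, `deletion`, `insertion`,
#'   `deletion_plus_insertion`), `variant_key`, `display_label`,
#'   `net_delta`, `edited`, `artifact_subs`, `offwindow_indels` and the
#'   within-window ops.
#' @export
classify_read <- function(aln, window, variant_index = NULL, ref = NULL) {
  ops <- if (inherits(aln, "edit_alignment")) aln$ops else aln
  if (!is.null(ref)) ops <- normalize_ops(ops, ref)
  if (!is.null(window$ref_length) &&
      (window$base_range[1] < 0L || window$base_range[2] > window$ref_length))
    stop_internal("editing window outside reference")
  if (!is.null(variant_index) && nrow(ops) > 0L) {
    disc <- ops$kind == "sub" & ops$ref_start == variant_index & ops$ref_len == 1L
    ops <- ops[!disc, , drop = FALSE]
  }
  within <- logical(nrow(ops))
  for (k in seq_len(nrow(ops))) {
    if (ops$kind[k] == "ins") {
      within[k] <- ops$ref_start[k] >= window$insertion_range[1] &&
        ops$ref_start[k] <= window$insertion_range[2]
    } else {
      within[k] <- ops$ref_start[k] < window$base_range[2] &&
        (ops$ref_start[k] + ops$ref_len[k]) > window$base_range[1]
    }
  }
  win_ops <- ops[within, , drop = FALSE]
  out_ops <- ops[!within, , drop = FALSE]
  artifact_subs <- sum(out_ops$kind == "sub")
  offwindow_indels <- sum(out_ops$kind != "sub")
  has_del <- any(win_ops$kind == "del")
  has_ins <- any(win_ops$kind == "ins")
  has_sub <- any(win_ops$kind == "sub")
  mutation_class <-
    if (has_del && has_ins) "deletion_plus_insertion"
    else if (has_del) "deletion"
    else if (has_ins) "insertion"
    else if (has_sub) "base_pair_exchange"
    else "WT"
  net_delta <- sum(nchar(win_ops$alt[win_ops$kind == "ins"])) -
    sum(win_ops$ref_len[win_ops$kind == "del"])
  structure(list(
    mutation_class = mutation_class,
    variant_key = variant_key(win_ops, window$cut_site),
    display_label = display_label(win_ops),
    net_delta = as.integer(net_delta),
    edited = mutation_class != "WT",
    artifact_subs = as.integer(artifact_subs),
    offwindow_indels = as.integer(offwindow_indels),
    within_ops = win_ops), class = "edit_call")
}

#' Filter, align and classify every read of a sample
#'
#' Composes the per-read pipeline: length/indicator filtering, global
#' alignment against both allele references, allele assignment, operation
#' canonicalization and editing-window classification. Identical read
#' sequences are aligned once and the result reused.
#'
#' @param reads A read-set data frame (see [read_sequences()]) or character
#'   vector of sequences.
#' @param refs Allele reference pair from [build_allele_references()].
#' @param window An [editing_window()].
#' @param params An [alignment_params()].
#' @param policy A [filter_policy()].
#' @param sample_id Sample label carried into the output.
#' @return A list of class `edit_calls` with a per-read `calls` data frame,
#'   an `accounting` list of totals, and any threshold `warnings`.
#' @export
call_sample <- function(reads, refs, window, params = alignment_params(),
                        policy = filter_policy(), sample_id = "sample") {
  if (is.character(reads))
    reads <- data.frame(read_id = sprintf("read%06d", seq_along(reads)),
                        sequence = toupper(reads), stringsAsFactors = FALSE)
  target <- refs$target
  non_target <- refs$non_target
  ref_len <- nchar(target$sequence)
  min_len <- policy$min_read_len %||% max(1L, ref_len - 30L)
  n <- nrow(reads)
  allele <- character(n)
  mutation_class <- character(n)
  key <- character(n)
  label <- character(n)
  net_delta <- integer(n)
  artifact_subs <- integer(n)
  offwindow_indels <- integer(n)
  score_t <- rep(NA_real_, n)
  score_n <- rep(NA_real_, n)
  passed <- logical(n)
  reason <- rep(NA_character_, n)
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    s <- toupper(reads$sequence[i])
    if (nchar(s) < min_len) {
      reason[i] <- "too_short"
      next
    }
    if (!passes_indicator_filter(s, target, policy)) {
      reason[i] <- "missing_indicator"
      next
    }
    passed[i] <- TRUE
    hit <- get0(s, envir = cache, inherits = FALSE)
    if (is.null(hit)) {
      asn <- assign_allele(s, target, non_target, params)
      chosen_ref <- if (asn$allele == "non_target") non_target else target
      ops <- normalize_ops(asn$alignment$ops, chosen_ref)
      call <- classify_read(ops, window,
                            variant_index = target$variant_index)
      hit <- list(asn = asn, call = call)
      assign(s, hit, envir = cache)
    }
    allele[i] <- hit$asn$allele
    score_t[i] <- hit$asn$score_target
    score_n[i] <- hit$asn$score_non_target
    mutation_class[i] <- hit$call$mutation_class
    key[i] <- hit$call$variant_key
    label[i] <- hit$call$display_label
    net_delta[i] <- hit$call$net_delta
    artifact_subs[i] <- hit$call$artifact_subs
    offwindow_indels[i] <- hit$call$offwindow_indels
  }
  allele[!passed] <- NA_character_
  mutation_class[!passed] <- NA_character_
  key[!passed] <- NA_character_
  label[!passed] <- NA_character_
  calls <- data.frame(read_id = reads$read_id, passed_filter = passed,
                      filter_reason = reason, allele = allele,
                      mutation_class = mutation_class, variant_key = key,
                      display_label = label, net_delta = net_delta,
                      artifact_subs = artifact_subs,
                      offwindow_indels = offwindow_indels,
                      score_target = score_t, score_non_target = score_n,
                      stringsAsFactors = FALSE)
  edited <- passed & mutation_class != "WT" & !is.na(mutation_class)
  accounting <- list(
    sample_id = sample_id,
    n_input = n,
    n_too_short = sum(reason == "too_short", na.rm = TRUE),
    n_missing_indicator = sum(reason == "missing_indicator", na.rm = TRUE),
    n_filtered = sum(passed),
    n_target = sum(passed & allele == "target", na.rm = TRUE),
    n_non_target = sum(passed & allele == "non_target", na.rm = TRUE),
    n_ambiguous = sum(passed & allele == "ambiguous", na.rm = TRUE),
    n_edited_target = sum(edited & allele == "target", na.rm = TRUE),
    n_edited_non_target = sum(edited & allele == "non_target", na.rm = TRUE),
    n_offwindow_indel = sum(passed & offwindow_indels > 0L),
    n_artifact_sub_reads = sum(passed & artifact_subs > 0L))
  warnings <- character(0)
  if (accounting$n_filtered < policy$min_reads_per_sample) {
    warnings <- sprintf(
      "sample %s: below %d filtered reads (%d) - estimates may be unstable",
      sample_id, policy$min_reads_per_sample, accounting$n_filtered)
    warning(warnings, call. = FALSE)
  }
  structure(list(calls = calls, accounting = accounting,
                 warnings = warnings, sample_id = sample_id),
            class = "edit_calls")
}

#' @export
print.edit_calls <- function(x, ...) {
  a <- x$accounting
  cat(sprintf("edit calls for %s: %d reads, %d filtered (%d target / %d non-target / %d ambiguous), %d edited target\n",
              a$sample_id, a$n_input, a$n_filtered, a$n_target,
              a$n_non_target, a$n_ambiguous, a$n_edited_target))
  invisible(x)
}
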