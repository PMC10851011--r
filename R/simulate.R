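#' Built-in synthetic demonstration locus
#'
#' A fully synthetic diploid amplicon emulating an allele-specific editing
#' experiment at a deep-intronic cryptic splice variant: an 81-nt window
#' whose centre base (0-based index 40) is C on the non-target allele and T
#' on the target allele, where the T completes a strong cryptic donor motif
#' (`CAG|GTAAGT`); a 20-nt guide whose protospacer covers the variant
#' (making it allele-specific) with an NGG PAM placing the blunt cut 6
#' bases downstream of the variant. No real genomic sequence is used.
#'
#' @return A list with `variant` ([variant_spec()]), `guide`
#'   ([guide_spec()]), `refs` (allele-reference pair) and `window`
#'   ([editing_window()]).
#' @export
demo_locus <- function() {
  context <- paste0("TCTTTATCAAGCCACAGCCTATATTCGGCACGGCCACAGGCAAGT",
                    "GCACCGGGTCAGCGGCTTGGAGTTAGGGTCACGTGC")
  variant <- variant_spec(label = "demo C>T", context = context,
                          variant_index = 40L, ref_base = "C",
                          alt_base = "T", flank = 40L)
  guide <- guide_spec(name = "guide demo", protospacer = "ACGGCCACAGGTAAGTGCAC",
                      pam = "NGG", ortholog = "SpCas9", strand = "plus")
  refs <- build_allele_references(variant)
  window <- locate_cut_site(guide, refs$target)
  list(variant = variant, guide = guide, refs = refs, window = window)
}

#' Default simulated indel spectrum
#'
#' Four canonical outcomes concentrated at the cut site: a 9-base deletion
#' (probability 0.49), a 1-base adenosine insertion (0.27), a 1-base
#' thymidine insertion (0.12) and a 2-base deletion (0.12) - the archetypal
#' mix of one dominant microhomology-mediated deletion plus 1-bp
#' end-joining insertions that Cas9 editing produces at a single cut.
#'
#' @return Named numeric probability vector keyed by canonical variant key.
#' @export
default_spectrum <- function() {
  c("del|-4|9|" = 0.49, "ins|0|0|A" = 0.27, "ins|0|0|T" = 0.12,
    "del|-1|2|" = 0.12)
}

#' Configuration for the synthetic amplicon read generator
#'
#' @param refs Allele-reference pair ([build_allele_references()]).
#' @param window [editing_window()] the spectrum offsets refer to.
#' @param n_reads Number of reads to generate.
#' @param allele_share_target Fraction of reads drawn from the target
#'   allele (0.5 for a balanced diploid locus).
#' @param editing_rate Fraction of target-allele reads carrying an edit.
#' @param spectrum Named probability vector (canonical variant key ->
#'   probability, summing to 1); ops must lie within the editing window.
#' @param sub_error_rate Per-base substitution sequencing-error
#'   probability (default 0.001); errors fall uniformly on read positions
#'   not created by the injected variant.
#' @param seed Integer seed making the read set reproducible.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(refs, window, n_reads = 20000L,
                              allele_share_target = 0.5,
                              editing_rate = 0.3,
                              spectrum = default_spectrum(),
                              sub_error_rate = 0.001, seed = NULL) {
  if (abs(sum(spectrum) - 1) > 1e-9)
    stop_config("spectrum probabilities must sum to 1")
  if (any(spectrum < 0)) stop_config("spectrum probabilities must be >= 0")
  if (allele_share_target < 0 || allele_share_target > 1 ||
      editing_rate < 0 || editing_rate > 1 ||
      sub_error_rate < 0 || sub_error_rate > 1)
    stop_config("rates must lie in [0, 1]")
  target <- refs$target
  variants <- lapply(names(spectrum), function(key) {
    ops <- parse_variant_key(key, window$cut_site)
    ops <- normalize_ops(ops, target)
    within <- vapply(seq_len(nrow(ops)), function(k) {
      if (ops$kind[k] == "ins")
        ops$ref_start[k] >= window$insertion_range[1] &&
          ops$ref_start[k] <= window$insertion_range[2]
      else ops$ref_start[k] < window$base_range[2] &&
        ops$ref_start[k] + ops$ref_len[k] > window$base_range[1]
    }, TRUE)
    if (!all(within))
      stop_config("spectrum variant ", key, " lies outside the editing window")
    ops
  })
  keys <- vapply(variants, variant_key, "", cut_site = window$cut_site)
  spectrum <- setNames(as.numeric(spectrum), keys)
  structure(list(refs = refs, window = window,
                 n_reads = as.integer(n_reads),
                 allele_share_target = allele_share_target,
                 editing_rate = editing_rate, spectrum = spectrum,
                 variant_ops = setNames(variants, keys),
                 sub_error_rate = sub_error_rate, seed = seed),
            class = "simulation_config")
}

# pre-compute the error-free sequence and the editable-position mask
# (TRUE for read positions that originate from the reference) per outcome
build_outcome_templates <- function(cfg) {
  tpl <- list()
  mk <- function(name, ref_seq, ops) {
    seqv <- apply_edit_ops(ref_seq, ops)
    n <- nchar(ref_seq)
    keep <- rep(TRUE, n)
    repl_origin <- rep(TRUE, n)
    ins_at <- integer(n + 1L)
    for (k in seq_len(nrow(ops))) {
      s <- ops$ref_start[k]; l <- ops$ref_len[k]
      if (ops$kind[k] == "del") keep[(s + 1L):(s + l)] <- FALSE
      else if (ops$kind[k] == "sub") repl_origin[(s + 1L):(s + l)] <- FALSE
      else ins_at[s + 1L] <- ins_at[s + 1L] + nchar(ops$alt[k])
    }
    mask <- logical(0)
    for (p in seq_len(n)) {
      if (ins_at[p] > 0L) mask <- c(mask, rep(FALSE, ins_at[p]))
      if (keep[p]) mask <- c(mask, repl_origin[p])
    }
    if (ins_at[n + 1L] > 0L) mask <- c(mask, rep(FALSE, ins_at[n + 1L]))
    stopifnot(length(mask) == nchar(seqv))
    tpl[[name]] <<- list(sequence = seqv, mask = mask)
  }
  mk("non_target:WT", cfg$refs$non_target$sequence, empty_ops())
  mk("target:WT", cfg$refs$target$sequence, empty_ops())
  for (key in names(cfg$variant_ops))
    mk(paste0("target:", key), cfg$refs$target$sequence,
       cfg$variant_ops[[key]])
  tpl
}

#' Simulate an amplicon read set with known ground truth
#'
#' For each read: the allele of origin is Bernoulli(`allele_share_target`);
#' target-allele reads are edited with probability `editing_rate`, the
#' outcome drawn from the spectrum; substitution sequencing errors are
#' injected per base at `sub_error_rate` on positions not created by the
#' variant. Qualities are constant Q30 (classification ignores them). The
#' output is deterministic given the seed.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `reads` (read-set data frame: `read_id`, `sequence`,
#'   `quality`) and `truth` (`read_id`, `true_allele`, `true_key`,
#'   `n_injected_errors`).
#' @export
simulate_reads <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  tpl <- build_outcome_templates(cfg)
  with_seed(cfg$seed, {
    n <- cfg$n_reads
    is_target <- runif(n) < cfg$allele_share_target
    edited <- is_target & (runif(n) < cfg$editing_rate)
    keys <- rep("WT", n)
    if (any(edited)) {
      draws <- sample(names(cfg$spectrum), sum(edited), replace = TRUE,
                      prob = cfg$spectrum)
      keys[edited] <- draws
    }
    outcome <- paste0(ifelse(is_target, "target", "non_target"), ":", keys)
    seqs <- vapply(tpl[outcome], `[[`, "", "sequence")
    nerr <- integer(n)
    if (cfg$sub_error_rate > 0) {
      n_editable <- vapply(tpl[outcome], function(t) sum(t$mask), 0L)
      nerr <- rbinom(n, n_editable, cfg$sub_error_rate)
      for (i in which(nerr > 0L)) {
        t <- tpl[[outcome[i]]]
        editable <- which(t$mask)
        pos <- if (length(editable) == 1L) editable
          else sample(editable, nerr[i])
        chars <- seq_chars(seqs[i])
        for (p in pos)
          chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
        seqs[i] <- paste(chars, collapse = "")
      }
    }
    reads <- data.frame(read_id = sprintf("read%06d", seq_len(n)),
                        sequence = unname(seqs),
                        quality = strrep("?", nchar(seqs)),  # Q30
                        stringsAsFactors = FALSE)
    truth <- data.frame(read_id = reads$read_id,
                        true_allele = ifelse(is_target, "target",
                                             "non_target"),
                        true_key = keys,
                        n_injected_errors = nerr,
                        stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  })
}

#' Compare pipeline calls against simulation ground truth
#'
#' @param truth Truth table from [simulate_reads()].
#' @param calls An `edit_calls` object (or its `calls` data frame) produced
#'   on the same reads.
#' @return A list of class `recovery_summary`: per-read agreement rates on
#'   allele and variant key (over reads passing the filter), the estimated
#'   vs true editing efficiency, and per-key spectrum deltas.
#' @export
evaluate_recovery <- function(truth, calls) {
  df <- if (inherits(calls, "edit_calls")) calls$calls else calls
  if (is.null(truth) || nrow(truth) == 0L) stop_input("empty truth table")
  if (!setequal(truth$read_id, df$read_id))
    stop_input("read id mismatch between truth and calls")
  m <- merge(truth, df, by = "read_id", sort = FALSE)
  p <- m[m$passed_filter, , drop = FALSE]
  allele_acc <- 100 * mean(p$allele == p$true_allele)
  edited_truth <- p[p$true_key != "WT" & p$true_allele == "target", ,
                    drop = FALSE]
  key_acc <- if (nrow(edited_truth))
    100 * mean(edited_truth$variant_key == edited_truth$true_key &
               edited_truth$allele == "target") else NA_real_
  tgt <- p[p$true_allele == "target", , drop = FALSE]
  true_eff <- 100 * mean(tgt$true_key != "WT")
  est_tgt <- p[p$allele == "target", , drop = FALSE]
  est_eff <- 100 * mean(est_tgt$mutation_class != "WT")
  true_spec <- 100 * prop.table(table(edited_truth$true_key))
  called_edit <- p[p$allele == "target" & p$mutation_class != "WT", ,
                   drop = FALSE]
  est_spec <- 100 * prop.table(table(called_edit$variant_key))
  keys <- sort(union(names(true_spec), names(est_spec)))
  spec_delta <- data.frame(
    variant_key = keys,
    true_pct = as.numeric(true_spec[keys]),
    est_pct = as.numeric(est_spec[keys]),
    stringsAsFactors = FALSE)
  spec_delta[is.na(spec_delta)] <- 0
  spec_delta$delta <- spec_delta$est_pct - spec_delta$true_pct
  structure(list(n_passed = nrow(p),
                 allele_accuracy = allele_acc,
                 variant_key_accuracy = key_acc,
                 true_efficiency_within_target = true_eff,
                 est_efficiency_within_target = est_eff,
                 efficiency_delta = est_eff - true_eff,
                 spectrum = spec_delta),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("recovery over %d filtered reads: allele accuracy %.2f%%, variant-key accuracy %s, efficiency %.2f%% (true %.2f%%)\n",
              x$n_passed, x$allele_accuracy,
              if (is.na(x$variant_key_accuracy)) "NA"
              else sprintf("%.2f%%", x$variant_key_accuracy),
              x$est_efficiency_within_target,
              x$true_efficiency_within_target))
  invisible(x)
}
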