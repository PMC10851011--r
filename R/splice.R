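#' Reconstruct the post-edit allele sequence for an indel variant
#'
#' Converts a canonical variant key (offsets relative to the cut site) back
#' into absolute edit operations and applies them to the target allele
#' reference, giving the sequence a cell carries after acquiring that
#' editing outcome.
#'
#' @param target Target `allele_reference` (or plain sequence).
#' @param variant Canonical variant key (e.g. `"del|-4|9|"`) or an edit-op
#'   data frame with absolute coordinates; `"WT"` returns the reference.
#' @param cut_site Cut-site coordinate used to resolve key offsets
#'   (required when `variant` is a key).
#' @return The reconstructed nucleotide sequence.
#' @export
reconstruct_variant_sequence <- function(target, variant, cut_site = NULL) {
  ref_seq <- as_ref_sequence(target)
  ops <- if (is.character(variant)) {
    if (identical(variant, "WT")) empty_ops()
    else parse_variant_key(variant, cut_site)
  } else variant
  apply_edit_ops(ref_seq, ops)
}

#' Parse a canonical variant key into edit operations
#'
#' @param key Canonical key, fields `kind|offset|ref_len|alt` joined by `;`.
#' @param cut_site Cut-site coordinate the offsets are relative to.
#' @return An edit-op data frame with absolute reference coordinates.
#' @export
parse_variant_key <- function(key, cut_site) {
  if (is.null(cut_site)) stop_input("cut_site required to resolve a variant key")
  if (identical(key, "WT")) return(empty_ops())
  parts <- strsplit(key, ";", fixed = TRUE)[[1]]
  rows <- lapply(parts, function(p) {
    f <- strsplit(p, "|", fixed = TRUE)[[1]]
    if (length(f) < 3L || !f[1] %in% c("sub", "del", "ins"))
      stop_input("unparseable variant key component: ", p)
    data.frame(kind = f[1],
               ref_start = as.integer(f[2]) + as.integer(cut_site),
               ref_len = as.integer(f[3]),
               alt = if (length(f) >= 4L) f[4] else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Train a position weight matrix donor-site scorer
#'
#' Builds per-position log-odds weights
#' `log2(((count + 0.5) / (N + 2)) / background)` from aligned donor-site
#' training sequences (pseudocount 0.5 per base).
#'
#' @param donor_site_seqs Character vector of at least 10 equal-width
#'   A/C/G/T training sequences covering the exon|intron boundary
#'   (conventionally positions -3..+6 for a width of 9).
#' @param background Per-base background frequencies (A, C, G, T); uniform
#'   by default.
#' @return An object of class `splice_pwm` with the weight matrix (rows
#'   A/C/G/T, one column per motif position).
#' @export
train_pwm <- function(donor_site_seqs, background = rep(0.25, 4)) {
  seqs <- toupper(donor_site_seqs)
  if (length(seqs) < 10L) stop_input("need at least 10 training sites")
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop_input("training sites must all have the same width")
  if (w < 4L) stop_input("motif width must be >= 4")
  if (!all(is_acgt(seqs))) stop_input("training sites must be A/C/G/T only")
  if (length(background) != 4L || any(background <= 0))
    stop_input("background must be four positive frequencies")
  background <- background / sum(background)
  names(background) <- DNA_BASES
  mat <- do.call(rbind, strsplit(seqs, ""))
  counts <- vapply(seq_len(w), function(j)
    vapply(DNA_BASES, function(b) sum(mat[, j] == b), 0L), integer(4))
  n <- length(seqs)
  freq <- (counts + 0.5) / (n + 2)
  weights <- log2(freq / background)
  rownames(weights) <- DNA_BASES
  colnames(weights) <- seq_len(w)
  structure(list(kind = "pwm_logodds", weights = weights, motif_width = w,
                 background = background, n_train = n),
            class = "splice_pwm")
}

#' Built-in donor-site position weight matrix
#'
#' A log-odds scorer for the canonical mammalian U2 donor motif (positions
#' -3..+6 across the exon|intron boundary, consensus MAG|GTRAGT), built
#' from the classic donor-site base composition against a uniform
#' background. Serves as a desk-scale stand-in for external splice-score
#' predictions; any monotone splice-score comparator can replace it via
#' [external_splice_scores()].
#'
#' @return An object of class `splice_pwm` of motif width 9.
#' @export
donor_pwm <- function() {
  freq <- matrix(c(
    # A     C     G     T      (position)
    0.35, 0.36, 0.18, 0.11,   # -3
    0.60, 0.13, 0.13, 0.14,   # -2
    0.09, 0.03, 0.80, 0.08,   # -1
    0.004, 0.004, 0.988, 0.004, # +1 (G of the GT core)
    0.004, 0.008, 0.004, 0.984, # +2 (T of the GT core)
    0.59, 0.03, 0.35, 0.03,   # +3
    0.71, 0.08, 0.12, 0.09,   # +4
    0.06, 0.06, 0.82, 0.06,   # +5
    0.15, 0.17, 0.19, 0.49),  # +6
    nrow = 4)
  weights <- log2(freq / 0.25)
  rownames(weights) <- DNA_BASES
  colnames(weights) <- seq_len(ncol(weights))
  structure(list(kind = "pwm_logodds", weights = weights,
                 motif_width = ncol(weights),
                 background = setNames(rep(0.25, 4), DNA_BASES),
                 n_train = NA_integer_),
            class = "splice_pwm")
}

#' Externally computed splice scores keyed by variant
#'
#' Wraps a table of splice scores produced by an external predictor into
#' the model interface used by [classify_splice_impact()]. The mapping must
#' cover the reserved keys `"WT"` (unedited reference allele) and
#' `"pathological"` (variant-carrying allele).
#'
#' @param x A two-column data frame (`variant_key`, `score`) or a path to a
#'   TSV with those columns.
#' @return An object of class `splice_scores`.
#' @export
external_splice_scores <- function(x) {
  tab <- if (is.character(x)) read.delim(x, header = TRUE, sep = "\t",
                                         stringsAsFactors = FALSE) else x
  if (!all(c("variant_key", "score") %in% names(tab)))
    stop_input("external scores need variant_key and score columns")
  scores <- setNames(as.numeric(tab$score), tab$variant_key)
  if (!all(c("WT", "pathological") %in% names(scores)))
    stop_input("external scores must cover the WT and pathological contexts")
  if (any(!is.finite(scores))) stop_input("scores must be finite")
  structure(list(kind = "external_scores", scores = scores),
            class = "splice_scores")
}

#' Scan a sequence for the best-scoring donor site
#'
#' Slides the motif over a search interval and returns the best (leftmost
#' maximal) start position and its log-odds score.
#'
#' @param sequence Nucleotide sequence to scan.
#' @param model A `splice_pwm`.
#' @param search_interval 0-based half-open interval of candidate motif
#'   start positions, or `NULL` for the whole sequence.
#' @return A list with `pos` (0-based motif start), `score` and the full
#'   `scores` vector over the interval.
#' @export
score_donor_sites <- function(sequence, model, search_interval = NULL) {
  stopifnot(inherits(model, "splice_pwm"))
  sequence <- toupper(as_ref_sequence(sequence))
  w <- model$motif_width
  n <- nchar(sequence)
  if (is.null(search_interval)) search_interval <- c(0L, n)
  lo <- max(0L, as.integer(search_interval[1]))
  hi <- min(n, as.integer(search_interval[2]))
  if (hi - lo < w) stop_input("search interval shorter than the motif")
  starts <- lo:(hi - w)
  chars <- seq_chars(sequence)
  idx <- match(chars, DNA_BASES)
  scores <- vapply(starts, function(s) {
    cols <- idx[(s + 1L):(s + w)]
    if (anyNA(cols)) return(-Inf)
    sum(model$weights[cbind(cols, seq_len(w))])
  }, 0)
  best <- which.max(scores)
  list(pos = starts[best], score = scores[best],
       scores = setNames(scores, starts))
}

#' Classify the splice impact of every variant in a spectrum
#'
#' Reconstructs the post-edit target-allele sequence for each spectrum
#' variant, scores its best cryptic donor site, and compares it against the
#' pathological (variant-carrying) and wild-type allele scores: a variant
#' is `disrupting` when its best score falls below the wild-type score plus
#' `margin_disrupt`, `enhancing` when it reaches the pathological score
#' minus `margin_enhance`, and `neutral` otherwise. Also reports the
#' spectrum-weighted fraction of disrupting outcomes.
#'
#' @param spectrum An `editing_profile` or named percentage vector keyed by
#'   canonical variant key.
#' @param target,non_target The allele-reference pair; the target carries
#'   the pathological (cryptic-donor-creating) base.
#' @param model A `splice_pwm` (default [donor_pwm()]) or
#'   [external_splice_scores()].
#' @param cut_site Cut-site coordinate used to resolve variant keys.
#' @param search_interval Donor-site search interval passed to
#'   [score_donor_sites()]; defaults to the whole sequence.
#' @param margin_disrupt,margin_enhance Score margins for the category
#'   boundaries (both 0 by default: disrupting is strictly below wild type,
#'   enhancing at or above pathological).
#' @return An object of class `splice_impact` with a per-variant verdict
#'   table, the reference scores and `fraction_disrupting` (percent,
#'   spectrum-weighted).
#' @export
classify_splice_impact <- function(spectrum, target, non_target,
                                   model = donor_pwm(), cut_site = NULL,
                                   search_interval = NULL,
                                   margin_disrupt = 0, margin_enhance = 0) {
  weights <- as_spectrum(spectrum)
  external <- inherits(model, "splice_scores")
  if (!external && !inherits(model, "splice_pwm"))
    stop_input("model must be a splice_pwm or splice_scores object")
  if (external) {
    score_path <- model$scores[["pathological"]]
    score_wt <- model$scores[["WT"]]
    get_score <- function(key) {
      if (!key %in% names(model$scores))
        stop_input("no external score for variant ", key)
      model$scores[[key]]
    }
  } else {
    score_path <- score_donor_sites(target, model, search_interval)$score
    score_wt <- score_donor_sites(non_target, model, search_interval)$score
    get_score <- function(key) {
      seq <- reconstruct_variant_sequence(target, key, cut_site)
      score_donor_sites(seq, model, search_interval)$score
    }
  }
  keys <- names(weights)
  scores <- vapply(keys, get_score, 0)
  category <- ifelse(scores < score_wt + margin_disrupt, "disrupting",
              ifelse(scores >= score_path - margin_enhance, "enhancing",
                     "neutral"))
  verdicts <- data.frame(variant_key = keys, weight_pct = unname(weights),
                         best_donor_score = unname(scores),
                         category = category, stringsAsFactors = FALSE)
  frac <- 100 * sum(weights[category == "disrupting"]) / sum(weights)
  structure(list(verdicts = verdicts, score_pathological = score_path,
                 score_wt = score_wt, fraction_disrupting = frac),
            class = "splice_impact")
}

#' @export
print.splice_impact <- function(x, ...) {
  cat(sprintf("splice impact: pathological score %.2f, WT score %.2f; %.1f%% of edits disrupting\n",
              x$score_pathological, x$score_wt, x$fraction_disrupting))
  print(x$verdicts)
  invisible(x)
}
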