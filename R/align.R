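#' Affine-gap alignment scoring parameters
#'
#' Defaults (+2 match, -3 mismatch, -8 gap open, -1 gap extend) prefer one
#' long gap over scattered mismatches, matching the dominant single-indel
#' outcomes of Cas9 editing. A gap of length L costs
#' `gap_open + (L - 1) * gap_extend`. End gaps are penalized by default
#' because reads qualifying as full-length amplicons span the whole
#' reference window; `"free_ends"` leaves leading/trailing gaps unpenalized
#' for truncated-read experiments.
#'
#' @param match,mismatch,gap_open,gap_extend Alignment scores; must satisfy
#'   `gap_open <= gap_extend <= 0 <= match` and `mismatch < 0`.
#' @param end_gap_policy `"penalized"` or `"free_ends"`.
#' @return An object of class `alignment_params`.
#' @export
alignment_params <- function(match = 2, mismatch = -3, gap_open = -8,
                             gap_extend = -1,
                             end_gap_policy = c("penalized", "free_ends")) {
  end_gap_policy <- match.arg(end_gap_policy)
  if (!(gap_open <= gap_extend && gap_extend <= 0 && 0 <= match))
    stop_config("require gap_open <= gap_extend <= 0 <= match")
  if (!(mismatch < 0)) stop_config("mismatch must be negative")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, end_gap_policy = end_gap_policy),
            class = "alignment_params")
}

empty_ops <- function() {
  data.frame(kind = character(0), ref_start = integer(0),
             ref_len = integer(0), alt = character(0),
             stringsAsFactors = FALSE)
}

as_ref_sequence <- function(ref) {
  if (inherits(ref, "allele_reference")) ref$sequence else toupper(as.character(ref))
}

#' Globally align a read against a reference with affine gap penalties
#'
#' Needleman-Wunsch/Gotoh global alignment with a deterministic traceback
#' (diagonal preferred over deletion over insertion on score ties). The
#' returned edit operations use 0-based reference coordinates; insertion
#' positions are inter-base. Substitutions are reported per base;
#' [normalize_ops()] reduces indels to their canonical left-shifted form.
#'
#' @param read A read sequence (character) or a row of a read set.
#' @param ref An `allele_reference` or plain character reference sequence.
#' @param params An [alignment_params()].
#' @return A list of class `edit_alignment` with `score`, `ops` (data frame
#'   `kind`/`ref_start`/`ref_len`/`alt`) and `aligned_span` (0-based,
#'   half-open reference interval covered by the read).
#' @examples
#' global_align("ACGT", "ACGGT")$ops     # one 1-base deletion
#' @export
global_align <- function(read, ref, params = alignment_params()) {
  read_seq <- if (is.list(read) || is.data.frame(read)) read$sequence else read
  read_seq <- toupper(as.character(read_seq))
  ref_seq <- as_ref_sequence(ref)
  if (is.na(read_seq) || nchar(read_seq) == 0L) stop_input("empty read")
  if (nchar(ref_seq) == 0L) stop_input("empty reference")
  res <- .ampedit_align_cpp(ref_seq, read_seq, params$match, params$mismatch,
                            params$gap_open, params$gap_extend,
                            params$end_gap_policy == "free_ends")
  ops <- data.frame(kind = as.character(res$kind),
                    ref_start = as.integer(res$ref_start),
                    ref_len = as.integer(res$ref_len),
                    alt = as.character(res$alt),
                    stringsAsFactors = FALSE)
  structure(list(score = res$score, ops = ops,
                 aligned_span = as.integer(res$span)),
            class = "edit_alignment")
}

#' Apply edit operations to a reference sequence
#'
#' Reconstructs the read (or post-edit allele sequence) implied by a set of
#' non-overlapping edit operations.
#'
#' @param ref Reference sequence or `allele_reference`.
#' @param ops Edit-operation data frame as produced by [global_align()].
#' @return The edited sequence (character scalar).
#' @export
apply_edit_ops <- function(ref, ops) {
  ref_seq <- as_ref_sequence(ref)
  n <- nchar(ref_seq)
  if (nrow(ops) == 0L) return(ref_seq)
  bad <- ops$ref_start < 0L | (ops$ref_start + ops$ref_len) > n |
    (ops$kind == "ins" & ops$ref_start > n)
  if (any(bad)) stop_input("edit operation outside reference bounds")
  chars <- seq_chars(ref_seq)
  keep <- rep(TRUE, n)
  repl <- chars
  ins_at <- vector("list", n + 1L)   # insertions before 0-based position p
  for (k in seq_len(nrow(ops))) {
    kind <- ops$kind[k]
    s <- ops$ref_start[k]
    l <- ops$ref_len[k]
    if (kind == "del") {
      keep[(s + 1L):(s + l)] <- FALSE
    } else if (kind == "sub") {
      repl[(s + 1L):(s + l)] <- seq_chars(ops$alt[k])
    } else if (kind == "ins") {
      ins_at[[s + 1L]] <- c(ins_at[[s + 1L]], ops$alt[k])
    } else stop_internal("unknown op kind: ", kind)
  }
  out <- character(0)
  for (p in seq_len(n)) {
    if (!is.null(ins_at[[p]])) out <- c(out, ins_at[[p]])
    if (keep[p]) out <- c(out, repl[p])
  }
  if (!is.null(ins_at[[n + 1L]])) out <- c(out, ins_at[[n + 1L]])
  paste(out, collapse = "")
}

# left-shift a single deletion to its leftmost equivalent position
shift_del_left <- function(chars, start, len) {
  while (start > 0L && chars[start] == chars[start + len]) start <- start - 1L
  start
}

# left-shift an insertion (inter-base position, inserted string) leftwards
shift_ins_left <- function(chars, pos, alt) {
  a <- seq_chars(alt)
  L <- length(a)
  while (pos > 0L && chars[pos] == a[L]) {
    a <- c(chars[pos], a[-L])
    pos <- pos - 1L
  }
  list(pos = pos, alt = paste(a, collapse = ""))
}

#' Canonicalize edit operations by left-alignment
#'
#' Shifts every insertion and deletion to its leftmost equivalent position
#' (left-alignment in repeat context), merges adjacent compatible operations,
#' and sorts by reference position, yielding the unique canonical
#' representative of the edit-equivalence class. Substitutions are kept
#' per base. The result is idempotent and independent of which optimal
#' alignment produced the raw operations.
#'
#' @param ops Edit-operation data frame.
#' @param ref Reference sequence or `allele_reference` the ops refer to.
#' @return A canonical edit-operation data frame.
#' @examples
#' ops <- data.frame(kind = "del", ref_start = 3L, ref_len = 1L, alt = "",
#'                   stringsAsFactors = FALSE)
#' normalize_ops(ops, "CAAAG")  # deletion shifted to the first A
#' @export
normalize_ops <- function(ops, ref) {
  ref_seq <- as_ref_sequence(ref)
  chars <- seq_chars(ref_seq)
  if (nrow(ops) == 0L) return(empty_ops())
  check_overlap <- function(o) {
    oo <- o[o$kind != "ins", , drop = FALSE]
    if (nrow(oo) > 1L) {
      oo <- oo[order(oo$ref_start), , drop = FALSE]
      if (any(oo$ref_start[-1L] < (oo$ref_start + oo$ref_len)[-nrow(oo)]))
        stop_internal("overlapping edit operations")
    }
  }
  check_overlap(ops)
  cur <- ops
  repeat {
    nxt <- cur
    for (k in seq_len(nrow(nxt))) {
      if (nxt$kind[k] == "del") {
        nxt$ref_start[k] <- shift_del_left(chars, nxt$ref_start[k], nxt$ref_len[k])
      } else if (nxt$kind[k] == "ins") {
        s <- shift_ins_left(chars, nxt$ref_start[k], nxt$alt[k])
        nxt$ref_start[k] <- s$pos
        nxt$alt[k] <- s$alt
      }
    }
    nxt <- nxt[order(nxt$ref_start, match(nxt$kind, c("del", "ins", "sub")),
                     nxt$alt), , drop = FALSE]
    # merge adjacent compatible ops
    merged <- nxt[0, , drop = FALSE]
    for (k in seq_len(nrow(nxt))) {
      row <- nxt[k, , drop = FALSE]
      j <- nrow(merged)
      if (j > 0L) {
        last <- merged[j, , drop = FALSE]
        if (row$kind == "del" && last$kind == "del" &&
            last$ref_start + last$ref_len == row$ref_start) {
          merged$ref_len[j] <- last$ref_len + row$ref_len
          next
        }
        if (row$kind == "ins" && last$kind == "ins" &&
            last$ref_start == row$ref_start) {
          merged$alt[j] <- paste0(last$alt, row$alt)
          next
        }
      }
      merged <- rbind(merged, row)
    }
    rownames(merged) <- NULL
    if (identical(merged, cur)) break
    cur <- merged
  }
  cur
}

#' Assign a read to its allele of origin
#'
#' Aligns the read against both allele references and assigns it to the
#' higher-scoring one. On a score tie the base aligned opposite the
#' discriminating position decides (alternate base: target, reference base:
#' non-target); if that base is deleted, or matches neither allele, the read
#' is `"ambiguous"`.
#'
#' @param read Read sequence (character) or read-set row.
#' @param target,non_target The `allele_reference` pair from
#'   [build_allele_references()].
#' @param params An [alignment_params()].
#' @return A list with `allele` (`"target"`, `"non_target"` or
#'   `"ambiguous"`), `alignment` (the [global_align()] result against the
#'   chosen reference, or the target if ambiguous), and both scores.
#' @export
assign_allele <- function(read, target, non_target,
                          params = alignment_params()) {
  aln_t <- global_align(read, target, params)
  aln_n <- global_align(read, non_target, params)
  vi <- target$variant_index
  if (aln_t$score > aln_n$score) {
    allele <- "target"
  } else if (aln_n$score > aln_t$score) {
    allele <- "non_target"
  } else {
    base <- read_base_at(aln_t$ops, target, vi)
    allele <- if (is.na(base)) "ambiguous"
      else if (base == target$discriminating_base) "target"
      else if (base == non_target$discriminating_base) "non_target"
      else "ambiguous"
  }
  aln <- switch(allele, non_target = aln_n, aln_t)
  list(allele = allele, alignment = aln,
       score_target = aln_t$score, score_non_target = aln_n$score)
}

# the read base aligned opposite reference position `pos`, NA if deleted
read_base_at <- function(ops, ref, pos) {
  ref_seq <- as_ref_sequence(ref)
  for (k in seq_len(nrow(ops))) {
    s <- ops$ref_start[k]
    l <- ops$ref_len[k]
    if (ops$kind[k] == "del" && pos >= s && pos < s + l) return(NA_character_)
    if (ops$kind[k] == "sub" && pos >= s && pos < s + l)
      return(substr(ops$alt[k], pos - s + 1L, pos - s + 1L))
  }
  substr(ref_seq, pos + 1L, pos + 1L)
}

#' @export
print.edit_alignment <- function(x, ...) {
  cat(sprintf("global alignment: score %g, %d edit op(s), span [%d, %d)\n",
              x$score, nrow(x$ops), x$aligned_span[1], x$aligned_span[2]))
  if (nrow(x$ops)) print(x$ops)
  invisible(x)
}
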