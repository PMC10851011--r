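#' Quantify allele-specific editing outcomes in an amplicon sample
#'
#' The front door of the package: takes merged amplicon reads plus the
#' variant and guide specification, and fits the per-sample editing
#' profile - read accounting, allele-specific editing efficiencies and the
#' canonical indel spectrum. Internally the reads are filtered
#' (length + indicator sequences), globally aligned against both allele
#' references with affine gap penalties, assigned an allele of origin,
#' left-normalized and classified against the editing window.
#'
#' @param reads A read-set data frame (see [read_sequences()]), a character
#'   vector of sequences, or a path to a FASTA/FASTQ file.
#' @param variant A [variant_spec()].
#' @param guide A [guide_spec()].
#' @param params [alignment_params()].
#' @param policy [filter_policy()].
#' @param half_width Editing-window half width in bases (default 5).
#' @param sample_id Sample label.
#' @return An object of class `editing_profile` supporting `print()`,
#'   `summary()`, `coef()` (the three editing percentages), `plot()`
#'   (spectrum barplot) and `simulate()` (parametric resampling of read
#'   sets from the fitted profile).
#' @examples
#' locus <- demo_locus()
#' sim <- simulate_reads(simulation_config(locus$refs, locus$window,
#'                                         n_reads = 300, seed = 7))
#' fit <- quantify_editing(sim$reads, locus$variant, locus$guide,
#'                         policy = filter_policy(min_reads_per_sample = 100))
#' coef(fit)
#' @export
quantify_editing <- function(reads, variant, guide,
                             params = alignment_params(),
                             policy = filter_policy(), half_width = 5L,
                             sample_id = "sample") {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_sequences(reads)
  refs <- build_allele_references(variant)
  window <- locate_cut_site(guide, refs$target, half_width = half_width)
  calls <- call_sample(reads, refs, window, params = params,
                       policy = policy, sample_id = sample_id)
  profile <- summarize_calls(calls)
  profile$config <- list(variant = unclass(variant),
                         guide = unclass(guide),
                         params = unclass(params),
                         policy = unclass(policy),
                         half_width = as.integer(half_width),
                         cut_site = window$cut_site)
  profile$refs <- refs
  profile$window <- window
  profile
}

#' @export
print.editing_profile <- function(x, ...) {
  a <- x$counts
  cat(sprintf("editing profile for sample '%s'\n", x$sample_id))
  cat(sprintf("  reads: %d input, %d filtered (%d target, %d non-target, %d ambiguous)\n",
              a$n_input, a$n_filtered, a$n_target, a$n_non_target,
              a$n_ambiguous))
  fmtp <- function(p) if (is.na(p)) "." else sprintf("%.1f%%", p)
  cat(sprintf("  editing efficiency: %s of all alleles, %s within the target allele\n",
              fmtp(x$efficiency_all_alleles),
              fmtp(x$efficiency_within_target)))
  cat(sprintf("  non-target editing: %s\n", fmtp(x$non_target_editing)))
  if (nrow(x$spectrum)) {
    cat("  top indel variants (% of edited target reads):\n")
    top <- head(x$spectrum, 5L)
    for (i in seq_len(nrow(top)))
      cat(sprintf("    %-12s %6.1f%%  (n = %d)\n", top$display_label[i],
                  top$pct_edited[i], top$count[i]))
  }
  if (length(x$warnings)) cat("  warning:", x$warnings, "\n")
  invisible(x)
}

#' @export
summary.editing_profile <- function(object, ...) {
  cls <- object$calls
  passed <- cls[cls$passed_filter, , drop = FALSE]
  class_tab <- table(allele = passed$allele, class = passed$mutation_class)
  structure(list(profile = object, class_table = class_tab,
                 implied_cells = implied_cell_fraction(
                   max(0, min(100, object$efficiency_all_alleles %||% 0,
                              na.rm = TRUE)))),
            class = "summary.editing_profile")
}

#' @export
print.summary.editing_profile <- function(x, ...) {
  print(x$profile)
  cat("\nmutation classes by allele:\n")
  print(x$class_table)
  cat(sprintf("\nimplied edited-cell fraction (diploid, single targeted allele): %.1f%%\n",
              x$implied_cells))
  invisible(x)
}

#' @export
coef.editing_profile <- function(object, ...) {
  c(efficiency_all_alleles = object$efficiency_all_alleles,
    efficiency_within_target = object$efficiency_within_target,
    non_target_editing = object$non_target_editing)
}

#' @export
plot.editing_profile <- function(x, n_top = 10L, ...) {
  sp <- head(x$spectrum, n_top)
  if (nrow(sp) == 0L) {
    warning("no edited reads to plot", call. = FALSE)
    return(invisible(x))
  }
  graphics::barplot(sp$pct_edited, names.arg = sp$display_label,
                    las = 2, ylab = "% of edited target reads",
                    main = sprintf("indel spectrum: %s", x$sample_id), ...)
  invisible(x)
}

#' Parametric resampling of read sets from a fitted editing profile
#'
#' Draws new synthetic read sets whose allele share, editing rate and indel
#' spectrum equal the fitted estimates - a parametric bootstrap of the
#' sequencing experiment.
#'
#' @param object A fitted `editing_profile` (from [quantify_editing()],
#'   which stores the reference pair and window).
#' @param nsim Number of read sets to draw.
#' @param seed Integer seed.
#' @param n_reads Reads per set (defaults to the fitted filtered count).
#' @param ... Unused.
#' @return A list of `nsim` simulation results (each as in
#'   [simulate_reads()]).
#' @export
simulate.editing_profile <- function(object, nsim = 1, seed = NULL,
                                     n_reads = NULL, ...) {
  if (is.null(object$refs) || is.null(object$window))
    stop_input("profile lacks references; refit with quantify_editing()")
  a <- object$counts
  if (a$n_target == 0L || a$n_edited_target == 0L)
    stop_input("cannot resample from a profile without edited target reads")
  share <- a$n_target / (a$n_target + a$n_non_target)
  rate <- a$n_edited_target / a$n_target
  spec <- setNames(object$spectrum$count / sum(object$spectrum$count),
                   object$spectrum$variant_key)
  with_seed(seed, lapply(seq_len(nsim), function(k) {
    cfg <- simulation_config(object$refs, object$window,
                             n_reads = n_reads %||% a$n_filtered,
                             allele_share_target = share,
                             editing_rate = rate, spectrum = spec,
                             sub_error_rate = 0, seed = NULL)
    simulate_reads(cfg)
  }))
}
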