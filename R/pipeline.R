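#' Read a run configuration (YAML)
#'
#' A run configuration bundles the variant specification, the guide, the
#' alignment parameters, the filter policy and the editing-window half
#' width. All fields of `alignment` and `filter` are optional and default
#' to the package defaults. Coordinates are 0-based.
#'
#' @param path Path to a YAML file with blocks `variant` (label, context
#'   or context_fasta, variant_index, ref_base, alt_base, flank), `guide`
#'   (name, protospacer, pam, ortholog, strand, cut_offset), optional
#'   `alignment`, `filter` and `half_width`.
#' @return A list of class `run_config` with `variant`, `guide`, `params`,
#'   `policy`, `half_width`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  y <- yaml::read_yaml(path)
  v <- y$variant
  if (is.null(v)) stop_config("config lacks a variant block")
  context <- v$context
  if (is.null(context) && !is.null(v$context_fasta)) {
    fa <- read_sequences(v$context_fasta, format = "fasta")
    if (nrow(fa) < 1L) stop_config("context FASTA is empty")
    context <- fa$sequence[1]
  }
  variant <- variant_spec(label = v$label %||% "variant",
                          context = context,
                          variant_index = v$variant_index,
                          ref_base = v$ref_base, alt_base = v$alt_base,
                          flank = v$flank %||% 40L)
  g <- y$guide
  if (is.null(g)) stop_config("config lacks a guide block")
  guide <- guide_spec(name = g$name %||% "guide",
                      protospacer = g$protospacer, pam = g$pam,
                      ortholog = g$ortholog %||% "custom",
                      strand = g$strand %||% "plus",
                      cut_offset = g$cut_offset %||% 3L)
  al <- y$alignment %||% list()
  params <- alignment_params(match = al$match %||% 2,
                             mismatch = al$mismatch %||% -3,
                             gap_open = al$gap_open %||% -8,
                             gap_extend = al$gap_extend %||% -1,
                             end_gap_policy = al$end_gap_policy %||% "penalized")
  fl <- y$filter %||% list()
  policy <- filter_policy(
    indicator_len = fl$indicator_len %||% 15L,
    indicator_mode = fl$indicator_mode %||% "exact",
    min_reads_per_sample = fl$min_reads_per_sample %||% 10000L,
    min_read_len = fl$min_read_len)
  structure(list(variant = variant, guide = guide, params = params,
                 policy = policy, half_width = y$half_width %||% 5L),
            class = "run_config")
}

#' Quantify every sample of a sample sheet and write result tables
#'
#' Runs [quantify_editing()] per sample, writes the per-sample summary,
#' spectrum and JSON outputs, and - when two or more samples are present -
#' a replicate-concordance table.
#'
#' @param sheet A sample-sheet data frame ([read_sample_sheet()]) or path.
#' @param config A `run_config` ([read_run_config()]) or path.
#' @param out_dir Output directory.
#' @return A named list of `editing_profile` objects, invisibly; the
#'   concordance summary (if computed) is attached as attribute
#'   `"concordance"`.
#' @export
run_quantification <- function(sheet, config, out_dir) {
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  if (is.character(config)) config <- read_run_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  profiles <- list()
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]
    rp <- sheet$reads[i]
    if (!file.exists(rp)) stop_input("sample ", sid, ": reads file not found: ", rp)
    reads <- read_sequences(rp, format = sheet$format[i] %||% "auto")
    profiles[[sid]] <- quantify_editing(
      reads, config$variant, config$guide, params = config$params,
      policy = config$policy, half_width = config$half_width,
      sample_id = sid)
    write_profile_tables(profiles[[sid]], out_dir)
  }
  out <- profiles
  if (length(profiles) >= 2L) {
    ok <- vapply(profiles, function(p) nrow(p$spectrum) > 0L, TRUE)
    if (sum(ok) >= 2L) {
      conc <- replicate_concordance(profiles[ok])
      write.table(conc$pairs, file.path(out_dir, "replicate_concordance.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      attr(out, "concordance") <- conc
    }
  }
  invisible(out)
}
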