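#' Describe a heterozygous single-nucleotide variant in its genomic context
#'
#' A `variant_spec` pins down the discriminating single-base difference
#' between the two alleles of a diploid amplicon: a genomic context sequence,
#' the 0-based index of the variant within it, the reference and alternate
#' bases, and the flank width kept on each side when building the allele
#' reference pair (40 bp by default, giving an 81-nt reference window).
#'
#' @param label Free-text display label, e.g. an HGVS name. Display-only.
#' @param context Nucleotide string (A/C/G/T) containing the variant site.
#' @param variant_index 0-based index of the variant within `context`.
#' @param ref_base,alt_base Single reference/alternate nucleotides; the
#'   context must carry `ref_base` at `variant_index`.
#' @param flank Integer >= 1; bases kept on each side of the variant.
#' @return An object of class `variant_spec`.
#' @seealso [build_allele_references()]
#' @export
variant_spec <- function(label, context, variant_index, ref_base, alt_base,
                         flank = 40L) {
  context <- toupper(context)
  if (!is_acgt(context)) stop_input("context must contain only A/C/G/T")
  variant_index <- as.integer(variant_index)
  flank <- as.integer(flank)
  if (flank < 1L) stop_config("flank must be >= 1")
  if (!is_acgt(ref_base) || nchar(ref_base) != 1L ||
      !is_acgt(alt_base) || nchar(alt_base) != 1L)
    stop_input("ref_base and alt_base must be single A/C/G/T bases")
  if (ref_base == alt_base) stop_input("ref_base and alt_base must differ")
  n <- nchar(context)
  if (variant_index < 0L || variant_index >= n)
    stop_input("variant_index outside context")
  if (substr(context, variant_index + 1L, variant_index + 1L) != ref_base)
    stop_input("context does not carry ref_base at variant_index")
  if (variant_index < flank || n - variant_index - 1L < flank)
    stop_config("context too short for the requested flank on both sides")
  structure(list(label = label, context = context,
                 variant_index = variant_index,
                 ref_base = ref_base, alt_base = alt_base, flank = flank),
            class = "variant_spec")
}

#' Build the diploid allele reference pair
#'
#' Extracts the `2 * flank + 1` nt window centred on the variant and returns
#' the two allele references: the target allele carries the alternate
#' (disease) base at the centre, the non-target allele the reference base.
#' The two sequences differ at exactly that one position.
#'
#' @param spec A [variant_spec()].
#' @return A list with components `target` and `non_target`, each of class
#'   `allele_reference` with fields `allele`, `sequence`, `variant_index`
#'   (0-based, equal to `flank`) and `discriminating_base`.
#' @examples
#' vs <- variant_spec("demo", "AACCGGTTAACGGCCAATTGG", 10, "C", "T", flank = 10)
#' refs <- build_allele_references(vs)
#' refs$target$sequence
#' @export
build_allele_references <- function(spec) {
  stopifnot(inherits(spec, "variant_spec"))
  lo <- spec$variant_index - spec$flank   # 0-based window start
  win <- substr(spec$context, lo + 1L, spec$variant_index + spec$flank + 1L)
  vi <- spec$flank
  non_target <- win
  target <- win
  substr(target, vi + 1L, vi + 1L) <- spec$alt_base
  mk <- function(allele, sequence, base) {
    structure(list(allele = allele, sequence = sequence,
                   variant_index = vi, discriminating_base = base,
                   label = spec$label),
              class = "allele_reference")
  }
  list(target = mk("target", target, spec$alt_base),
       non_target = mk("non_target", non_target, spec$ref_base))
}

#' Describe a CRISPR guide RNA and its PAM requirement
#'
#' @param name Free-text guide name.
#' @param protospacer Protospacer sequence (typically 20-21 nt), written 5'->3'
#'   on the targeted strand.
#' @param pam PAM pattern over IUPAC codes, e.g. `"NGG"` (SpCas9),
#'   `"NNGRRT"` (SaCas9) or `"NNGG"` (SauriCas9/SlugCas9), immediately 3' of
#'   the protospacer.
#' @param ortholog Cas9 ortholog label (metadata only).
#' @param strand `"plus"` or `"minus"` relative to the allele reference.
#' @param cut_offset Inter-base distance of the blunt cut measured 5' of the
#'   PAM; 3 for all common Cas9 orthologs.
#' @return An object of class `guide_spec`.
#' @export
guide_spec <- function(name, protospacer, pam,
                       ortholog = c("SpCas9", "SaCas9", "SauriCas9",
                                    "SlugCas9", "custom"),
                       strand = c("plus", "minus"), cut_offset = 3L) {
  ortholog <- match.arg(ortholog)
  strand <- match.arg(strand)
  protospacer <- toupper(protospacer)
  pam <- toupper(pam)
  if (!is_acgt(protospacer)) stop_input("protospacer must be A/C/G/T")
  if (!is_iupac(pam)) stop_input("PAM must use IUPAC nucleotide codes")
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L) stop_config("cut_offset must be >= 0")
  structure(list(name = name, protospacer = protospacer, pam = pam,
                 ortholog = ortholog, strand = strand,
                 cut_offset = cut_offset),
            class = "guide_spec")
}

# all 0-based start positions where protospacer+PAM matches `sequence`
match_guide_sites <- function(sequence, guide) {
  len <- nchar(guide$protospacer)
  plen <- nchar(guide$pam)
  hits <- integer(0)
  from <- 1L
  repeat {
    p <- regexpr(guide$protospacer, substr(sequence, from, nchar(sequence)),
                 fixed = TRUE)
    if (p < 0L) break
    at <- from + as.integer(p) - 1L        # 1-based start
    pam_seq <- substr(sequence, at + len, at + len + plen - 1L)
    if (nchar(pam_seq) == plen && iupac_match(guide$pam, pam_seq))
      hits <- c(hits, at - 1L)
    from <- at + 1L
    if (from > nchar(sequence)) break
  }
  hits
}

#' Locate the Cas9 cleavage site and derive the editing window
#'
#' Finds the unique protospacer + PAM match on the stated strand of the
#' target allele reference, places a blunt cut `cut_offset` bases 5' of the
#' PAM (inter-base coordinate), and derives the editing window of
#' `half_width` bases on each side of the cut. Substitutions and deletions
#' are attributed to editing when they touch the half-open base interval
#' `[cut - half_width, cut + half_width)`; insertions when they fall at an
#' inter-base position in `[cut - half_width, cut + half_width]`.
#'
#' @param guide A [guide_spec()].
#' @param ref An `allele_reference` (normally the target allele).
#' @param half_width Editing-window half width in bases (default 5).
#' @return An object of class `editing_window` with fields `cut_site`
#'   (inter-base, 0..len), `half_width`, `base_range` (0-based half-open)
#'   and `insertion_range` (inclusive inter-base interval).
#' @examples
#' ref <- structure(list(allele = "target", sequence = "AAAATTTTCCCCGGGAGGAA",
#'                       variant_index = 0L, discriminating_base = "A"),
#'                  class = "allele_reference")
#' g <- guide_spec("toy", "TTTTCCCC", "NGG", "custom", "plus")
#' locate_cut_site(g, ref)$cut_site  # 9
#' @export
locate_cut_site <- function(guide, ref, half_width = 5L) {
  stopifnot(inherits(guide, "guide_spec"), inherits(ref, "allele_reference"))
  n <- nchar(ref$sequence)
  if (guide$strand == "plus") {
    hits <- match_guide_sites(ref$sequence, guide)
    if (length(hits) == 0L)
      stop_input("guide not found: no protospacer+PAM match on plus strand")
    if (length(hits) > 1L)
      stop_input("ambiguous guide: protospacer+PAM matches more than once")
    pam_start <- hits + nchar(guide$protospacer)
    cut <- pam_start - guide$cut_offset
  } else {
    rc <- revcomp(ref$sequence)
    hits <- match_guide_sites(rc, guide)
    if (length(hits) == 0L)
      stop_input("guide not found: no protospacer+PAM match on minus strand")
    if (length(hits) > 1L)
      stop_input("ambiguous guide: protospacer+PAM matches more than once")
    cut_rc <- hits + nchar(guide$protospacer) - guide$cut_offset
    cut <- n - cut_rc
  }
  editing_window(cut, half_width, ref_length = n)
}

#' Construct an editing window around a cut site
#'
#' @param cut_site Inter-base cut coordinate on the reference (0..len).
#' @param half_width Window half width in bases.
#' @param ref_length Optional reference length for bounds checking.
#' @return An object of class `editing_window`.
#' @export
editing_window <- function(cut_site, half_width = 5L, ref_length = NULL) {
  cut_site <- as.integer(cut_site)
  half_width <- as.integer(half_width)
  if (half_width < 1L) stop_config("half_width must be >= 1")
  base_range <- c(cut_site - half_width, cut_site + half_width)  # half-open
  if (!is.null(ref_length)) {
    if (base_range[1] < 0L || base_range[2] > ref_length)
      stop_config("editing window extends outside the reference")
  }
  structure(list(cut_site = cut_site, half_width = half_width,
                 base_range = base_range,
                 insertion_range = c(cut_site - half_width,
                                     cut_site + half_width),
                 ref_length = ref_length),
            class = "editing_window")
}

#' @export
print.editing_window <- function(x, ...) {
  cat(sprintf(
    "editing window: cut site %d (inter-base), bases [%d, %d), insertions [%d, %d]\n",
    x$cut_site, x$base_range[1], x$base_range[2],
    x$insertion_range[1], x$insertion_range[2]))
  invisible(x)
}

#' @export
print.variant_spec <- function(x, ...) {
  cat(sprintf("variant %s: %s>%s at 0-based index %d (flank %d)\n",
              x$label, x$ref_base, x$alt_base, x$variant_index, x$flank))
  invisible(x)
}

#' @export
print.allele_reference <- function(x, ...) {
  cat(sprintf("%s allele (%s at index %d), %d nt\n%s\n", x$allele,
              x$discriminating_base, x$variant_index, nchar(x$sequence),
              x$sequence))
  invisible(x)
}
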