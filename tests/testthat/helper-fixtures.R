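# Shared fixtures: the built-in synthetic locus plus small constructors.

demo <- ampedit::demo_locus()

# a read carrying a given canonical variant key on the chosen allele
fixture_read <- function(key, allele = c("target", "non_target"),
                         locus = demo) {
  allele <- match.arg(allele)
  ref <- locus$refs[[allele]]
  ampedit::reconstruct_variant_sequence(ref, key, locus$window$cut_site)
}

# ops data frame shorthand
ops_df <- function(kind, ref_start, ref_len, alt) {
  data.frame(kind = kind, ref_start = as.integer(ref_start),
             ref_len = as.integer(ref_len), alt = alt,
             stringsAsFactors = FALSE)
}

quiet_policy <- function(...) {
  ampedit::filter_policy(min_reads_per_sample = 1L, ...)
}
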