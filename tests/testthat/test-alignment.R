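random_edit <- function(ref) {
  n <- nchar(ref)
  kind <- sample(c("del", "ins"), 1)
  if (kind == "del") {
    len <- sample(1:3, 1)
    start <- sample(0:(n - len), 1)
    ops_df("del", start, len, "")
  } else {
    ops_df("ins", sample(0:n, 1), 0,
           paste(sample(c("A", "C", "G", "T"), sample(1:2, 1),
                        replace = TRUE), collapse = ""))
  }
}

test_that("identity alignment has full match score and no ops", {
  s <- "ACGTACGTAC"
  aln <- global_align(s, s)
  expect_equal(aln$score, 2 * nchar(s))
  expect_equal(nrow(aln$ops), 0)
  expect_equal(aln$aligned_span, c(0, nchar(s)))
  expect_error(global_align("", s), class = "ampedit_input_error")
})

test_that("single-indel optima match the exhaustive oracle", {
  # read ACGT vs ref ACGGT: one 1-base deletion, score 4*2 - 8 = 0
  aln <- global_align("ACGT", "ACGGT")
  expect_equal(aln$score, oracle_align_score("ACGGT", "ACGT"))
  expect_equal(aln$score, 0)
  expect_equal(aln$ops$kind, "del")
  expect_equal(aln$ops$ref_len, 1L)
  expect_true(aln$ops$ref_start %in% c(2L, 3L))

  # read ACGTTACGT vs ref ACGTACGT: one 1-base insertion of T
  aln2 <- global_align("ACGTTACGT", "ACGTACGT")
  expect_equal(aln2$score, oracle_align_score("ACGTACGT", "ACGTTACGT"))
  expect_equal(aln2$ops$kind, "ins")
  expect_equal(aln2$ops$alt, "T")
})

test_that("alignment score equals the oracle on random short pairs", {
  set.seed(11)
  for (k in 1:300) {
    ref <- random_dna(sample(1:12, 1))
    read <- random_dna(sample(1:12, 1))
    expect_equal(global_align(read, ref)$score,
                 oracle_align_score(ref, read),
                 info = paste(ref, read))
  }
})

test_that("ops always reconstruct the read", {
  set.seed(12)
  for (k in 1:200) {
    ref <- random_dna(sample(5:40, 1))
    read <- random_dna(sample(5:40, 1))
    aln <- global_align(read, ref)
    expect_equal(apply_edit_ops(ref, aln$ops), read)
    norm <- normalize_ops(aln$ops, ref)
    expect_equal(apply_edit_ops(ref, norm), read)
  }
})

test_that("indels are left-aligned in repeat context", {
  # deletion of one A inside CAAAG reported at the third A
  del <- ops_df("del", 3, 1, "")
  norm <- normalize_ops(del, "CAAAG")
  expect_equal(norm$ref_start, 1L)
  # insertion of T inside GTTTC reported after the last T
  ins <- ops_df("ins", 4, 0, "T")
  norm2 <- normalize_ops(ins, "GTTTC")
  expect_equal(norm2$ref_start, 1L)
  expect_equal(norm2$alt, "T")
  # non-repeat context is a fixed point
  fp <- ops_df("del", 2, 1, "")
  expect_equal(normalize_ops(fp, "ACGTA"), fp)
})

test_that("normalization is idempotent and alignment-tie invariant", {
  set.seed(13)
  refs <- c("CCAAAAGGTTTTCC", "ACGTACGTACGT", "AAAACCCCGGGG", "ATATATATAT")
  for (ref in refs) {
    for (k in 1:25) {
      read <- apply_edit_ops(ref, random_edit(ref))
      aln <- global_align(read, ref)
      n1 <- normalize_ops(aln$ops, ref)
      expect_identical(normalize_ops(n1, ref), n1)
    }
  }
  # equivalent raw placements of the same physical edit canonicalize equally
  ref <- "GGCAAAATCC"
  placements <- lapply(2:5, function(s) ops_df("del", s, 2, ""))
  canon <- lapply(placements, function(o) {
    # only placements describing the same read count
    read <- apply_edit_ops(ref, o)
    if (read == "GGCAATCC") normalize_ops(o, ref) else NULL
  })
  canon <- Filter(Negate(is.null), canon)
  expect_true(length(canon) >= 3)
  for (o in canon[-1]) expect_identical(o, canon[[1]])
})

test_that("allele assignment uses score then the discriminating base", {
  refs <- demo$refs
  # exact target read
  a1 <- assign_allele(refs$target$sequence, refs$target, refs$non_target)
  expect_equal(a1$allele, "target")
  expect_equal(nrow(a1$alignment$ops), 0)
  # non-target read with a 2-base deletion far from the variant
  read <- apply_edit_ops(refs$non_target$sequence, ops_df("del", 5, 2, ""))
  a2 <- assign_allele(read, refs$target, refs$non_target)
  expect_equal(a2$allele, "non_target")
  expect_equal(a2$score_non_target - a2$score_target, 5)  # match - mismatch
  # deletion spanning the discriminating base: scores tie, base deleted
  vi <- refs$target$variant_index
  read3 <- apply_edit_ops(refs$target$sequence, ops_df("del", vi - 2, 5, ""))
  a3 <- assign_allele(read3, refs$target, refs$non_target)
  expect_equal(a3$score_target, a3$score_non_target)
  expect_equal(a3$allele, "ambiguous")
})
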