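test_that("indicator filter requires both terminal k-mers in order", {
  ref <- demo$refs$target
  pol <- filter_policy()
  expect_true(passes_indicator_filter(ref$sequence, ref, pol))
  # missing the final 20 bases: downstream indicator absent
  trunc <- substr(ref$sequence, 1, nchar(ref$sequence) - 20)
  expect_false(passes_indicator_filter(trunc, ref, pol))
  # central 9-base deletion keeps both terminal indicators
  del9 <- fixture_read("del|-4|9|")
  expect_true(passes_indicator_filter(del9, ref, pol))
  # one mismatch inside an indicator: rejected exact, accepted lenient
  mut <- ref$sequence
  substr(mut, 3, 3) <- if (substr(mut, 3, 3) == "A") "C" else "A"
  expect_false(passes_indicator_filter(mut, ref, pol))
  expect_true(passes_indicator_filter(
    mut, ref, filter_policy(indicator_mode = "max_1_mismatch")))
})

test_that("editing-window rules classify reads as in the protocol", {
  w <- demo$window
  vi <- demo$refs$target$variant_index
  # no ops: wild type
  wt <- classify_read(ops_df(character(0), integer(0), integer(0),
                             character(0)), w)
  expect_equal(wt$mutation_class, "WT")
  expect_equal(wt$variant_key, "WT")
  # 9-base deletion starting 4 bases left of the cut: "del9"
  del9 <- classify_read(ops_df("del", w$cut_site - 4, 9, ""), w)
  expect_equal(del9$mutation_class, "deletion")
  expect_equal(del9$display_label, "del9")
  expect_equal(del9$net_delta, -9L)
  expect_true(del9$edited)
  # substitution 7 bases right of the cut: sequencing artifact, read is WT
  art <- classify_read(ops_df("sub", w$cut_site + 7, 1, "A"), w)
  expect_equal(art$mutation_class, "WT")
  expect_equal(art$artifact_subs, 1L)
  expect_false(art$edited)
  # substitution within 5 bases of the cut: base pair exchange
  bpe <- classify_read(ops_df("sub", w$cut_site + 3, 1, "A"), w)
  expect_equal(bpe$mutation_class, "base_pair_exchange")
  expect_true(bpe$edited)
  # deletion plus insertion within the window
  di <- classify_read(rbind(ops_df("del", w$cut_site - 2, 2, ""),
                            ops_df("ins", w$cut_site + 1, 0, "G")), w)
  expect_equal(di$mutation_class, "deletion_plus_insertion")
  expect_equal(di$display_label, "delins2+G")
  # out-of-window indel only: WT with a flag
  owi <- classify_read(ops_df("del", w$base_range[2] + 4, 2, ""), w)
  expect_equal(owi$mutation_class, "WT")
  expect_equal(owi$offwindow_indels, 1L)
  expect_false(owi$edited)
  # the discriminating substitution is allele signal, not an edit
  disc <- classify_read(ops_df("sub", vi, 1, "C"), w, variant_index = vi)
  expect_equal(disc$mutation_class, "WT")
  expect_equal(disc$artifact_subs, 0L)
})

test_that("call_sample composes filter, assignment and classification", {
  refs <- demo$refs
  w <- demo$window
  del9 <- fixture_read("del|-4|9|")
  reads <- c(rep(refs$target$sequence, 6), rep(del9, 3),
             refs$non_target$sequence)
  res <- call_sample(reads, refs, w, policy = quiet_policy())
  a <- res$accounting
  expect_equal(a$n_input, 10)
  expect_equal(a$n_filtered, 10)
  expect_equal(a$n_target, 9)
  expect_equal(a$n_non_target, 1)
  expect_equal(a$n_edited_target, 3)
  keys <- res$calls$variant_key[res$calls$mutation_class != "WT"]
  expect_equal(unique(keys), "del|-4|9|")
})

test_that("read order never changes the accounting", {
  refs <- demo$refs
  w <- demo$window
  reads <- c(rep(refs$target$sequence, 4), rep(fixture_read("ins|0|0|A"), 2),
             rep(refs$non_target$sequence, 3), fixture_read("del|-1|2|"))
  a1 <- call_sample(reads, refs, w, policy = quiet_policy())$accounting
  set.seed(5)
  a2 <- call_sample(sample(reads), refs, w, policy = quiet_policy())$accounting
  expect_equal(a1[names(a1) != "sample_id"], a2[names(a2) != "sample_id"])
})

test_that("the discriminating base is never an edit on either allele", {
  refs <- demo$refs
  w <- demo$window
  res <- call_sample(c(refs$target$sequence, refs$non_target$sequence),
                     refs, w, policy = quiet_policy())
  expect_equal(res$calls$mutation_class, c("WT", "WT"))
  expect_equal(res$calls$allele, c("target", "non_target"))
  expect_equal(res$accounting$n_edited_target, 0)
})

test_that("samples below the read threshold warn but still process", {
  refs <- demo$refs
  reads <- rep(refs$target$sequence, 100)
  expect_warning(
    res <- call_sample(reads, refs, demo$window,
                       policy = filter_policy(min_reads_per_sample = 10000)),
    regexp = "below 10000 filtered reads")
  expect_equal(res$accounting$n_filtered, 100)
  expect_match(res$warnings, "below 10000")
})

test_that("error-free synthetic reads recover the injected key exactly", {
  cfg <- simulation_config(demo$refs, demo$window, n_reads = 400,
                           sub_error_rate = 0, seed = 99)
  sim <- simulate_reads(cfg)
  res <- call_sample(sim$reads, demo$refs, demo$window,
                     policy = quiet_policy())
  m <- merge(sim$truth, res$calls, by = "read_id")
  expect_true(all(m$passed_filter))
  expect_equal(m$allele, m$true_allele)
  edited <- m[m$true_key != "WT", ]
  expect_gt(nrow(edited), 0)
  expect_equal(edited$variant_key, edited$true_key)
  unedited <- m[m$true_key == "WT", ]
  expect_true(all(unedited$mutation_class == "WT"))
})
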