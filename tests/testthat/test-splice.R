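consensus_sites <- function(n = 20) rep("CAGGTAAGT", n)

test_that("variant sequences reconstruct with the right length", {
  target <- demo$refs$target
  cut <- demo$window$cut_site
  expect_equal(reconstruct_variant_sequence(target, "WT", cut),
               target$sequence)
  del9 <- reconstruct_variant_sequence(target, "del|-4|9|", cut)
  expect_equal(nchar(del9), nchar(target$sequence) - 9)
  expect_equal(substr(del9, 1, cut - 4),
               substr(target$sequence, 1, cut - 4))
  insA <- reconstruct_variant_sequence(target, "ins|0|0|A", cut)
  expect_equal(nchar(insA), nchar(target$sequence) + 1)
  expect_error(reconstruct_variant_sequence(target, "del|50|9|", cut),
               class = "ampedit_input_error")
})

test_that("reconstruct -> align -> classify returns the input key", {
  cut <- demo$window$cut_site
  for (key in names(default_spectrum())) {
    seq <- reconstruct_variant_sequence(demo$refs$target, key, cut)
    asn <- assign_allele(seq, demo$refs$target, demo$refs$non_target)
    expect_equal(asn$allele, "target")
    ops <- normalize_ops(asn$alignment$ops, demo$refs$target)
    call <- classify_read(ops, demo$window,
                          variant_index = demo$refs$target$variant_index)
    expect_equal(call$variant_key, key)
  }
})

test_that("PWM training follows the log-odds formula", {
  m <- train_pwm(consensus_sites(20))
  # count 20 of 20: log2(((20 + .5)/(20 + 2)) / .25)
  expect_equal(m$weights["C", 1], log2((20.5 / 22) / 0.25))
  # absent base: log2(((0 + .5)/(20 + 2)) / .25)
  expect_equal(m$weights["A", 1], log2((0.5 / 22) / 0.25))
  # degenerate PWM scores its own word maximally
  sc <- score_donor_sites("CAGGTAAGT", m)
  expect_equal(sc$pos, 0)
  expect_equal(sc$score, 9 * log2((20.5 / 22) / 0.25))
  anti <- chartr("ACGT", "TGCA", "CAGGTAAGT")
  expect_lt(score_donor_sites(anti, m)$score, sc$score)

  expect_error(train_pwm(consensus_sites(9)), class = "ampedit_input_error")
  expect_error(train_pwm(c(consensus_sites(9), "CAGG")),
               class = "ampedit_input_error")
})

test_that("uniform random training sites give near-zero weights", {
  set.seed(77)
  sites <- vapply(1:8000, function(i) random_dna(9), "")
  m <- train_pwm(sites)
  expect_lt(max(abs(m$weights)), 0.15)
})

test_that("donor scanning finds the motif and respects the interval", {
  m <- donor_pwm()
  seq <- paste0("TTTTTTTTTT", "CAGGTAAGT", "TTTTTTTTTT")
  sc <- score_donor_sites(seq, m)
  expect_equal(sc$pos, 10)
  set.seed(42)
  rnd <- vapply(1:500, function(i)
    score_donor_sites(random_dna(29), m)$score, 0)
  expect_true(all(rnd < sc$score))
  one <- score_donor_sites("CAGGTAAGT", m, c(0, 9))
  expect_equal(length(one$scores), 1)
  expect_error(score_donor_sites("CAGGT", m), class = "ampedit_input_error")
})

test_that("losing the GT core strictly lowers the donor score", {
  m <- donor_pwm()
  intact <- score_donor_sites(demo$refs$target$sequence, m)$score
  cut <- demo$window$cut_site
  vi <- demo$refs$target$variant_index
  # delete the G/T core bases of the cryptic donor (positions vi-1, vi)
  core_del <- reconstruct_variant_sequence(
    demo$refs$target, ops_df("del", vi - 1, 2, ""))
  expect_lt(score_donor_sites(core_del, m)$score, intact)
  # the pathological allele scores far above the wild-type allele
  wt <- score_donor_sites(demo$refs$non_target$sequence, m)$score
  expect_gt(intact, wt)
})

test_that("splice impact weights the disrupting fraction by the spectrum", {
  cut <- demo$window$cut_site
  vi <- demo$refs$target$variant_index
  # two variants that both delete the GT core: 100% disrupting
  gt_killers <- c(100)
  names(gt_killers) <- sprintf("del|%d|4|", vi - 2 - cut)
  imp <- classify_splice_impact(gt_killers, demo$refs$target,
                                demo$refs$non_target, cut_site = cut)
  expect_equal(imp$fraction_disrupting, 100)
  expect_equal(imp$verdicts$category, "disrupting")

  # mixed spectrum with an enhancing (pathological-equivalent) outcome
  spec <- c(60, 40)
  names(spec) <- c(sprintf("del|%d|4|", vi - 2 - cut), "del|4|1|")
  imp2 <- classify_splice_impact(spec, demo$refs$target,
                                 demo$refs$non_target, cut_site = cut)
  expect_equal(
    imp2$fraction_disrupting,
    100 * sum(spec[imp2$verdicts$category == "disrupting"]) / sum(spec))

  # external scores: lookup instead of reconstruction
  ext <- external_splice_scores(data.frame(
    variant_key = c("WT", "pathological", "del|-4|9|", "ins|0|0|T"),
    score = c(2, 10, 0.5, 10.5)))
  imp3 <- classify_splice_impact(
    c("del|-4|9|" = 70, "ins|0|0|T" = 30),
    demo$refs$target, demo$refs$non_target, model = ext)
  expect_equal(imp3$verdicts$category, c("disrupting", "enhancing"))
  expect_equal(imp3$fraction_disrupting, 70)
})
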