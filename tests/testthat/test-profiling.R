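make_profile <- function(reads) {
  calls <- call_sample(reads, demo$refs, demo$window, policy = quiet_policy())
  summarize_calls(calls)
}

test_that("editing efficiencies use both denominators", {
  del9 <- fixture_read("del|-4|9|")
  reads <- c(rep(demo$refs$target$sequence, 6), rep(del9, 3),
             demo$refs$non_target$sequence)
  p <- make_profile(reads)
  expect_equal(p$efficiency_all_alleles, 30)
  expect_equal(p$efficiency_within_target, 100 * 3 / 9)
  expect_equal(p$spectrum$pct_edited, 100)
  expect_equal(p$spectrum$display_label, "del9")

  # all non-target wild type: zero efficiency
  p0 <- make_profile(rep(demo$refs$non_target$sequence, 10))
  expect_equal(p0$efficiency_all_alleles, 0)
  expect_equal(nrow(p0$spectrum), 0)

  # efficiency over all alleles never exceeds the within-target figure
  expect_lte(p$efficiency_all_alleles, p$efficiency_within_target)
})

test_that("spectrum percentages are invariant under duplicating calls", {
  reads <- c(rep(demo$refs$target$sequence, 3),
             rep(fixture_read("del|-4|9|"), 2),
             fixture_read("ins|0|0|A"),
             rep(demo$refs$non_target$sequence, 4))
  p1 <- make_profile(reads)
  p2 <- make_profile(rep(reads, 2))
  expect_equal(p1$spectrum$pct_edited, p2$spectrum$pct_edited)
  expect_equal(p1$spectrum$pct_filtered, p2$spectrum$pct_filtered)
  expect_equal(p1$efficiency_all_alleles, p2$efficiency_all_alleles)
  expect_equal(sum(p1$spectrum$pct_edited), 100)
})

test_that("implied cell fraction doubles the allele-level efficiency", {
  expect_equal(as.numeric(implied_cell_fraction(21)), 42)
  expect_equal(as.numeric(implied_cell_fraction(30)), 60)
  expect_equal(as.numeric(implied_cell_fraction(0)), 0)
  expect_equal(as.numeric(implied_cell_fraction(60)), 100)  # capped
  expect_error(implied_cell_fraction(120), class = "ampedit_input_error")
  expect_error(implied_cell_fraction(-1), class = "ampedit_input_error")
})

test_that("profile comparison computes r, TVD and top-variant agreement", {
  a <- c("del|-4|9|" = 60, "ins|0|0|A" = 40)
  same <- compare_profiles(a, a)
  expect_equal(same$pearson_r, 1)
  expect_equal(same$total_variation_distance, 0)
  expect_true(same$top_variant_match)

  flipped <- compare_profiles(a, c("del|-4|9|" = 40, "ins|0|0|A" = 60))
  expect_equal(flipped$total_variation_distance, 0.2)
  expect_false(flipped$top_variant_match)

  disjoint <- compare_profiles(c("del|-4|9|" = 100), c("ins|0|0|T" = 100))
  expect_equal(disjoint$total_variation_distance, 1)
  expect_false(disjoint$top_variant_match)

  expect_error(compare_profiles(c("del|-4|9|" = 0), a),
               class = "ampedit_input_error")
})

test_that("replicate concordance averages all pairwise correlations", {
  a <- c("del|-4|9|" = 55, "ins|0|0|A" = 30, "ins|0|0|T" = 15)
  conc2 <- replicate_concordance(list(r1 = a, r2 = a))
  expect_equal(conc2$mean_r, 1)
  conc3 <- replicate_concordance(list(a, a, a + c(1, -1, 0)))
  expect_equal(nrow(conc3$pairs), 3)
  expect_error(replicate_concordance(list(a)),
               class = "ampedit_input_error")
})

test_that("replicates sampled from one spectrum are highly concordant", {
  profiles <- lapply(1:3, function(k) {
    cfg <- simulation_config(demo$refs, demo$window, n_reads = 10000,
                             seed = 200 + k)
    sim <- simulate_reads(cfg)
    calls <- call_sample(sim$reads, demo$refs, demo$window,
                         policy = quiet_policy())
    summarize_calls(calls, sample_id = paste0("rep", k))
  })
  conc <- replicate_concordance(profiles)
  expect_gt(conc$mean_r, 0.95)
})

test_that("editing rates of 10-30% are recovered across seeds", {
  # estimator consistency, isolated from the artifact rule's error-driven
  # false positives by simulating error-free reads
  cases <- data.frame(rate = rep(c(0.1, 0.25, 0.3), times = c(7, 7, 6)),
                      seed = 1000 + 1:20)
  for (i in seq_len(nrow(cases))) {
    cfg <- simulation_config(demo$refs, demo$window, n_reads = 20000,
                             editing_rate = cases$rate[i],
                             sub_error_rate = 0, seed = cases$seed[i])
    sim <- simulate_reads(cfg)
    calls <- call_sample(sim$reads, demo$refs, demo$window,
                         policy = quiet_policy())
    rec <- evaluate_recovery(sim$truth, calls)
    p <- cases$rate[i]
    se <- 100 * sqrt(p * (1 - p) / sum(sim$truth$true_allele == "target"))
    # against the nominal rate: only the generator's own draw noise remains
    expect_lt(abs(rec$est_efficiency_within_target - 100 * p), 3 * se,
              label = sprintf("rate %.2f seed %d", cases$rate[i],
                              cases$seed[i]))
    expect_equal(rec$efficiency_delta, 0)
  }
})

test_that("the artifact rule's false-positive bias is positive and bounded", {
  # with per-base error rate eps and a 2h-base window, about 2*h*eps of
  # unedited reads acquire a window substitution and count as edited; the
  # resulting efficiency bias must stay under twice that ceiling
  eps <- 0.001
  h <- demo$window$half_width
  deltas <- vapply(1:5, function(s) {
    cfg <- simulation_config(demo$refs, demo$window, n_reads = 20000,
                             editing_rate = 0.1, sub_error_rate = eps,
                             seed = 3000 + s)
    sim <- simulate_reads(cfg)
    calls <- call_sample(sim$reads, demo$refs, demo$window,
                         policy = quiet_policy())
    evaluate_recovery(sim$truth, calls)$efficiency_delta
  }, 0)
  expect_true(all(deltas > 0))
  expect_true(all(deltas < 2 * (2 * h + 1) * eps * 100))
})

test_that("predicted profiles parse and renormalize", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant\tfrequency", "del9@-4\t49", "insA@0\t27"), f)
  pred <- load_predicted_profile(f)
  expect_equal(sum(pred), 100)
  expect_equal(unname(pred["del|-4|9|"]), 100 * 49 / 76)
  expect_equal(unname(pred["ins|0|0|A"]), 100 * 27 / 76)

  f1 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant\tfrequency", "del3@0\t100"), f1)
  expect_equal(as.vector(load_predicted_profile(f1)), 100)

  fbad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant\tfrequency", "whatever\t10"), fbad)
  expect_error(load_predicted_profile(fbad), regexp = "line 2",
               class = "ampedit_input_error")
  fneg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant\tfrequency", "del9@-4\t-5"), fneg)
  expect_error(load_predicted_profile(fneg), class = "ampedit_input_error")
})

test_that("an observed spectrum agrees with its generating prediction", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant\tfrequency", "del9@-4\t49", "insA@0\t27",
               "insT@0\t12", "del2@-1\t12"), f)
  pred <- load_predicted_profile(f)
  cfg <- simulation_config(demo$refs, demo$window, n_reads = 10000,
                           seed = 31)
  sim <- simulate_reads(cfg)
  p <- summarize_calls(call_sample(sim$reads, demo$refs, demo$window,
                                   policy = quiet_policy()))
  cmp <- compare_profiles(p, pred)
  expect_gt(cmp$pearson_r, 0.97)
  expect_true(cmp$top_variant_match)
  expect_lt(cmp$total_variation_distance, 0.1)
})
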