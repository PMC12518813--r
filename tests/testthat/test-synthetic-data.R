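test_that("corpus generation is deterministic under a seed and respects its support", {
  cfg <- generator_config(n_nests = 3, seed = 8)
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(c1$motifs, c2$motifs)
  expect_identical(c1$ground_truth, c2$ground_truth)
  # intervals inside the configured support, onsets strictly increasing
  for (m in split_motifs(c1$motifs)) {
    d <- diff(m$onset_s)
    expect_true(all(d > 0))
    expect_true(all(d >= 0.009 - 1e-12 & d <= 0.29 + 1e-12))
  }
})

test_that("default nest sizes emulate the study design", {
  corpus <- generate_corpus(generator_config(seed = 12))
  gt <- corpus$ground_truth
  expect_equal(sum(gt$role == "tutor"), 17L)
  per_nest <- table(gt$nest_id[gt$role == "tutee"])
  expect_true(all(per_nest >= 1 & per_nest <= 4))
  # ten motifs per bird
  motifs_per_bird <- tapply(corpus$motifs$motif_id, corpus$motifs$bird_id,
                            function(x) length(unique(x)))
  expect_true(all(motifs_per_bird == 10))
  # tutor beats inside the truncation range
  expect_true(all(gt$true_beat_hz[gt$role == "tutor"] >= 8.6 &
                    gt$true_beat_hz[gt$role == "tutor"] <= 26.4))
})

test_that("zero jitter with a unimodal base produces perfectly isochronous motifs", {
  set.seed(1)
  cfg <- generator_config(ioi_jitter_cv = 0, inter_intra_ratio = 1)
  tut <- generate_tutor(cfg, beat_hz = 20)
  units <- build_analysis_units(tut$motifs)
  metrics <- summarize_units(units)
  expect_true(all(abs(metrics$npvi) < 1e-9))
  expect_true(all(abs(metrics$cv_adj) < 1e-9))
  expect_equal(unique(round(metrics$ioi_beat_hz, 6)), 20)
})

test_that("a jitter target below the structural CV of the bimodal base is rejected", {
  expect_error(generator_config(ioi_jitter_cv = 0.1),
               class = "mr_config_error")
  # unimodal base makes the same target feasible
  expect_silent(generator_config(ioi_jitter_cv = 0.1, inter_intra_ratio = 1))
})

test_that("realized within-motif CV approaches the configured target", {
  set.seed(2)
  cfg <- generator_config(motifs_per_bird = 200)
  tut <- generate_tutor(cfg, beat_hz = 17)
  cvs <- vapply(split_motifs(tut$motifs), function(m) {
    d <- diff(m$onset_s); sd(d) / mean(d)
  }, numeric(1))
  expect_lt(abs(mean(cvs) - 0.57) / 0.57, 0.10)
})

test_that("per-bird pooled intervals are bimodal in log duration", {
  set.seed(3)
  cfg <- generator_config(motifs_per_bird = 400)
  tut <- generate_tutor(cfg, beat_hz = 17.1)
  iois <- unlist(lapply(split_motifs(tut$motifs), function(m) diff(m$onset_s)))
  d <- stats::density(log(iois), bw = 0.12)
  peaks <- which(diff(sign(diff(d$y))) == -2) + 1
  major <- peaks[d$y[peaks] > 0.2 * max(d$y)]
  expect_equal(length(major), 2L)
  # the two modes sit roughly an inter/intra ratio apart
  ratio <- exp(max(d$x[major]) - min(d$x[major]))
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 3.5)
})

test_that("a faithful full copy with no slowdown reproduces the tutor's metrics", {
  set.seed(4)
  cfg <- generator_config(ioi_jitter_cv = 0, inter_intra_ratio = 1,
                          tutee_slowdown_factor = 1, tutee_beat_jitter_cv = 0,
                          copy_strategy_probs = c(full_copy = 1,
                                                  partial_copy = 0,
                                                  improvise = 0))
  tut <- generate_tutor(cfg, beat_hz = 18)
  pup <- generate_tutee(cfg, tut, strategy = "full_copy")
  m_t <- summarize_units(build_analysis_units(tut$motifs))
  both <- rbind(tut$motifs, pup$motifs)
  m_p <- summarize_units(build_analysis_units(both))
  # the shared run stops at the last tutor-matched element, so it reproduces
  # the tutor's intervals exactly even if novel elements were appended
  sh <- m_p[m_p$subset_kind == "ALL_SHARED", ]
  expect_equal(sh$ioi_beat_hz, m_t$ioi_beat_hz, tolerance = 1e-9)
  expect_equal(sh$npvi, m_t$npvi, tolerance = 1e-9)
  expect_equal(sh$cv_adj, m_t$cv_adj, tolerance = 1e-9)
  expect_equal(pup$slowdown, 1)
})

test_that("partial copiers yield exactly one PART_SHARED unit per motif", {
  set.seed(6)
  cfg <- generator_config(n_nests = 1)
  tut <- generate_tutor(cfg, beat_hz = 17)
  pup <- generate_tutee(cfg, tut, strategy = "partial_copy")
  units <- build_analysis_units(rbind(tut$motifs, pup$motifs),
                                min_intervals = 2)
  per_motif <- table(units$motif_id[units$subset_kind == "PART_SHARED"])
  expect_equal(length(per_motif), 10L)
  expect_true(all(per_motif == 1))
})

test_that("improvised runs carry higher local variability than faithful copies", {
  set.seed(10)
  cfg <- generator_config(n_nests = 12,
                          copy_strategy_probs = c(full_copy = 0.5,
                                                  partial_copy = 0,
                                                  improvise = 0.5),
                          improvise_jitter_multiplier = 2)
  corpus <- generate_corpus(cfg)
  metrics <- summarize_units(build_analysis_units(corpus$motifs))
  expect_gt(mean(metrics$npvi[metrics$subset_kind == "NOT_SHARED"]),
            mean(metrics$npvi[metrics$subset_kind == "ALL_SHARED"]))
})

test_that("unknown copy strategies are rejected", {
  cfg <- generator_config()
  set.seed(1)
  tut <- generate_tutor(cfg)
  expect_error(generate_tutee(cfg, tut, strategy = "mimic"),
               class = "mr_config_error")
})

test_that("estimated tutor beats recover the ground truth under low jitter", {
  cfg <- generator_config(n_nests = 6, ioi_jitter_cv = 0.1,
                          inter_intra_ratio = 1, seed = 14)
  corpus <- generate_corpus(cfg)
  metrics <- summarize_units(build_analysis_units(corpus$motifs))
  tut <- metrics[metrics$subset_kind == "TUTOR", ]
  est <- tapply(tut$ioi_beat_hz, tut$bird_id, mean)
  gt <- corpus$ground_truth
  truth <- setNames(gt$true_beat_hz, gt$bird_id)[names(est)]
  expect_lt(mean(abs(est - truth) / truth), 0.02)
})

test_that("nest-level beat correlation falls as tempo-copy fidelity degrades", {
  fidelity <- c(0.02, 0.1, 0.3)  # tutee_beat_jitter_cv; smaller = higher
  mean_r <- sapply(fidelity, function(f) {
    rs <- sapply(1:8, function(s) {
      cfg <- generator_config(tutee_beat_jitter_cv = f,
                              seed = 1000 * s + round(1000 * f))
      corpus <- generate_corpus(cfg)
      beats <- vapply(split(corpus$motifs, corpus$motifs$bird_id),
                      function(b) mean(vapply(split_motifs(b), function(m) {
                        1 / mean(diff(m$onset_s))
                      }, numeric(1))), numeric(1))
      gt <- corpus$ground_truth
      tutor_beat <- beats[gt$bird_id[gt$role == "tutor"]]
      names(tutor_beat) <- gt$nest_id[gt$role == "tutor"]
      tutee_mean <- tapply(beats[gt$bird_id[gt$role == "tutee"]],
                           gt$nest_id[gt$role == "tutee"], mean)
      cor(tutor_beat[names(tutee_mean)], tutee_mean)
    })
    mean(rs)
  })
  expect_true(all(diff(mean_r) < 0))
})

test_that("generated corpora round-trip through the annotation formats", {
  corpus <- generate_corpus(generator_config(n_nests = 2, motifs_per_bird = 2,
                                             seed = 21))
  path <- withr::local_tempfile(fileext = ".csv")
  write_motifs(corpus$motifs, path)
  back <- read_motifs(path)
  ref <- validate_motifs(corpus$motifs)
  expect_identical(back$label, ref$label)
  expect_lt(max(abs(back$onset_s - ref$onset_s)), 1e-6)
})
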