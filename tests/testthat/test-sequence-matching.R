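tutor5 <- c("A", "B", "C", "D", "E")

test_that("shared marking is label membership", {
  expect_identical(mark_shared(c("A", "B", "C", "X", "Y"), tutor5),
                   c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_identical(mark_shared(c("X", "Y", "Z"), tutor5), rep(FALSE, 3))
  expect_identical(mark_shared(tutor5, tutor5), rep(TRUE, 5))
  expect_error(mark_shared(c("A"), character(0)),
               class = "mr_validation_error")
})

test_that("a complete in-order copy with appended elements is ALL_SHARED and stops at the last match", {
  run <- extract_shared_run(c(tutor5, "F"), tutor5)
  expect_identical(run$kind, "ALL_SHARED")
  expect_equal(c(run$start, run$end), c(1L, 5L))
  expect_identical(run$tutor_positions, 1:5)
})

test_that("an incomplete beginning snippet is PART_SHARED", {
  run <- extract_shared_run(c("A", "B", "C", "X", "Y"), tutor5,
                            min_intervals = 2)
  expect_identical(run$kind, "PART_SHARED")
  expect_equal(run$end, 3L)
  # skipping a tutor element still follows the order (subsequence mode) but
  # can never count as a complete copy
  run2 <- extract_shared_run(c("A", "C", "E", "X"), tutor5, min_intervals = 2)
  expect_identical(run2$kind, "PART_SHARED")
  expect_identical(run2$tutor_positions, c(1L, 3L, 5L))
  # substring mode demands consecutive tutor positions
  expect_null(extract_shared_run(c("A", "C", "E", "X"), tutor5,
                                 min_intervals = 2,
                                 match_mode = "substring"))
})

test_that("a shared run not anchored at the motif start is unclassified, with a warning", {
  expect_warning(
    run <- extract_shared_run(c("X", "A", "B", "C", "D"), tutor5,
                              min_intervals = 3),
    class = "mr_unanchored_run_warning")
  expect_null(run)
})

test_that("not-shared runs are the maximal qualifying novel stretches", {
  tutee <- strsplit("ABCXYZWABCQRS", "")[[1]]
  runs <- extract_not_shared_runs(tutee, c("A", "B", "C"), min_intervals = 2)
  expect_equal(runs$start, c(4L, 11L))
  expect_equal(runs$end, c(7L, 13L))
  expect_equal(nrow(extract_not_shared_runs(tutor5, tutor5)), 0L)
  # "XX" between shared As is too short at a 3-element minimum
  expect_equal(nrow(extract_not_shared_runs(c("A", "X", "X", "A"), "A",
                                            min_intervals = 2)), 0L)
})

test_that("unit extraction matches hand enumeration on simple nests", {
  # fully shared 6-element tutee: one EVERYTHING + one ALL_SHARED, no NOT_SHARED
  nest <- make_nest("ABCDEF", "ABCDEF")
  units <- build_analysis_units(nest)
  tutee_units <- units[units$role == "tutee", ]
  expect_setequal(as.character(tutee_units$subset_kind),
                  c("EVERYTHING", "ALL_SHARED"))
  expect_equal(tutee_units$n_iois, c(5L, 5L))
  # tutor motif of n elements -> one TUTOR unit with n - 1 IOIs
  tut <- units[units$subset_kind == "TUTOR", ]
  expect_equal(nrow(tut), 1L)
  expect_equal(tut$n_iois, 5L)
})

test_that("a too-short candidate contributes only to EVERYTHING and is logged", {
  # tutee XABCD: no beginning-anchored shared run, single novel element too
  # short for NOT_SHARED -> only the whole-motif unit remains
  nest <- make_nest("ABCDE", "XABCD")
  units <- suppressWarnings(build_analysis_units(nest, min_intervals = 3))
  tutee_units <- units[units$role == "tutee", ]
  expect_identical(as.character(tutee_units$subset_kind), "EVERYTHING")
  excl <- attr(units, "exclusions")
  expect_true(!is.null(excl) && "NOT_SHARED" %in% excl$subset_kind)
})

test_that("units never share intervals across run boundaries and sum to onset spans", {
  # partial copier with improvised tail (shared beginning + novel run)
  nest <- make_nest("ABCDE", c("ABCWXYZ", "ABCDE"))
  units <- build_analysis_units(nest, min_intervals = 2)
  for (i in seq_len(nrow(units))) {
    motif <- nest[nest$bird_id == units$bird_id[i] &
                    nest$motif_id == units$motif_id[i], ]
    onsets <- motif$onset_s[units$start_index[i]:units$end_index[i]]
    expect_equal(sum(units$iois[[i]]), max(onsets) - min(onsets),
                 tolerance = 1e-9)
  }
  u1 <- units[units$bird_id == "U1", ]
  part <- u1[u1$subset_kind == "PART_SHARED", ]
  ns <- u1[u1$subset_kind == "NOT_SHARED", ]
  expect_equal(nrow(part), 1L)
  expect_equal(nrow(ns), 1L)
  # disjoint element index ranges
  expect_true(part$end_index < ns$start_index)
})

test_that("shared/not-shared is a partition and returned runs are maximal", {
  set.seed(42)
  alphabet <- c(LETTERS[1:6], letters[24:26])
  for (rep in 1:50) {
    tutor <- LETTERS[1:6]
    tutee <- sample(alphabet, sample(4:12, 1), replace = TRUE)
    shared <- mark_shared(tutee, tutor)
    runs <- extract_not_shared_runs(tutee, tutor, min_intervals = 1)
    covered <- unlist(lapply(seq_len(nrow(runs)),
                             function(i) runs$start[i]:runs$end[i]))
    # partition: every element is shared xor not-shared
    expect_true(all(!shared[covered]))
    # maximality: neighbours of every run are shared or out of bounds
    for (i in seq_len(nrow(runs))) {
      if (runs$start[i] > 1) expect_true(shared[runs$start[i] - 1L])
      if (runs$end[i] < length(tutee)) expect_true(shared[runs$end[i] + 1L])
    }
  }
})

test_that("relabelling a shared element to a novel label never lengthens the shared run", {
  set.seed(7)
  tutor <- LETTERS[1:6]
  for (rep in 1:30) {
    tutee <- sample(c(tutor, "x", "y"), 8, replace = TRUE)
    base <- suppressWarnings(
      extract_shared_run(tutee, tutor, min_intervals = 1))
    base_len <- if (is.null(base)) 0L else base$end
    shared_idx <- which(mark_shared(tutee, tutor))
    if (!length(shared_idx)) next
    tweaked <- tutee
    tweaked[sample(shared_idx, 1)] <- "zz"
    new <- suppressWarnings(
      extract_shared_run(tweaked, tutor, min_intervals = 1))
    new_len <- if (is.null(new)) 0L else new$end
    expect_lte(new_len, base_len)
  }
})

test_that("a nest without a tutor is a configuration error", {
  nest <- make_motif("ABCD", role = "tutee")
  expect_error(build_analysis_units(nest), class = "mr_config_error")
})

test_that("unit tables round-trip through their CSV form", {
  nest <- make_nest("ABCDEF", c("ABCDEF", "ABCXYZW"))
  units <- build_analysis_units(nest, min_intervals = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_units(units, path)
  back <- read_units(path)
  expect_equal(nrow(back), nrow(units))
  expect_identical(as.character(back$subset_kind),
                   as.character(units$subset_kind))
  expect_lt(max(abs(unlist(back$iois) - unlist(units$iois))), 1e-6)
})
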