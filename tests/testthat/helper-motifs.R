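# Build a one-motif annotation table from labels and onsets (or a constant
# IOI when onsets are not given).
make_motif <- function(labels, onsets = NULL, ioi = 0.06,
                       nest = "N1", bird = "B1", role = "tutee",
                       motif = "m1") {
  labels <- strsplit(labels, "")[[1]]
  if (is.null(onsets)) onsets <- (seq_along(labels) - 1) * ioi
  data.frame(nest_id = nest, bird_id = bird, role = role, motif_id = motif,
             element_index = seq_along(labels), label = labels,
             onset_s = onsets, stringsAsFactors = FALSE)
}

# A nest: one tutor motif plus tutee motifs given as label strings. Tutee
# onsets default to a constant IOI (slightly different per bird so units are
# distinguishable).
make_nest <- function(tutor_labels, tutee_labels = character(0),
                      nest = "N1", ioi = 0.06) {
  rows <- list(make_motif(tutor_labels, nest = nest, bird = "T1",
                          role = "tutor", ioi = ioi))
  for (i in seq_along(tutee_labels)) {
    rows[[length(rows) + 1L]] <-
      make_motif(tutee_labels[i], nest = nest, bird = paste0("U", i),
                 role = "tutee", ioi = ioi * (1 + 0.05 * i))
  }
  do.call(rbind, rows)
}

# Random positive IOI vector for property loops.
random_iois <- function(m, min = 0.01, max = 0.3) {
  stats::runif(m, min, max)
}
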