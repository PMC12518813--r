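#' Configuration for the synthetic nest generator
#'
#' Builds and validates the parameter set controlling [generate_corpus()].
#' Defaults emulate the structure of the studied breeding colony: 17 nests
#' with 1–4 tutees each (median 2), ten crystallised motifs per bird,
#' per-bird quasi-isochronous beats drawn from a normal distribution with
#' mean 17.1 Hz and sd 3.7 Hz truncated to 8.6–26.4 Hz, bimodal IOIs (short
#' intra-syllable gaps vs longer inter-syllable gaps) confined to
#' 0.009–0.29 s, within-motif IOI variability with a coefficient of
#' variation of 0.57, and tutees whose tempo follows their tutor's but is on
#' average 5% slower.
#'
#' The bimodal interval structure arises from grouping elements into
#' syllables of `syllable_size_range` elements; gaps inside a syllable get a
#' short base duration, gaps between syllables one `inter_intra_ratio`
#' times longer, with the overall mean pinned to `1 / beat`. Per-interval
#' multiplicative log-normal jitter is then calibrated per bird so the
#' realized within-motif CV matches `ioi_jitter_cv`. A target CV below the
#' structural CV of the bimodal base pattern is infeasible and rejected; for
#' low-variability corpora (e.g. parameter-recovery studies) set
#' `inter_intra_ratio = 1`.
#'
#' @param n_nests number of nests (tutor families).
#' @param tutees_per_nest_probs probabilities of 1, 2, 3, 4 tutees per nest.
#' @param motifs_per_bird motifs recorded per bird.
#' @param tutor_beat_mean_hz,tutor_beat_sd_hz,tutor_beat_range_hz normal
#'   distribution (mean, sd, truncation range) of tutor IOI beats.
#' @param elements_per_motif inclusive range of elements per motif
#'   (uniform; max 26 so labels stay single letters).
#' @param syllable_size_range inclusive range of elements per syllable.
#' @param inter_intra_ratio ratio of inter-syllable to intra-syllable base
#'   gap durations (1 = unimodal).
#' @param ioi_jitter_cv target realized within-motif CV of the intervals.
#' @param ioi_support_s inclusive support of generated intervals (seconds).
#' @param tutee_slowdown_factor mean multiplicative tempo slowdown of tutees
#'   relative to their tutor (>= 1).
#' @param tutee_beat_jitter_cv CV of the per-tutee deviation around the
#'   slowdown factor; 0 means every tutee copies its tutor's tempo exactly
#'   up to the slowdown (tempo-copy fidelity knob — smaller is higher
#'   fidelity).
#' @param copy_strategy_probs probabilities of the tutee copying strategies
#'   `full_copy`, `partial_copy`, `improvise`.
#' @param improvise_jitter_multiplier jitter inflation on improvised (novel)
#'   intervals.
#' @param seed optional integer seed recorded in the config and used by
#'   [generate_corpus()].
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_nests = 17,
                             tutees_per_nest_probs = c(0.30, 0.35, 0.20, 0.15),
                             motifs_per_bird = 10,
                             tutor_beat_mean_hz = 17.1,
                             tutor_beat_sd_hz = 3.7,
                             tutor_beat_range_hz = c(8.6, 26.4),
                             elements_per_motif = c(6, 14),
                             syllable_size_range = c(1, 3),
                             inter_intra_ratio = 2.5,
                             ioi_jitter_cv = 0.57,
                             ioi_support_s = c(0.009, 0.29),
                             tutee_slowdown_factor = 1.05,
                             tutee_beat_jitter_cv = 0.02,
                             copy_strategy_probs = c(full_copy = 0.3,
                                                     partial_copy = 0.4,
                                                     improvise = 0.3),
                             improvise_jitter_multiplier = 1.5,
                             seed = NULL) {
  cfg <- list(n_nests = n_nests,
              tutees_per_nest_probs = tutees_per_nest_probs,
              motifs_per_bird = motifs_per_bird,
              tutor_beat_mean_hz = tutor_beat_mean_hz,
              tutor_beat_sd_hz = tutor_beat_sd_hz,
              tutor_beat_range_hz = tutor_beat_range_hz,
              elements_per_motif = elements_per_motif,
              syllable_size_range = syllable_size_range,
              inter_intra_ratio = inter_intra_ratio,
              ioi_jitter_cv = ioi_jitter_cv,
              ioi_support_s = ioi_support_s,
              tutee_slowdown_factor = tutee_slowdown_factor,
              tutee_beat_jitter_cv = tutee_beat_jitter_cv,
              copy_strategy_probs = copy_strategy_probs,
              improvise_jitter_multiplier = improvise_jitter_multiplier,
              seed = seed)
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  stop_cfg <- function(msg) mr_stop(msg, "mr_config_error")
  if (cfg$n_nests < 1) stop_cfg("n_nests must be >= 1")
  if (length(cfg$tutees_per_nest_probs) != 4 ||
      any(cfg$tutees_per_nest_probs < 0) ||
      abs(sum(cfg$tutees_per_nest_probs) - 1) > 1e-8) {
    stop_cfg("tutees_per_nest_probs must be 4 non-negative values summing to 1")
  }
  if (cfg$motifs_per_bird < 1) stop_cfg("motifs_per_bird must be >= 1")
  if (cfg$tutor_beat_mean_hz <= 0 || cfg$tutor_beat_sd_hz < 0) {
    stop_cfg("tutor beat distribution must be positive")
  }
  rng <- cfg$tutor_beat_range_hz
  if (length(rng) != 2 || rng[1] <= 0 || rng[2] <= rng[1]) {
    stop_cfg("tutor_beat_range_hz must be an increasing positive pair")
  }
  el <- cfg$elements_per_motif
  if (length(el) != 2 || el[1] < 3 || el[2] < el[1] || el[2] > 26) {
    stop_cfg("elements_per_motif must be a range within [3, 26]")
  }
  sy <- cfg$syllable_size_range
  if (length(sy) != 2 || sy[1] < 1 || sy[2] < sy[1]) {
    stop_cfg("syllable_size_range must be an increasing range from >= 1")
  }
  if (cfg$inter_intra_ratio < 1) stop_cfg("inter_intra_ratio must be >= 1")
  if (cfg$ioi_jitter_cv < 0) stop_cfg("ioi_jitter_cv must be >= 0")
  sup <- cfg$ioi_support_s
  if (length(sup) != 2 || sup[1] <= 0 || sup[2] <= sup[1]) {
    stop_cfg("ioi_support_s must be an increasing positive pair")
  }
  if (cfg$tutee_slowdown_factor < 1) {
    stop_cfg("tutee_slowdown_factor must be >= 1")
  }
  if (cfg$tutee_beat_jitter_cv < 0) stop_cfg("tutee_beat_jitter_cv must be >= 0")
  p <- cfg$copy_strategy_probs
  if (length(p) != 3 || any(p < 0) || abs(sum(p) - 1) > 1e-8 ||
      !setequal(names(p), c("full_copy", "partial_copy", "improvise"))) {
    stop_cfg("copy_strategy_probs must be named probabilities for full_copy, partial_copy, improvise summing to 1")
  }
  if (cfg$improvise_jitter_multiplier < 1) {
    stop_cfg("improvise_jitter_multiplier must be >= 1")
  }
  # Feasibility: the bimodal base pattern alone already has a CV; jitter can
  # only add variability, so the target CV must not lie below the largest
  # structural CV any intra/inter gap mix can produce.
  max_structural <- max_structural_cv(cfg$inter_intra_ratio)
  if (cfg$ioi_jitter_cv < max_structural - 1e-9) {
    stop_cfg(sprintf(paste0("ioi_jitter_cv = %.3f is below the structural CV ",
                            "%.3f of the bimodal base pattern; lower ",
                            "inter_intra_ratio (1 = unimodal) or raise the ",
                            "jitter target"),
                     cfg$ioi_jitter_cv, max_structural))
  }
  structure(cfg, class = "generator_config")
}

# Largest CV a two-level base pattern (values 1 and rho, inter-gap fraction
# f in (0,1)) can reach; evaluated on a grid.
max_structural_cv <- function(rho) {
  if (rho <= 1) return(0)
  f <- seq(0.01, 0.99, by = 0.01)
  max((rho - 1) * sqrt(f * (1 - f)) / (1 + (rho - 1) * f))
}

sample_int_range <- function(a, b) if (a == b) a else sample(seq(a, b), 1L)

draw_truncnorm <- function(mean, sd, range) {
  if (sd == 0) return(min(max(mean, range[1]), range[2]))
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= range[1] && x <= range[2]) return(x)
  }
}

# Gap types of a motif: group n elements into syllables, mark each gap as
# within-syllable ("intra") or between-syllable ("inter").
draw_gap_types <- function(n_elements, syllable_size_range) {
  sizes <- integer(0)
  while (sum(sizes) < n_elements) {
    sizes <- c(sizes, sample_int_range(syllable_size_range[1],
                                       syllable_size_range[2]))
  }
  excess <- sum(sizes) - n_elements
  if (excess > 0) sizes[length(sizes)] <- sizes[length(sizes)] - excess
  sizes <- sizes[sizes > 0]
  last_of_syllable <- cumsum(sizes)
  gap_idx <- seq_len(n_elements - 1L)
  ifelse(gap_idx %in% last_of_syllable, "inter", "intra")
}

# Base (noise-free) gap durations with the overall mean pinned to 1/beat.
base_gaps <- function(gap_type, beat_hz, ratio) {
  w <- ifelse(gap_type == "inter", ratio, 1)
  x <- length(w) / (beat_hz * sum(w))
  w * x
}

# Lognormal jitter sd (per gap) so the realized sequence CV approaches the
# target: total^2 + 1 = (1 + jitter^2)(1 + structural^2) for unit-mean
# multiplicative noise.
jitter_sigma <- function(base, target_cv) {
  mu <- mean(base)
  cvb <- sqrt(mean((base - mu)^2)) / mu
  j2 <- (1 + target_cv^2) / (1 + cvb^2) - 1
  if (j2 < -1e-9) {
    mr_stop(sprintf("target CV %.3f infeasible for base pattern with structural CV %.3f",
                    target_cv, cvb), "mr_config_error")
  }
  sqrt(log1p(max(j2, 0)))
}

# All motifs of one bird as an annotation table. The label sequence and base
# timing are fixed (crystallised song); only the per-interval jitter varies
# between motifs.
bird_motifs <- function(cfg, nest_id, bird_id, role, labels, base, sigma) {
  m <- length(base)
  n <- m + 1L
  sup <- cfg$ioi_support_s
  rows <- vector("list", cfg$motifs_per_bird)
  for (j in seq_len(cfg$motifs_per_bird)) {
    mult <- stats::rlnorm(m, meanlog = -sigma^2 / 2, sdlog = sigma)
    d <- pmin(pmax(base * mult, sup[1]), sup[2])
    onsets <- cumsum(c(0, d))
    durations <- 0.6 * c(d, mean(d))
    rows[[j]] <- data.frame(
      nest_id = nest_id, bird_id = bird_id, role = role,
      motif_id = sprintf("m%02d", j),
      element_index = seq_len(n), label = labels,
      onset_s = onsets, offset_s = onsets + durations,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate a synthetic tutor
#'
#' Draws a tutor bird: a beat from the configured (truncated normal)
#' distribution, a crystallised element sequence labelled `A`, `B`, `C`,
#' ... with a syllable grouping, a bimodal base interval pattern whose mean
#' equals `1 / beat`, and `motifs_per_bird` motifs differing only in
#' calibrated log-normal timing jitter.
#'
#' @param config a [generator_config()].
#' @param nest_id,bird_id identifiers.
#' @param beat_hz optional beat override (otherwise drawn).
#' @return list with `motifs` (annotation table), `beat_hz`, `labels`,
#'   `gap_type`, `sigma`; feed it to [generate_tutee()].
#' @export
generate_tutor <- function(config, nest_id = "N01", bird_id = "T01",
                           beat_hz = NULL) {
  cfg <- validate_generator_config(config)
  if (is.null(beat_hz)) {
    beat_hz <- draw_truncnorm(cfg$tutor_beat_mean_hz, cfg$tutor_beat_sd_hz,
                              cfg$tutor_beat_range_hz)
  }
  n <- sample_int_range(cfg$elements_per_motif[1], cfg$elements_per_motif[2])
  labels <- LETTERS[seq_len(n)]
  gap_type <- draw_gap_types(n, cfg$syllable_size_range)
  base <- base_gaps(gap_type, beat_hz, cfg$inter_intra_ratio)
  sigma <- jitter_sigma(base, cfg$ioi_jitter_cv)
  motifs <- bird_motifs(cfg, nest_id, bird_id, "tutor", labels, base,
                        rep(sigma, length(base)))
  list(motifs = motifs, beat_hz = beat_hz, labels = labels,
       gap_type = gap_type, sigma = sigma, nest_id = nest_id,
       bird_id = bird_id)
}

#' Generate a synthetic tutee for a tutor
#'
#' The tutee's tempo is derived from its tutor's: its beat is the tutor's
#' beat divided by an individual slowdown factor centred on
#' `tutee_slowdown_factor` (log-normal spread `tutee_beat_jitter_cv`), so
#' nest-level tutor-tutee beat correlation is an emergent property. Its
#' element sequence follows the copying `strategy`:
#'
#' * `full_copy` — the tutor's complete sequence (occasionally with one or
#'   two novel elements appended);
#' * `partial_copy` — a beginning-anchored portion of the tutor's sequence
#'   continued with novel elements;
#' * `improvise` — at most a token tutor prefix, then a run of at least
#'   four novel elements whose intervals are drawn independently and
#'   jittered `improvise_jitter_multiplier` times harder.
#'
#' Novel labels (`n1`, `n2`, ...) never collide with tutor labels.
#'
#' @param config a [generator_config()].
#' @param tutor a tutor from [generate_tutor()].
#' @param strategy one of `"full_copy"`, `"partial_copy"`, `"improvise"`;
#'   drawn from `copy_strategy_probs` when `NULL`.
#' @param bird_id identifier.
#' @return list with `motifs`, `beat_hz`, `slowdown`, `strategy`, `labels`.
#' @export
generate_tutee <- function(config, tutor, strategy = NULL, bird_id = "U01.1") {
  cfg <- validate_generator_config(config)
  if (is.null(strategy)) {
    strategy <- sample(names(cfg$copy_strategy_probs), 1L,
                       prob = cfg$copy_strategy_probs)
  }
  if (!strategy %in% c("full_copy", "partial_copy", "improvise")) {
    mr_stop(paste0("unknown copy strategy: ", strategy), "mr_config_error")
  }
  sdlog <- sqrt(log1p(cfg$tutee_beat_jitter_cv^2))
  slowdown <- cfg$tutee_slowdown_factor *
    (if (sdlog > 0) exp(stats::rnorm(1, -sdlog^2 / 2, sdlog)) else 1)
  beat_hz <- tutor$beat_hz / slowdown

  n_tutor <- length(tutor$labels)
  n_target <- sample_int_range(cfg$elements_per_motif[1],
                               cfg$elements_per_motif[2])
  novel_label <- function(k) sprintf("n%d", seq_len(k))

  if (strategy == "full_copy") {
    n_app <- if (stats::runif(1) < 0.3) sample_int_range(1, 2) else 0L
    labels <- c(tutor$labels, novel_label(n_app))
    gap_type <- c(tutor$gap_type, rep("inter", n_app))
    novel_gaps <- integer(0)
  } else if (strategy == "partial_copy") {
    k <- sample_int_range(max(2L, ceiling(n_tutor / 2)), n_tutor - 1L)
    n_total <- max(k + 2L, n_target)
    n_new <- n_total - k
    labels <- c(tutor$labels[seq_len(k)], novel_label(n_new))
    gap_type <- c(tutor$gap_type[seq_len(k - 1L)], "inter",
                  draw_gap_types(n_new, cfg$syllable_size_range))
    novel_gaps <- seq(k, n_total - 1L)
  } else { # improvise
    p <- sample_int_range(0, min(2L, n_tutor))
    n_total <- max(p + 4L, n_target)
    n_new <- n_total - p
    labels <- c(tutor$labels[seq_len(p)], novel_label(n_new))
    gap_type <- c(if (p >= 2) tutor$gap_type[seq_len(p - 1L)],
                  if (p >= 1) "inter",
                  draw_gap_types(n_new, cfg$syllable_size_range))
    novel_gaps <- seq(max(p, 1L), n_total - 1L)
  }

  base <- base_gaps(gap_type, beat_hz, cfg$inter_intra_ratio)
  sigma <- rep(jitter_sigma(base, cfg$ioi_jitter_cv), length(base))
  if (strategy == "improvise") {
    sigma[novel_gaps] <- sigma[novel_gaps] * cfg$improvise_jitter_multiplier
  }
  motifs <- bird_motifs(cfg, tutor$nest_id, bird_id, "tutee", labels, base,
                        sigma)
  list(motifs = motifs, beat_hz = beat_hz, slowdown = slowdown,
       strategy = strategy, labels = labels)
}

#' Generate a complete synthetic corpus with ground truth
#'
#' Draws `n_nests` nests — one tutor plus 1–4 tutees each — and returns the
#' pooled annotation table together with a ground-truth sidecar holding the
#' true per-bird beats, slowdowns and copying strategies, for
#' parameter-recovery studies. Fully reproducible when the config carries a
#' seed.
#'
#' @param config a [generator_config()].
#' @return Object of class `rhythm_corpus`: list with `motifs` (annotation
#'   table, round-trippable through [write_motifs()]/[read_motifs()]),
#'   `ground_truth` (one row per bird: `nest_id`, `bird_id`, `role`,
#'   `strategy`, `true_beat_hz`, `slowdown`) and `config`.
#' @examples
#' corpus <- generate_corpus(generator_config(n_nests = 2, seed = 7))
#' head(corpus$ground_truth)
#' @export
generate_corpus <- function(config = generator_config()) {
  cfg <- validate_generator_config(config)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  motif_list <- list()
  truth <- list()
  for (i in seq_len(cfg$n_nests)) {
    nest_id <- sprintf("N%02d", i)
    tutor <- generate_tutor(cfg, nest_id = nest_id,
                            bird_id = sprintf("T%02d", i))
    motif_list[[length(motif_list) + 1L]] <- tutor$motifs
    truth[[length(truth) + 1L]] <- data.frame(
      nest_id = nest_id, bird_id = tutor$bird_id, role = "tutor",
      strategy = NA_character_, true_beat_hz = tutor$beat_hz,
      slowdown = NA_real_, stringsAsFactors = FALSE)
    n_tutees <- sample(1:4, 1L, prob = cfg$tutees_per_nest_probs)
    for (j in seq_len(n_tutees)) {
      tutee <- generate_tutee(cfg, tutor,
                              bird_id = sprintf("U%02d.%d", i, j))
      motif_list[[length(motif_list) + 1L]] <- tutee$motifs
      truth[[length(truth) + 1L]] <- data.frame(
        nest_id = nest_id, bird_id = sprintf("U%02d.%d", i, j),
        role = "tutee", strategy = tutee$strategy,
        true_beat_hz = tutee$beat_hz, slowdown = tutee$slowdown,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(motifs = validate_motifs(do.call(rbind, motif_list)),
                 ground_truth = do.call(rbind, truth),
                 config = cfg),
            class = "rhythm_corpus")
}

#' @export
print.rhythm_corpus <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf("Synthetic corpus: %d nests, %d tutors, %d tutees, %d motifs\n",
              length(unique(gt$nest_id)), sum(gt$role == "tutor"),
              sum(gt$role == "tutee"),
              length(unique(motif_key(x$motifs)))))
  if (!is.null(x$config$seed)) cat("  seed:", x$config$seed, "\n")
  tab <- table(gt$strategy[gt$role == "tutee"])
  cat("  tutee strategies:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
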