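## Synthetic-data generators: closed testing loop for every analysis stage.
## One global integer seed per config; substreams are drawn sequentially from
## the seeded base RNG, so a fixed seed gives bit-identical tables.

rtnorm <- function(n, mean, sd, lower = 1e-3) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
  }
  x
}

check_prob <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop(name, " must be a probability in [0, 1]")
  invisible(p)
}

#' Configuration for the behavioral-log generator
#'
#' Generates object-exploration bouts with a known novel-object preference so
#' the scoring stage can be tested against ground truth. Bout durations are
#' log-normal (positive, right-skewed); since durations are identically
#' distributed for both objects, the expected discrimination index is
#' 2 * preference_novel - 1.
#'
#' @param preference_novel probability a bout targets the novel object.
#' @param n_bouts number of exploration bouts.
#' @param bout_duration_mean mean bout duration, seconds.
#' @param bout_duration_shape log-scale sd of the log-normal duration.
#' @param trial_length trial duration, seconds; bouts are placed without
#'   overlap inside `[0, trial_length]` (durations are rescaled in the rare
#'   case their sum exceeds 90% of the trial).
#' @param animal_id,trial_id identifiers stamped on the log.
#' @param seed integer RNG seed.
#' @return list of class `behavior_sim_config`.
#' @export
behavior_sim_config <- function(preference_novel = 0.5, n_bouts = 30,
                                bout_duration_mean = 2,
                                bout_duration_shape = 0.6,
                                trial_length = 600,
                                animal_id = "sim1", trial_id = "trial1",
                                seed = 1L) {
  check_prob(preference_novel, "preference_novel")
  if (n_bouts < 1) stop("n_bouts must be a positive integer")
  if (bout_duration_mean <= 0 || bout_duration_shape <= 0)
    stop("bout duration mean and shape must be > 0")
  if (trial_length <= 0) stop("trial_length must be > 0")
  structure(list(preference_novel = preference_novel,
                 n_bouts = as.integer(n_bouts),
                 bout_duration_mean = bout_duration_mean,
                 bout_duration_shape = bout_duration_shape,
                 trial_length = trial_length,
                 animal_id = animal_id, trial_id = trial_id,
                 seed = as.integer(seed)),
            class = "behavior_sim_config")
}

#' Simulate a scored exploration log
#'
#' @param cfg a [behavior_sim_config()].
#' @return a `trial_log` (see [read_event_log()]) with non-overlapping bouts
#'   inside `[0, trial_length]`; object choice is i.i.d.
#'   Bernoulli(preference_novel).
#' @export
simulate_trial_log <- function(cfg) {
  stopifnot(inherits(cfg, "behavior_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_bouts
  novel <- stats::rbinom(n, 1, cfg$preference_novel) == 1
  sdlog <- cfg$bout_duration_shape
  meanlog <- log(cfg$bout_duration_mean) - sdlog^2 / 2
  dur <- stats::rlnorm(n, meanlog, sdlog)
  budget <- 0.9 * cfg$trial_length
  if (sum(dur) > budget) dur <- dur * budget / sum(dur)
  # spread the free time over n+1 gaps (Dirichlet via normalized exponentials)
  gaps <- stats::rexp(n + 1)
  gaps <- gaps / sum(gaps) * (cfg$trial_length - sum(dur))
  starts <- cumsum(gaps)[seq_len(n)] + c(0, cumsum(dur))[seq_len(n)]
  new_trial_log(data.frame(
    animal_id = cfg$animal_id, trial_id = cfg$trial_id,
    bout_index = seq_len(n),
    object_label = ifelse(novel, "novel", "familiar"),
    t_start_s = starts, t_stop_s = starts + dur
  ))
}

#' Configuration for the slice-population generator
#'
#' Generative twin of the count-based reactivation estimator: each slice holds
#' `cells_per_slice` DAPI nuclei, of which a Binomial(tag_fraction) subset is
#' mCherry-tagged; tagged cells are c-Fos+ with probability `p_react_tagged`,
#' untagged with `p_active_untagged`. The implied chance-corrected enrichment
#' is `p_react_tagged / (tag_fraction * p_react_tagged +
#' (1 - tag_fraction) * p_active_untagged)` (see [implied_enrichment()]).
#'
#' @param n_slices number of slices.
#' @param cells_per_slice DAPI+ count per slice.
#' @param roi_area_mm2 ROI area per slice, mm^2.
#' @param tag_fraction probability a cell is mCherry+.
#' @param p_react_tagged probability a tagged cell is c-Fos+.
#' @param p_active_untagged probability an untagged cell is c-Fos+.
#' @param animal_id,region identifiers stamped on the slices.
#' @param intensity_mean,intensity_sd per-cell mean-fluorescence distribution
#'   for c-Fos+ cells (arbitrary units), used by
#'   [simulate_cell_intensities()].
#' @param tagged_intensity_shift additive intensity shift for mCherry+ cells.
#' @param seed integer RNG seed.
#' @return list of class `ensemble_sim_config`.
#' @export
ensemble_sim_config <- function(n_slices = 5, cells_per_slice = 2000,
                                roi_area_mm2 = 1.0, tag_fraction = 0.05,
                                p_react_tagged = 0.42,
                                p_active_untagged = 0.08275,
                                animal_id = "sim1", region = "LEC",
                                intensity_mean = 3.5, intensity_sd = 1.0,
                                tagged_intensity_shift = 0,
                                seed = 1L) {
  check_prob(tag_fraction, "tag_fraction")
  check_prob(p_react_tagged, "p_react_tagged")
  check_prob(p_active_untagged, "p_active_untagged")
  if (n_slices < 1 || cells_per_slice < 1)
    stop("n_slices and cells_per_slice must be positive integers")
  if (roi_area_mm2 <= 0) stop("roi_area_mm2 must be > 0")
  structure(list(n_slices = as.integer(n_slices),
                 cells_per_slice = as.integer(cells_per_slice),
                 roi_area_mm2 = roi_area_mm2, tag_fraction = tag_fraction,
                 p_react_tagged = p_react_tagged,
                 p_active_untagged = p_active_untagged,
                 animal_id = animal_id, region = region,
                 intensity_mean = intensity_mean,
                 intensity_sd = intensity_sd,
                 tagged_intensity_shift = tagged_intensity_shift,
                 seed = as.integer(seed)),
            class = "ensemble_sim_config")
}

#' Ground-truth enrichment implied by a generator configuration
#'
#' @param cfg an [ensemble_sim_config()].
#' @return the population value of the chance-corrected overlap,
#'   `p_react_tagged / (tag_fraction * p_react_tagged +
#'   (1 - tag_fraction) * p_active_untagged)`.
#' @export
implied_enrichment <- function(cfg) {
  stopifnot(inherits(cfg, "ensemble_sim_config"))
  denom <- cfg$tag_fraction * cfg$p_react_tagged +
    (1 - cfg$tag_fraction) * cfg$p_active_untagged
  if (denom <= 0) stop("overall c-Fos probability is 0; enrichment undefined")
  cfg$p_react_tagged / denom
}

#' Simulate slice-level cell-count tables
#'
#' @param cfg an [ensemble_sim_config()].
#' @return data frame with columns `animal_id`, `slice_id`, `region`,
#'   `area_mm2`, `n_dapi`, `n_cfos`, `n_mcherry`, `n_overlap` satisfying
#'   `n_overlap <= min(n_cfos, n_mcherry) <= n_dapi`.
#' @export
simulate_slice_counts <- function(cfg) {
  stopifnot(inherits(cfg, "ensemble_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_slices
  cells <- cfg$cells_per_slice
  n_mcherry <- stats::rbinom(n, cells, cfg$tag_fraction)
  n_overlap <- stats::rbinom(n, n_mcherry, cfg$p_react_tagged)
  n_cfos_untagged <- stats::rbinom(n, cells - n_mcherry, cfg$p_active_untagged)
  data.frame(
    animal_id = cfg$animal_id,
    slice_id = sprintf("slice%02d", seq_len(n)),
    region = cfg$region, area_mm2 = cfg$roi_area_mm2,
    n_dapi = cells, n_cfos = n_overlap + n_cfos_untagged,
    n_mcherry = n_mcherry, n_overlap = n_overlap
  )
}

#' Simulate per-cell intensity tables for c-Fos+ cells
#'
#' Draws one mean-fluorescence value per c-Fos+ cell of a simulated count
#' table: Normal(`intensity_mean`, `intensity_sd`), truncated positive, with
#' `tagged_intensity_shift` added for mCherry+ cells.
#'
#' @param counts a table from [simulate_slice_counts()].
#' @param cfg the [ensemble_sim_config()] used to generate it.
#' @return long-format data frame `animal_id`, `slice_id`, `cell_id`,
#'   `mcherry_flag`, `mean_intensity`.
#' @export
simulate_cell_intensities <- function(counts, cfg) {
  stopifnot(inherits(cfg, "ensemble_sim_config"))
  set.seed(cfg$seed + 1L)
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    n_pos <- counts$n_overlap[i]
    n_neg <- counts$n_cfos[i] - n_pos
    if (n_pos + n_neg == 0L) return(NULL)
    flag <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
    data.frame(
      animal_id = counts$animal_id[i], slice_id = counts$slice_id[i],
      cell_id = seq_along(flag), mcherry_flag = flag,
      mean_intensity = rtnorm(length(flag),
                              cfg$intensity_mean +
                                cfg$tagged_intensity_shift * flag,
                              cfg$intensity_sd)
    )
  })
  do.call(rbind, rows)
}

## --- spine generator ---------------------------------------------------

default_spine_class_params <- function() {
  # (mean, sd) of truncated-normal length and head max diameter per class,
  # centered >= ~2.5 sd inside each class's decision region so the threshold
  # classifier recovers the generating class with probability >= 0.95
  list(
    thin      = list(length = c(0.70, 0.10), head_max = c(0.48, 0.04)),
    long_thin = list(length = c(1.50, 0.18), head_max = c(0.48, 0.04)),
    mushroom  = list(length = c(1.00, 0.20), head_max = c(0.85, 0.08)),
    stubby    = list(length = c(0.30, 0.05), head_max = c(0.50, 0.04)),
    filopodia = list(length = c(2.80, 0.30), head_max = c(0.48, 0.04))
  )
}

#' Configuration for the synthetic spine-table generator
#'
#' Samples per-spine morphometric feature vectors from class-conditional
#' truncated-normal distributions centered inside each class's decision
#' region, with the generating class stored in a sidecar column for recovery
#' tests. The default mixture matches the per-20-um class proportions of an
#' amyloid-model mCherry control group (thin 0.268, long thin 0.335, mushroom
#' 0.207, stubby 0.033, filopodia 0.158).
#'
#' @param n_spines number of spines.
#' @param class_mixture 5 non-negative weights (thin, long_thin, mushroom,
#'   stubby, filopodia) summing to 1.
#' @param neckless_fraction probability a record lacks a neck (neck fields
#'   NA), exercising the refinement stage.
#' @param class_params per-class length/head-diameter (mean, sd) list; see
#'   the package default for the expected structure.
#' @param spines_per_segment,segments_per_neuron layout of spines onto
#'   dendrite segments (each segment represents 20 um of traced dendrite).
#' @param animal_id identifier stamped on the table.
#' @param seed integer RNG seed.
#' @return list of class `spine_sim_config`.
#' @export
spine_sim_config <- function(n_spines = 1000,
                             class_mixture = c(thin = 0.268,
                                               long_thin = 0.335,
                                               mushroom = 0.207,
                                               stubby = 0.033,
                                               filopodia = 0.157),
                             neckless_fraction = 0.1,
                             class_params = default_spine_class_params(),
                             spines_per_segment = 25,
                             segments_per_neuron = 2,
                             animal_id = "sim1", seed = 1L) {
  if (length(class_mixture) != 5L || any(class_mixture < 0))
    stop("class_mixture must be 5 non-negative weights")
  if (abs(sum(class_mixture) - 1) > 1e-9)
    stop("class_mixture must sum to 1 (got ", sum(class_mixture), ")")
  check_prob(neckless_fraction, "neckless_fraction")
  if (n_spines < 1) stop("n_spines must be a positive integer")
  names(class_mixture) <- spine_classes()
  structure(list(n_spines = as.integer(n_spines),
                 class_mixture = class_mixture,
                 neckless_fraction = neckless_fraction,
                 class_params = class_params,
                 spines_per_segment = as.integer(spines_per_segment),
                 segments_per_neuron = as.integer(segments_per_neuron),
                 animal_id = animal_id, seed = as.integer(seed)),
            class = "spine_sim_config")
}

#' Simulate a spine morphometric feature table
#'
#' @param cfg a [spine_sim_config()].
#' @return data frame, one row per spine, with identifiers (`spine_id`,
#'   `neuron_id`, `segment_id`, `animal_id`), the nine raw features of
#'   [spine_feature_names()] in um, a `dendrite_diameter` column, and the
#'   ground-truth `true_class` sidecar column. `neckless_fraction` of the
#'   rows have NA neck fields.
#' @export
simulate_spine_table <- function(cfg) {
  stopifnot(inherits(cfg, "spine_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_spines
  counts <- as.vector(stats::rmultinom(1, n, cfg$class_mixture))
  true_class <- rep(spine_classes(), counts)
  len <- head_max <- numeric(n)
  pos <- 1L
  for (i in seq_along(counts)) {
    if (counts[i] == 0L) next
    p <- cfg$class_params[[spine_classes()[i]]]
    idx <- pos:(pos + counts[i] - 1L)
    len[idx] <- rtnorm(counts[i], p$length[1], p$length[2])
    head_max[idx] <- rtnorm(counts[i], p$head_max[1], p$head_max[2])
    pos <- pos + counts[i]
  }
  ord <- sample.int(n)
  len <- len[ord]; head_max <- head_max[ord]; true_class <- true_class[ord]

  head_mean <- head_max * rtnorm(n, 0.85, 0.03)
  head_length <- pmin(len * rtnorm(n, 0.40, 0.05), 0.95 * len)
  neck_min <- rtnorm(n, 0.18, 0.03)
  neck_mean <- neck_min * rtnorm(n, 1.25, 0.05)
  neck_length <- pmax(len - head_length, 0.02) * rtnorm(n, 0.9, 0.05)
  neckless <- stats::rbinom(n, 1, cfg$neckless_fraction) == 1
  neck_min[neckless] <- neck_mean[neckless] <- neck_length[neckless] <- NA_real_

  seg_of <- (seq_len(n) - 1L) %/% cfg$spines_per_segment
  neuron_of <- seg_of %/% cfg$segments_per_neuron
  data.frame(
    spine_id = sprintf("sp%05d", seq_len(n)),
    animal_id = cfg$animal_id,
    neuron_id = sprintf("n%03d", neuron_of + 1L),
    segment_id = sprintf("seg%d", seg_of %% cfg$segments_per_neuron + 1L),
    length = len, head_max_diameter = head_max,
    head_mean_diameter = head_mean, head_length = head_length,
    neck_min_diameter = neck_min, neck_mean_diameter = neck_mean,
    neck_length = neck_length,
    attachment_diameter = rtnorm(n, 0.30, 0.05),
    straightness = stats::runif(n, 0.7, 1),
    dendrite_diameter = stats::runif(n, 2, 4),
    true_class = true_class
  )
}
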