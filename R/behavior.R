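#' Read a behavioral event log
#'
#' Parses a CSV of manually scored exploration bouts (one row per bout, in the
#' style of Chronotate marker exports) into a validated trial log. Required
#' columns are `object_label`, `t_start_s` and `t_stop_s`; `bout_index`,
#' `animal_id` and `trial_id` are used when present.
#'
#' @param path path to a CSV file.
#' @param animal_id,trial_id identifiers attached to the log when the file
#'   does not carry them.
#' @return A `trial_log`: a data frame with columns `animal_id`, `trial_id`,
#'   `bout_index`, `object_label`, `t_start_s`, `t_stop_s`, ordered by start
#'   time. An empty file yields a zero-row log.
#' @details Rows with `t_stop_s <= t_start_s` or missing fields abort with an
#'   error naming the offending row. Overlapping bouts (possible in manual
#'   scoring) raise a warning but are kept as recorded.
#' @export
read_event_log <- function(path, animal_id = NULL, trial_id = NULL) {
  if (!file.exists(path)) stop("event log not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    return(new_trial_log(data.frame(
      animal_id = character(), trial_id = character(),
      bout_index = integer(), object_label = character(),
      t_start_s = numeric(), t_stop_s = numeric()
    )))
  }
  needed <- c("object_label", "t_start_s", "t_stop_s")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L)
    stop("event log ", path, " is missing columns: ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(df$t_start_s) | !is.finite(df$t_stop_s) |
                 df$t_stop_s < df$t_start_s)
  if (length(bad) > 0L)
    stop("event log ", path, ": invalid bout (t_stop_s < t_start_s or ",
         "non-numeric timestamps) at row(s) ", paste(bad, collapse = ", "))
  if (is.null(df$animal_id)) df$animal_id <- animal_id %||% "animal1"
  if (is.null(df$trial_id))  df$trial_id  <- trial_id %||% "trial1"
  if (is.null(df$bout_index)) df$bout_index <- seq_len(nrow(df))
  df <- df[order(df$t_start_s),
           c("animal_id", "trial_id", "bout_index", "object_label",
             "t_start_s", "t_stop_s")]
  rownames(df) <- NULL
  warn_on_overlap(df)
  new_trial_log(df)
}

new_trial_log <- function(df) {
  class(df) <- c("trial_log", "data.frame")
  df
}

warn_on_overlap <- function(df) {
  if (nrow(df) < 2L) return(invisible(NULL))
  o <- order(df$t_start_s)
  n_overlap <- sum(df$t_start_s[o][-1] < df$t_stop_s[o][-nrow(df)])
  if (n_overlap > 0L)
    warning(n_overlap, " overlapping bout(s); summed as recorded")
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Discrimination index
#'
#' DI = (t_novel - t_familiar) / (t_novel + t_familiar): +1 means exclusive
#' exploration of the novel object, 0 no preference, -1 exclusive exploration
#' of the familiar object.
#'
#' @param t_novel,t_familiar non-negative exploration times (seconds);
#'   vectorized.
#' @return dimensionless values in \[-1, 1\]; `NA` (with a warning) where both
#'   times are zero, since the index is then undefined rather than 0.
#' @examples
#' discrimination_index(16.43, 9.9)  # 0.248 when rounded to 3 decimals
#' @export
discrimination_index <- function(t_novel, t_familiar) {
  if (any(t_novel < 0, na.rm = TRUE) || any(t_familiar < 0, na.rm = TRUE))
    stop("exploration times must be non-negative")
  total <- t_novel + t_familiar
  di <- ifelse(total > 0, (t_novel - t_familiar) / total, NA_real_)
  if (any(total == 0, na.rm = TRUE))
    warning("DI undefined for trial(s) with zero total exploration; NA returned")
  di
}

#' Summarize one trial
#'
#' Reduces a trial log to per-object exploration time, interaction (bout)
#' counts, the discrimination index, and optionally the total distance
#' travelled from a tracked body-center coordinate table.
#'
#' @param log a `trial_log` (see [read_event_log()]).
#' @param coords optional data frame with columns `x_cm`, `y_cm` (body-center
#'   track, one row per frame, in recording order) used for total distance.
#' @param novel_label which object label counts as "novel"; defaults to
#'   `"novel"`, falling back to `"object1"` for encoding-phase logs.
#' @return one-row data frame: `animal_id`, `trial_id`, `time_novel_s`,
#'   `time_familiar_s`, `bouts_novel`, `bouts_familiar`, `di`,
#'   `total_distance_cm` (`NA` without coordinates).
#' @export
summarize_trial <- function(log, coords = NULL, novel_label = NULL) {
  stopifnot(inherits(log, "trial_log") || is.data.frame(log))
  labels <- unique(log$object_label)
  if (is.null(novel_label))
    novel_label <- if ("novel" %in% labels || nrow(log) == 0L) "novel" else "object1"
  dur <- log$t_stop_s - log$t_start_s
  is_novel <- log$object_label == novel_label
  t_nov <- sum(dur[is_novel])
  t_fam <- sum(dur[!is_novel])
  # zero-duration bouts are scoring no-ops: not counted as interactions
  is_novel <- is_novel[dur > 0]
  di <- if (t_nov + t_fam > 0) (t_nov - t_fam) / (t_nov + t_fam) else NA_real_
  data.frame(
    animal_id = if (nrow(log)) log$animal_id[1] else NA_character_,
    trial_id  = if (nrow(log)) log$trial_id[1] else NA_character_,
    time_novel_s = t_nov, time_familiar_s = t_fam,
    bouts_novel = sum(is_novel), bouts_familiar = sum(!is_novel),
    di = di,
    total_distance_cm = if (is.null(coords)) NA_real_ else track_distance(coords)
  )
}

#' Total path length of a tracked coordinate series
#'
#' @param coords data frame with `x_cm`, `y_cm` columns in frame order.
#' @return sum of frame-to-frame Euclidean steps, in cm.
#' @export
track_distance <- function(coords) {
  stopifnot(all(c("x_cm", "y_cm") %in% names(coords)))
  if (nrow(coords) < 2L) return(0)
  sum(sqrt(diff(coords$x_cm)^2 + diff(coords$y_cm)^2))
}

#' Occupancy heatmap from a nose-position track
#'
#' Bins tracked positions into an `n_bins` x `n_bins` grid over the arena and
#' reports the percentage of total time spent in each cell (the grid sums to
#' 100 exactly).
#'
#' @param coords data frame with `x_cm`, `y_cm` columns (typically the nose
#'   marker), origin at an arena corner.
#' @param arena_size length-2 numeric, arena extent in cm (x, y).
#' @param n_bins bins per axis.
#' @return `n_bins` x `n_bins` matrix of percentages; `[i, j]` is the i-th x
#'   bin and j-th y bin.
#' @export
occupancy_heatmap <- function(coords, arena_size = c(40, 40), n_bins = 10) {
  stopifnot(all(c("x_cm", "y_cm") %in% names(coords)),
            length(arena_size) == 2L, all(arena_size > 0), n_bins >= 1)
  x <- coords$x_cm
  y <- coords$y_cm
  if (length(x) == 0L) stop("empty coordinate track")
  out_of_bounds <- x < 0 | x > arena_size[1] | y < 0 | y > arena_size[2]
  if (any(out_of_bounds)) {
    warning(sum(out_of_bounds), " sample(s) outside the arena; clipped to bounds")
    x <- pmin(pmax(x, 0), arena_size[1])
    y <- pmin(pmax(y, 0), arena_size[2])
  }
  bx <- pmin(pmax(ceiling(x / arena_size[1] * n_bins), 1L), n_bins)
  by <- pmin(pmax(ceiling(y / arena_size[2] * n_bins), 1L), n_bins)
  grid <- matrix(0, n_bins, n_bins)
  for (k in seq_along(bx)) grid[bx[k], by[k]] <- grid[bx[k], by[k]] + 1
  grid / length(bx) * 100
}

#' One-sample t test of discrimination indices against chance
#'
#' Tests whether a group's mean DI differs from the chance level of 0
#' (two-sided one-sample t test, animals as the unit).
#'
#' @param di numeric vector of per-animal discrimination indices (NA dropped).
#' @return list with `statistic` (t), `p.value`, `df`, `n`, `mean`, `sem`, and
#'   `degenerate` (TRUE when the sample variance is zero, in which case t is 0
#'   for an all-zero sample or signed infinity otherwise, and p is `NA`).
#' @export
di_vs_chance <- function(di) {
  di <- di[!is.na(di)]
  n <- length(di)
  if (n < 2L) stop("need at least 2 non-missing DI values")
  m <- mean(di)
  s <- stats::sd(di)
  if (s == 0) {
    t_stat <- if (m == 0) 0 else sign(m) * Inf
    return(list(statistic = t_stat, p.value = NA_real_, df = n - 1L,
                n = n, mean = m, sem = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(di, mu = 0)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter), n = n, mean = m, sem = s / sqrt(n),
       degenerate = FALSE)
}
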