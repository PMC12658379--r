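#' Refinement configuration for reconstructed spine tables
#'
#' Reconstruction artifacts are removed before analysis: protrusions lacking a
#' spine neck, spines below the minimum resolvable diameter, and (when the
#' parent dendrite diameter is recorded) spines on dendrites outside the
#' plausible diameter range used during tracing.
#'
#' @param dendrite_diameter_range permitted parent-dendrite diameters, um.
#' @param min_spine_diameter minimum head max diameter, um.
#' @param drop_neckless drop records whose neck diameter is absent.
#' @return list of class `refinement_config`.
#' @export
refinement_config <- function(dendrite_diameter_range = c(1, 5),
                              min_spine_diameter = 0.4,
                              drop_neckless = TRUE) {
  stopifnot(length(dendrite_diameter_range) == 2L,
            dendrite_diameter_range[1] < dendrite_diameter_range[2],
            min_spine_diameter > 0)
  structure(list(dendrite_diameter_range = dendrite_diameter_range,
                 min_spine_diameter = min_spine_diameter,
                 drop_neckless = isTRUE(drop_neckless)),
            class = "refinement_config")
}

#' Refine a reconstructed spine table
#'
#' @param spines data frame, one row per spine, um units; must contain
#'   `head_max_diameter`; `neck_min_diameter` (NA = neckless) and
#'   `dendrite_diameter` are used when present.
#' @param cfg a [refinement_config()].
#' @return list with `spines` (the retained rows) and `report` (named integer
#'   vector of removals per rule: `neckless`, `below_min_diameter`,
#'   `dendrite_out_of_range`). Rules are applied jointly; a spine failing
#'   several rules is counted under each.
#' @export
refine_spines <- function(spines, cfg = refinement_config()) {
  stopifnot(inherits(cfg, "refinement_config"),
            "head_max_diameter" %in% names(spines))
  neckless <- if (cfg$drop_neckless && "neck_min_diameter" %in% names(spines))
    is.na(spines$neck_min_diameter) else rep(FALSE, nrow(spines))
  too_small <- spines$head_max_diameter < cfg$min_spine_diameter
  dend_bad <- if ("dendrite_diameter" %in% names(spines))
    !is.na(spines$dendrite_diameter) &
      (spines$dendrite_diameter < cfg$dendrite_diameter_range[1] |
         spines$dendrite_diameter > cfg$dendrite_diameter_range[2])
  else rep(FALSE, nrow(spines))
  drop <- neckless | too_small | dend_bad
  list(spines = spines[!drop, , drop = FALSE],
       report = c(neckless = sum(neckless),
                  below_min_diameter = sum(too_small),
                  dendrite_out_of_range = sum(dend_bad),
                  removed = sum(drop), retained = sum(!drop)))
}

#' Spine surface area and volume from the frustum-plus-hemisphere solid
#'
#' The spine is modelled as a conical frustum from the attachment point
#' (radius `r_a`) to the head (radius `r_t`), capped by a terminal hemisphere
#' of radius `r_t`; the hemisphere at the attachment point is subtracted:
#' \deqn{V = \frac{\pi h}{3}(r_a^2 + r_a r_t + r_t^2) + \frac{2}{3}\pi r_t^3
#'        - \frac{2}{3}\pi r_a^3}
#' \deqn{A = \pi (r_a + r_t)\sqrt{h^2 + (r_a - r_t)^2} + 2\pi r_t^2
#'        - 2\pi r_a^2}
#' When `r_a = r_t` both reduce exactly to the cylinder of radius `r` and
#' height `h` (volume \eqn{\pi r^2 h}, lateral area \eqn{2\pi r h}).
#'
#' @param r_a attachment radius, um (> 0).
#' @param r_t terminal (head) radius, um (> 0).
#' @param h frustum height, um (> 0).
#' @return data frame with `surface_area` (um^2) and `volume` (um^3),
#'   vectorized over the inputs. A negative area (possible when
#'   `r_a > r_t` makes the subtracted attachment hemisphere dominate) is
#'   floored at 0 with a warning.
#' @export
frustum_geometry <- function(r_a, r_t, h) {
  if (any(r_a <= 0) || any(r_t <= 0) || any(h <= 0))
    stop("radii and height must be > 0")
  volume <- pi * h / 3 * (r_a^2 + r_a * r_t + r_t^2) +
    2 / 3 * pi * r_t^3 - 2 / 3 * pi * r_a^3
  area <- pi * (r_a + r_t) * sqrt(h^2 + (r_a - r_t)^2) +
    2 * pi * r_t^2 - 2 * pi * r_a^2
  if (any(area < 0)) {
    warning(sum(area < 0), " spine(s) with negative surface area floored at 0")
    area <- pmax(area, 0)
  }
  data.frame(surface_area = area, volume = volume)
}

#' Per-spine geometry from morphometric features
#'
#' Derives the frustum parameterization from the exported features — attachment
#' radius `attachment_diameter/2`, terminal radius `head_max_diameter/2`, and
#' frustum height `length - r_t` (the terminal hemisphere sits on top of the
#' frustum), floored at 1e-6 um — and appends `frustum_height`,
#' `surface_area` and `volume` columns.
#'
#' @param spines data frame with `length`, `head_max_diameter`,
#'   `attachment_diameter` (um).
#' @return `spines` with the three derived columns added.
#' @export
spine_geometry <- function(spines) {
  needed <- c("length", "head_max_diameter", "attachment_diameter")
  missing_cols <- setdiff(needed, names(spines))
  if (length(missing_cols) > 0L)
    stop("spine table missing columns: ", paste(missing_cols, collapse = ", "))
  r_a <- spines$attachment_diameter / 2
  r_t <- spines$head_max_diameter / 2
  h <- pmax(spines$length - r_t, 1e-6)
  geom <- frustum_geometry(r_a, r_t, h)
  spines$frustum_height <- h
  spines$surface_area <- geom$surface_area
  spines$volume <- geom$volume
  spines
}

#' Five-class threshold classification of dendritic spines
#'
#' Classifies each spine by head max diameter, length, and the length-to-width
#' ratio (LWR). The raw criteria — mushroom: head >= 0.6 um; stubby: LWR <= 1;
#' filopodia: length > 2 um; long thin: 1 < length <= 2 um; thin:
#' length <= 1 um — overlap, so a fixed precedence makes the rule set
#' exhaustive and mutually exclusive: mushroom, then stubby, then filopodia,
#' then long thin, then thin. The head-diameter boundary at exactly 0.6 um
#' belongs to mushroom.
#'
#' @param spines data frame with `length` and `head_max_diameter` (and
#'   `head_mean_diameter` if `width = "head_mean"`), um.
#' @param width which diameter defines the LWR denominator.
#' @return `spines` with `lwr` and `class_label` (factor with levels thin,
#'   long_thin, mushroom, stubby, filopodia) columns added.
#' @export
classify_spines <- function(spines, width = c("head_max", "head_mean")) {
  width <- match.arg(width)
  wcol <- if (width == "head_max") "head_max_diameter" else "head_mean_diameter"
  needed <- c("length", wcol, "head_max_diameter")
  missing_cols <- setdiff(unique(needed), names(spines))
  if (length(missing_cols) > 0L)
    stop("spine table missing columns: ", paste(missing_cols, collapse = ", "))
  bad <- which(!is.finite(spines$length) | !is.finite(spines[[wcol]]) |
                 spines$length <= 0 | spines[[wcol]] <= 0)
  if (length(bad) > 0L)
    stop("non-positive or missing length/width for spine row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  lwr <- spines$length / spines[[wcol]]
  head_max <- spines$head_max_diameter
  label <- ifelse(head_max >= 0.6, "mushroom",
           ifelse(lwr <= 1, "stubby",
           ifelse(spines$length > 2, "filopodia",
           ifelse(spines$length > 1, "long_thin", "thin"))))
  spines$lwr <- lwr
  spines$class_label <- factor(label, levels = spine_classes())
  spines
}

#' @rdname classify_spines
#' @export
spine_classes <- function() c("thin", "long_thin", "mushroom", "stubby", "filopodia")

#' Per-class spine counts per 20-um dendrite segment
#'
#' Scales raw per-segment class counts to a common 20-um normalization so
#' densities are comparable across segments, and reports the total density
#' (which equals the sum over classes exactly).
#'
#' @param spines classified spine table with `neuron_id`, `segment_id`,
#'   `class_label`.
#' @param segment_length_um traced length of each segment, um; either a single
#'   number applying to all segments or a data frame `neuron_id`, `segment_id`,
#'   `length_um`.
#' @param per one of `"segment"` (one row per segment), `"neuron"` or
#'   `"animal"` (means over segments within the unit; requires `neuron_id` /
#'   `animal_id` columns).
#' @return data frame with one row per unit: the five per-20-um class counts
#'   and `total_per_20um`.
#' @export
per_segment_counts <- function(spines, segment_length_um = 20,
                               per = c("segment", "neuron", "animal")) {
  per <- match.arg(per)
  needed <- c("neuron_id", "segment_id", "class_label")
  missing_cols <- setdiff(needed, names(spines))
  if (length(missing_cols) > 0L)
    stop("spine table missing columns: ", paste(missing_cols, collapse = ", "))
  seg_key <- interaction(spines$neuron_id, spines$segment_id, drop = TRUE)
  tab <- table(seg_key, factor(spines$class_label, levels = spine_classes()))
  seg_info <- do.call(rbind, lapply(split(spines, seg_key), function(g)
    data.frame(animal_id = if ("animal_id" %in% names(g)) g$animal_id[1] else NA,
               neuron_id = g$neuron_id[1], segment_id = g$segment_id[1])))
  if (is.data.frame(segment_length_um)) {
    lk <- interaction(segment_length_um$neuron_id,
                      segment_length_um$segment_id, drop = FALSE)
    len <- segment_length_um$length_um[match(rownames(tab), as.character(lk))]
    if (any(is.na(len))) stop("unknown segment length for segment(s) ",
                              paste(rownames(tab)[is.na(len)], collapse = ", "))
  } else {
    if (!is.finite(segment_length_um) || segment_length_um <= 0)
      stop("segment_length_um must be a positive length in um")
    len <- rep(segment_length_um, nrow(tab))
  }
  scaled <- sweep(unclass(tab), 1, 20 / len, `*`)
  out <- data.frame(seg_info, scaled, check.names = FALSE, row.names = NULL)
  out$total_per_20um <- rowSums(scaled)
  if (per == "segment") return(out)
  unit <- if (per == "neuron") interaction(out$animal_id, out$neuron_id, drop = TRUE)
          else factor(out$animal_id)
  num_cols <- c(spine_classes(), "total_per_20um")
  agg <- do.call(rbind, lapply(split(out, unit), function(g) {
    row <- g[1, setdiff(names(seg_info), if (per == "animal") c("neuron_id", "segment_id") else "segment_id"), drop = FALSE]
    row$n_segments <- nrow(g)
    for (cc in num_cols) row[[cc]] <- mean(g[[cc]])
    row
  }))
  rownames(agg) <- NULL
  agg
}

#' Cross-tabulate cluster assignments against morphological classes
#'
#' @param assignments cluster labels (one per spine).
#' @param class_labels morphological class labels (same spines, same order).
#' @return contingency table (clusters x classes) of absolute counts; the
#'   marginals equal the cluster sizes and class counts.
#' @export
cluster_class_crosstab <- function(assignments, class_labels) {
  if (length(assignments) != length(class_labels))
    stop("assignments and class_labels differ in length")
  table(cluster = assignments,
        class = factor(class_labels, levels = spine_classes()))
}
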