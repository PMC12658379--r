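#' Cell density per mm^2
#'
#' @param count non-negative cell count(s).
#' @param area_mm2 ROI area(s) in mm^2, strictly positive.
#' @return cells/mm^2.
#' @export
cell_density <- function(count, area_mm2) {
  if (any(area_mm2 <= 0)) stop("ROI area must be > 0 mm^2")
  if (any(count < 0)) stop("counts must be non-negative")
  count / area_mm2
}

#' Reactivation percentage within the tagged population
#'
#' Percentage of mCherry-tagged cells that are also c-Fos positive:
#' 100 * overlap / mCherry.
#'
#' @param n_overlap,n_mcherry non-negative integer counts (vectorized).
#' @return percentage in \[0, 100\]; `NA` with a warning where `n_mcherry` is 0
#'   (those slices carry no information about reactivation).
#' @export
reactivation_percentage <- function(n_overlap, n_mcherry) {
  if (any(n_overlap < 0) || any(n_mcherry < 0)) stop("counts must be non-negative")
  if (any(n_overlap > n_mcherry))
    stop("overlap count exceeds mCherry count")
  out <- ifelse(n_mcherry > 0, 100 * n_overlap / n_mcherry, NA_real_)
  if (any(n_mcherry == 0))
    warning(sum(n_mcherry == 0), " slice(s) with no mCherry+ cells excluded (NA)")
  out
}

#' Expected chance level of c-Fos/mCherry overlap
#'
#' Under independent labeling, the expected fraction of DAPI cells that are
#' double positive is (cFos/DAPI) * (mCherry/DAPI), computed per slice.
#'
#' @param n_cfos,n_mcherry,n_dapi non-negative counts; `n_dapi > 0`.
#' @return probability in \[0, 1\].
#' @export
chance_level <- function(n_cfos, n_mcherry, n_dapi) {
  if (any(n_dapi <= 0)) stop("DAPI count must be > 0")
  if (any(n_cfos < 0) || any(n_mcherry < 0)) stop("counts must be non-negative")
  (n_cfos / n_dapi) * (n_mcherry / n_dapi)
}

#' Chance-corrected overlap (enrichment, overlap-over-chance)
#'
#' Per-slice reactivation index: (overlap/DAPI) divided by the chance level.
#' A value of 1 means the tagged ensemble reactivates at chance; values above
#' 1 indicate preferential reactivation.
#'
#' @param n_overlap,n_cfos,n_mcherry,n_dapi per-slice counts (vectorized).
#' @return non-negative enrichment values; `NA` with a warning where chance is
#'   0 with zero overlap (uninformative slice). Chance 0 with positive overlap
#'   is an impossible count combination and errors.
#' @export
enrichment_index <- function(n_overlap, n_cfos, n_mcherry, n_dapi) {
  if (any(n_overlap > pmin(n_cfos, n_mcherry)))
    stop("overlap exceeds min(cFos, mCherry): inconsistent counts")
  chance <- chance_level(n_cfos, n_mcherry, n_dapi)
  if (any(chance == 0 & n_overlap > 0))
    stop("zero chance level with positive overlap: inconsistent counts")
  undef <- chance == 0
  if (any(undef))
    warning(sum(undef), " slice(s) with zero chance level excluded (NA)")
  ifelse(undef, NA_real_, (n_overlap / n_dapi) / chance)
}

#' Per-slice and per-animal reactivation summary
#'
#' Computes, for every slice, c-Fos and mCherry densities, the co-localization
#' percentage, overlap/DAPI, the chance level and the chance-corrected
#' enrichment, then averages each statistic over slices within animal
#' (unweighted by default, matching the convention that four to five sections
#' are averaged per animal); animals are the unit of downstream analysis.
#'
#' @param counts data frame with columns `animal_id`, `slice_id`, `region`,
#'   `area_mm2`, `n_dapi`, `n_cfos`, `n_mcherry`, `n_overlap`.
#' @param area_weighted if TRUE, per-animal means weight slices by ROI area.
#' @return object of class `reactivation_summary`: list with `per_slice` and
#'   `per_animal` data frames.
#' @export
reactivation_summary <- function(counts, area_weighted = FALSE) {
  validate_slice_counts(counts)
  ps <- counts
  ps$density_cfos <- cell_density(ps$n_cfos, ps$area_mm2)
  ps$density_mcherry <- cell_density(ps$n_mcherry, ps$area_mm2)
  ps$coloc_pct <- suppressWarnings(
    reactivation_percentage(ps$n_overlap, ps$n_mcherry))
  ps$overlap_over_dapi <- ps$n_overlap / ps$n_dapi
  ps$chance <- chance_level(ps$n_cfos, ps$n_mcherry, ps$n_dapi)
  ps$enrichment <- suppressWarnings(
    enrichment_index(ps$n_overlap, ps$n_cfos, ps$n_mcherry, ps$n_dapi))

  stats_cols <- c("density_cfos", "density_mcherry", "coloc_pct",
                  "overlap_over_dapi", "chance", "enrichment")
  key <- interaction(ps$animal_id, ps$region, drop = TRUE)
  groups <- split(ps, key)
  pa <- do.call(rbind, lapply(groups, function(g) {
    row <- data.frame(animal_id = g$animal_id[1], region = g$region[1],
                      n_slices = nrow(g))
    for (s in stats_cols) {
      v <- g[[s]]
      w <- if (area_weighted) g$area_mm2 else rep(1, nrow(g))
      ok <- !is.na(v)
      row[[s]] <- if (any(ok)) sum(v[ok] * w[ok]) / sum(w[ok]) else NA_real_
    }
    row
  }))
  rownames(pa) <- NULL
  dropped <- pa[rowSums(is.na(pa[stats_cols])) == length(stats_cols), ]
  if (nrow(dropped) > 0L)
    warning("animal(s) with no valid slice excluded: ",
            paste(dropped$animal_id, collapse = ", "))
  pa <- pa[rowSums(is.na(pa[stats_cols])) < length(stats_cols), ]
  structure(list(per_slice = ps, per_animal = pa,
                 area_weighted = area_weighted),
            class = "reactivation_summary")
}

#' @export
print.reactivation_summary <- function(x, ...) {
  cat("Reactivation summary:", nrow(x$per_slice), "slices,",
      nrow(x$per_animal), "animal x region means",
      if (x$area_weighted) "(area-weighted)" else "", "\n")
  cat("Per-animal means:\n")
  print(x$per_animal, digits = 4)
  invisible(x)
}

validate_slice_counts <- function(counts) {
  needed <- c("animal_id", "slice_id", "region", "area_mm2",
              "n_dapi", "n_cfos", "n_mcherry", "n_overlap")
  missing_cols <- setdiff(needed, names(counts))
  if (length(missing_cols) > 0L)
    stop("slice count table missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (any(counts$n_overlap > pmin(counts$n_cfos, counts$n_mcherry)))
    stop("n_overlap exceeds min(n_cfos, n_mcherry)")
  if (any(counts$n_cfos > counts$n_dapi) || any(counts$n_mcherry > counts$n_dapi))
    stop("label counts exceed DAPI count")
  if (any(counts$area_mm2 <= 0)) stop("area_mm2 must be > 0")
  invisible(counts)
}

#' Home-cage-normalized c-Fos density fold change
#'
#' Divides each behaviorally stimulated (encoding) animal's c-Fos density by
#' the mean density of the home-cage control group of the same genotype and
#' region, so a fold change of 1 means no activation above baseline.
#'
#' @param densities data frame with columns `animal_id`, `genotype`, `region`,
#'   `condition`, `density` (cells/mm^2, one row per animal x region).
#' @param hc_condition the label of the home-cage control condition.
#' @return data frame with per-animal `fold_change` plus per
#'   genotype x region x condition group `mean` and `sem` columns
#'   (`group_mean`, `group_sem`). The HC group itself normalizes to mean 1.
#' @export
fold_change_vs_homecage <- function(densities, hc_condition = "HC") {
  needed <- c("animal_id", "genotype", "region", "condition", "density")
  missing_cols <- setdiff(needed, names(densities))
  if (length(missing_cols) > 0L)
    stop("density table missing columns: ", paste(missing_cols, collapse = ", "))
  key <- interaction(densities$genotype, densities$region, drop = TRUE)
  out <- do.call(rbind, lapply(split(densities, key), function(g) {
    hc <- g$density[g$condition == hc_condition]
    if (length(hc) == 0L)
      stop("no home-cage ('", hc_condition, "') animals for genotype ",
           g$genotype[1], ", region ", g$region[1])
    g$fold_change <- g$density / mean(hc)
    g
  }))
  rownames(out) <- NULL
  gkey <- interaction(out$genotype, out$region, out$condition, drop = TRUE)
  gm <- tapply(out$fold_change, gkey, mean)
  gs <- tapply(out$fold_change, gkey, function(v) stats::sd(v) / sqrt(length(v)))
  out$group_mean <- as.numeric(gm[as.character(gkey)])
  out$group_sem <- as.numeric(gs[as.character(gkey)])
  out
}

#' Per-animal single-cell mean c-Fos intensity
#'
#' Averages per-cell mean fluorescence within slice, then over slices within
#' animal, separately for the total c-Fos+ population and the
#' mCherry+ / mCherry- partitions.
#'
#' @param intensities long-format data frame with columns `animal_id`,
#'   `slice_id`, `cell_id`, `mcherry_flag` (logical or 0/1), `mean_intensity`
#'   (arbitrary units, one row per c-Fos+ cell).
#' @param partition one of `"total"`, `"mcherry_pos"`, `"mcherry_neg"`.
#' @return data frame `animal_id`, `partition`, `mean_intensity`, `n_slices`.
#'   Slices with an empty partition are skipped for that partition with a
#'   warning.
#' @export
mean_cell_intensity <- function(intensities,
                                partition = c("total", "mcherry_pos",
                                              "mcherry_neg")) {
  partition <- match.arg(partition)
  needed <- c("animal_id", "slice_id", "mcherry_flag", "mean_intensity")
  missing_cols <- setdiff(needed, names(intensities))
  if (length(missing_cols) > 0L)
    stop("intensity table missing columns: ",
         paste(missing_cols, collapse = ", "))
  keep <- switch(partition,
                 total = rep(TRUE, nrow(intensities)),
                 mcherry_pos = as.logical(intensities$mcherry_flag),
                 mcherry_neg = !as.logical(intensities$mcherry_flag))
  sub <- intensities[keep, ]
  n_slices_all <- tapply(intensities$slice_id, intensities$animal_id,
                         function(s) length(unique(s)))
  if (nrow(sub) == 0L) stop("no cells in partition '", partition, "'")
  slice_key <- interaction(sub$animal_id, sub$slice_id, drop = TRUE)
  slice_means <- tapply(sub$mean_intensity, slice_key, mean)
  slice_animal <- tapply(sub$animal_id, slice_key, `[`, 1)
  n_used <- table(slice_animal)
  skipped <- sum(n_slices_all[names(n_used)] - as.numeric(n_used))
  if (skipped > 0)
    warning(skipped, " slice(s) with empty '", partition, "' partition skipped")
  am <- tapply(as.numeric(slice_means), as.character(slice_animal), mean)
  data.frame(animal_id = names(am), partition = partition,
             mean_intensity = as.numeric(am),
             n_slices = as.integer(n_used[names(am)]),
             row.names = NULL)
}
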