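test_that("density, colocalization and chance level follow their definitions", {
  expect_equal(cell_density(0, 1), 0)
  expect_equal(cell_density(150, 0.5), 300)
  expect_error(cell_density(10, 0), "> 0")

  expect_equal(reactivation_percentage(50, 50), 100)
  expect_equal(reactivation_percentage(0, 40), 0)
  expect_warning(rp <- reactivation_percentage(0, 0), "excluded")
  expect_true(is.na(rp))
  expect_error(reactivation_percentage(5, 3), "exceeds")

  expect_equal(chance_level(100, 50, 1000), 0.005)
  expect_equal(chance_level(0, 50, 1000), 0)
  expect_equal(chance_level(1000, 1000, 1000), 1)
  expect_error(chance_level(1, 1, 0), "> 0")
})

test_that("enrichment is exact at chance, scale-free, and guards bad counts", {
  expect_equal(enrichment_index(5, 100, 50, 1000), 1)
  expect_equal(enrichment_index(21, 100, 50, 1000), 4.2)
  # multiplying all counts by k leaves enrichment and coloc % unchanged
  for (k in c(2, 7)) {
    expect_equal(enrichment_index(21 * k, 100 * k, 50 * k, 1000 * k), 4.2)
    expect_equal(reactivation_percentage(21 * k, 50 * k),
                 reactivation_percentage(21, 50))
  }
  expect_error(enrichment_index(5, 0, 50, 1000), "inconsistent")
  expect_warning(e0 <- enrichment_index(0, 0, 50, 1000), "zero chance")
  expect_true(is.na(e0))
})

test_that("independence generator gives mean enrichment 1 over synthetic animals", {
  per_animal <- vapply(1:100, function(s) {
    cs <- simulate_slice_counts(ensemble_sim_config(
      n_slices = 5, cells_per_slice = 2000, tag_fraction = 0.05,
      p_react_tagged = 0.1, p_active_untagged = 0.1, seed = 1000L + s))
    mean(enrichment_index(cs$n_overlap, cs$n_cfos, cs$n_mcherry, cs$n_dapi))
  }, numeric(1))
  tt <- t.test(per_animal, mu = 1)
  expect_gt(tt$p.value, 0.01)
  expect_lt(abs(mean(per_animal) - 1),
            2 * sd(per_animal) / sqrt(length(per_animal)) + 0.02)
})

test_that("enrichment is stable under 50% uniform thinning of the cells", {
  thin_counts <- function(cs, keep = 0.5) {
    ov <- rbinom(nrow(cs), cs$n_overlap, keep)
    cf <- ov + rbinom(nrow(cs), cs$n_cfos - cs$n_overlap, keep)
    mc <- ov + rbinom(nrow(cs), cs$n_mcherry - cs$n_overlap, keep)
    rest <- rbinom(nrow(cs), cs$n_dapi - cs$n_cfos - cs$n_mcherry + cs$n_overlap,
                   keep)
    transform(cs, n_overlap = ov, n_cfos = cf, n_mcherry = mc,
              n_dapi = cf + mc - ov + rest)
  }
  set.seed(5)
  ratio <- vapply(1:100, function(s) {
    cs <- simulate_slice_counts(ensemble_sim_config(
      n_slices = 10, cells_per_slice = 4000, tag_fraction = 0.06,
      p_react_tagged = 0.35, p_active_untagged = 0.09, seed = 400L + s))
    th <- thin_counts(cs)
    mean(enrichment_index(th$n_overlap, th$n_cfos, th$n_mcherry, th$n_dapi)) /
      mean(enrichment_index(cs$n_overlap, cs$n_cfos, cs$n_mcherry, cs$n_dapi))
  }, numeric(1))
  expect_lt(abs(mean(ratio) - 1), 0.03)
})

test_that("per-animal aggregation averages slices and recovers the truth", {
  one <- data.frame(animal_id = "a1", slice_id = c("s1", "s2", "s3"),
                    region = "DG", area_mm2 = 0.8, n_dapi = 1000,
                    n_cfos = 100, n_mcherry = 50, n_overlap = 21)
  rs <- reactivation_summary(one)
  expect_equal(nrow(rs$per_animal), 1L)
  expect_equal(rs$per_animal$enrichment, 4.2)        # identical slices
  expect_equal(rs$per_animal$coloc_pct, 42)
  expect_equal(rs$per_animal$density_cfos, 125)

  single <- reactivation_summary(one[1, ])           # one-slice animal is fine
  expect_equal(single$per_animal$enrichment, 4.2)

  # parameter recovery: 6 animals x 5 slices at the moderate-enrichment config
  counts <- do.call(rbind, lapply(1:6, function(a)
    simulate_slice_counts(ensemble_sim_config(
      n_slices = 5, cells_per_slice = 2000, tag_fraction = 0.05,
      p_react_tagged = 0.25, p_active_untagged = 0.08514,
      animal_id = sprintf("m%d", a), region = "DG", seed = 500L + a))))
  pa <- reactivation_summary(counts)$per_animal
  lam <- implied_enrichment(ensemble_sim_config(
    tag_fraction = 0.05, p_react_tagged = 0.25, p_active_untagged = 0.08514))
  sem <- sd(pa$enrichment) / sqrt(nrow(pa))
  expect_lt(abs(mean(pa$enrichment) - lam), 2 * sem + 0.05)
})

test_that("home-cage fold change normalizes HC to 1 and matches group ratios", {
  d <- data.frame(
    animal_id = sprintf("m%d", 1:8),
    genotype = "WT", region = "CA3",
    condition = rep(c("HC", "encoding"), each = 4),
    density = c(90, 100, 105, 100, 220, 240, 230, 247))
  fc <- fold_change_vs_homecage(d)
  hc <- fc[fc$condition == "HC", ]
  expect_equal(mean(hc$fold_change), 1)              # HC against itself
  enc <- fc[fc$condition == "encoding", ]
  expect_equal(unique(enc$group_mean),
               mean(d$density[5:8]) / mean(d$density[1:4]))
  expect_error(fold_change_vs_homecage(d[d$condition != "HC", ]),
               "no home-cage")
})

test_that("single-cell intensity summaries average within slice then animal", {
  flat <- data.frame(animal_id = "a1", slice_id = rep(c("s1", "s2"), each = 3),
                     cell_id = 1:6, mcherry_flag = c(1, 0, 0, 1, 1, 0),
                     mean_intensity = 5.0)
  expect_equal(mean_cell_intensity(flat)$mean_intensity, 5.0)

  set.seed(3)
  mixed <- data.frame(animal_id = "a1",
                      slice_id = rep(c("s1", "s2"), each = 40),
                      cell_id = 1:80,
                      mcherry_flag = rep(c(TRUE, FALSE), 40),
                      mean_intensity = rnorm(80, 4, 0.5))
  tot <- mean_cell_intensity(mixed, "total")$mean_intensity
  pos <- mean_cell_intensity(mixed, "mcherry_pos")$mean_intensity
  neg <- mean_cell_intensity(mixed, "mcherry_neg")$mean_intensity
  expect_true(tot >= min(pos, neg) && tot <= max(pos, neg))  # convexity

  # recovery of a +2.0 intensity shift in the tagged population
  cfg <- ensemble_sim_config(n_slices = 5, cells_per_slice = 3000,
                             tag_fraction = 0.2, p_react_tagged = 0.5,
                             p_active_untagged = 0.2,
                             tagged_intensity_shift = 2.0, seed = 12L)
  ints <- simulate_cell_intensities(simulate_slice_counts(cfg), cfg)
  shift <- mean_cell_intensity(ints, "mcherry_pos")$mean_intensity -
    mean_cell_intensity(ints, "mcherry_neg")$mean_intensity
  expect_lt(abs(shift - 2.0), 0.2)
})
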