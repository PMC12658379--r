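test_that("refinement removes neckless and sub-threshold records with a report", {
  sp <- full_spine_row(n = 4)
  sp$neck_min_diameter[2] <- NA            # neckless
  sp$head_max_diameter[3] <- 0.3           # below the 0.4 um minimum
  sp$dendrite_diameter[4] <- 7             # outside 1-5 um
  ref <- refine_spines(sp)
  expect_equal(nrow(ref$spines), 1L)
  expect_equal(unname(ref$report[c("neckless", "below_min_diameter",
                                   "dendrite_out_of_range")]),
               c(1L, 1L, 1L))

  keep <- refine_spines(sp[2, ], refinement_config(drop_neckless = FALSE))
  expect_equal(nrow(keep$spines), 1L)

  big <- simulate_spine_table(spine_sim_config(n_spines = 1000,
                                               neckless_fraction = 0.2,
                                               seed = 2L))
  rep2 <- refine_spines(big)$report
  expect_lt(abs(rep2[["neckless"]] - 200), 4 * sqrt(1000 * 0.2 * 0.8))
})

test_that("frustum-plus-hemisphere geometry matches the integration oracle", {
  # equal radii: exact cylinder limit
  g <- frustum_geometry(0.2, 0.2, 1.5)
  expect_equal(g$volume, pi * 0.2^2 * 1.5)
  expect_equal(g$surface_area, 2 * pi * 0.2 * 1.5)

  # worked triple and random triples vs numerical solid of revolution
  set.seed(10)
  triples <- rbind(c(0.1, 0.3, 1.0),
                   cbind(runif(100, 0.05, 0.5), runif(100, 0.05, 0.5),
                         runif(100, 0.1, 3)))
  for (i in seq_len(nrow(triples))) {
    r_a <- triples[i, 1]; r_t <- triples[i, 2]; h <- triples[i, 3]
    ref <- oracle_geometry(r_a, r_t, h)
    got <- suppressWarnings(frustum_geometry(r_a, r_t, h))
    expect_lt(abs(got$volume / ref["volume"] - 1), 1e-3)
    if (ref["area"] > 0)
      expect_lt(abs(got$surface_area / ref["area"] - 1), 1e-3)
  }

  expect_error(frustum_geometry(0, 0.2, 1), "> 0")
  expect_error(frustum_geometry(0.1, 0.2, -1), "> 0")
  # wide attachment, tiny head: literal subtraction can go negative -> floored
  expect_warning(neg <- frustum_geometry(0.5, 0.1, 0.05), "floored")
  expect_equal(neg$surface_area, 0)
})

test_that("spine volume increases with height and terminal radius", {
  hs <- seq(0.2, 2, by = 0.2)
  vols_h <- frustum_geometry(0.1, 0.3, hs)$volume
  expect_true(all(diff(vols_h) > 0))
  rts <- seq(0.1, 0.5, by = 0.05)  # r_t >= r_a throughout
  vols_r <- frustum_geometry(0.1, rts, 1)$volume
  expect_true(all(diff(vols_r) > 0))
})

test_that("threshold classification follows the precedence and is total", {
  lab <- function(length, head) {
    as.character(classify_spines(data.frame(
      length = length, head_max_diameter = head,
      head_mean_diameter = head * 0.85))$class_label)
  }
  expect_equal(lab(0.8, 0.5), "thin")          # LWR 1.6, small head, short
  expect_equal(lab(2.5, 0.4), "filopodia")     # length > 2 um
  expect_equal(lab(1.5, 0.45), "long_thin")
  expect_equal(lab(0.4, 0.5), "stubby")        # LWR <= 1
  expect_equal(lab(1.0, 0.9), "mushroom")
  expect_equal(lab(1.0, 0.6), "mushroom")      # boundary owned by mushroom
  expect_equal(lab(0.5, 0.6), "mushroom")      # head rule precedes stubby
  expect_equal(lab(2.0, 0.45), "long_thin")    # length boundary at 2 um
  expect_equal(lab(1.0, 0.45), "thin")         # length boundary at 1 um

  expect_error(classify_spines(data.frame(length = 1)), "missing columns")
  expect_error(classify_spines(data.frame(length = -1, head_max_diameter = 0.5,
                                          head_mean_diameter = 0.4)),
               "non-positive")

  # totality and single-valuedness over a dense random grid
  set.seed(1)
  grid <- data.frame(length = runif(20000, 0.05, 4),
                     head_max_diameter = runif(20000, 0.05, 1.5))
  grid$head_mean_diameter <- grid$head_max_diameter * 0.85
  cl <- classify_spines(grid)
  expect_false(any(is.na(cl$class_label)))
  expect_true(all(as.character(cl$class_label) %in% spine_classes()))
})

test_that("per-segment counts normalize to 20 um and add up exactly", {
  sp <- classify_spines(simulate_spine_table(
    spine_sim_config(n_spines = 500, neckless_fraction = 0, seed = 6L)))
  seg <- per_segment_counts(sp)
  expect_equal(rowSums(seg[, spine_classes()]), seg$total_per_20um)

  # doubling every spine doubles densities, leaves proportions fixed
  sp2 <- rbind(sp, transform(sp, spine_id = paste0(spine_id, "b")))
  seg2 <- per_segment_counts(sp2)
  expect_equal(seg2$total_per_20um, 2 * seg$total_per_20um)
  expect_equal(as.matrix(seg2[, spine_classes()]) / seg2$total_per_20um,
               as.matrix(seg[, spine_classes()]) / seg$total_per_20um)

  # non-default traced length rescales to the 20-um convention
  seg40 <- per_segment_counts(sp, segment_length_um = 40)
  expect_equal(seg40$total_per_20um, seg$total_per_20um / 2)
  expect_error(per_segment_counts(sp, segment_length_um = 0), "positive")

  an <- per_segment_counts(sp, per = "animal")
  expect_equal(nrow(an), 1L)
  expect_equal(an$total_per_20um, mean(seg$total_per_20um))
})

test_that("cluster-class crosstab conserves marginals", {
  cls <- factor(rep(spine_classes(), times = c(5, 4, 3, 2, 1)),
                levels = spine_classes())
  aligned <- as.integer(cls)
  xt <- cluster_class_crosstab(aligned, cls)
  expect_true(all(xt[row(xt) != col(xt)] == 0))     # diagonal when aligned
  expect_equal(unname(rowSums(xt)), c(5, 4, 3, 2, 1))
  expect_equal(unname(colSums(xt)), c(5, 4, 3, 2, 1))
  expect_error(cluster_class_crosstab(1:3, cls), "length")

  # independent labels: no association detectable by chi-square
  set.seed(14)
  cl_rand <- sample(1:4, 5000, replace = TRUE)
  cls_rand <- factor(sample(spine_classes(), 5000, replace = TRUE),
                     levels = spine_classes())
  xt2 <- cluster_class_crosstab(cl_rand, cls_rand)
  expect_gt(suppressWarnings(chisq.test(xt2)$p.value), 0.001)
})
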