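#' Assemble a pipeline run configuration
#'
#' @param out_dir output directory (created if absent).
#' @param seed integer seed governing every stochastic stage.
#' @param groups named character vector mapping `animal_id` to group label.
#' @param behavior_logs character vector of event-log CSV paths (optional).
#' @param counts path to a slice-count CSV (optional).
#' @param intensities path to a long-format intensity CSV (optional).
#' @param spines path to a spine feature CSV (optional).
#' @param segment_length_um traced length per dendrite segment, um.
#' @param k number of spine clusters (`NULL` = elbow selection).
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, groups = character(),
                       behavior_logs = NULL, counts = NULL,
                       intensities = NULL, spines = NULL,
                       segment_length_um = 20, k = 5) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), groups = groups,
                 behavior_logs = behavior_logs, counts = counts,
                 intensities = intensities, spines = spines,
                 segment_length_um = segment_length_um, k = k),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; `groups` is a mapping from
#' animal id to group label.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(out_dir = y$out_dir %||% ".",
             seed = y$seed %||% 1L,
             groups = unlist(y$groups),
             behavior_logs = y$behavior_logs, counts = y$counts,
             intensities = y$intensities, spines = y$spines,
             segment_length_um = y$segment_length_um %||% 20,
             k = y$k %||% 5)
}

#' Validate pipeline inputs
#'
#' Schema checks for every referenced CSV, count-consistency checks
#' (overlap <= min(cFos, mCherry) <= DAPI, positive ROI areas), and
#' referential integrity between the inputs and the group map.
#'
#' @param cfg a `run_config`.
#' @return data frame with columns `stage`, `item`, `problem`; zero rows when
#'   everything passes.
#' @export
validate_inputs <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  v <- list()
  note <- function(stage, item, problem)
    v[[length(v) + 1L]] <<- data.frame(stage = stage, item = item,
                                       problem = problem)
  animals <- character()
  for (p in cfg$behavior_logs) {
    if (!file.exists(p)) { note("behavior", p, "file not found"); next }
    log <- tryCatch(suppressWarnings(read_event_log(p)),
                    error = function(e) {
                      note("behavior", p, conditionMessage(e)); NULL
                    })
    if (!is.null(log) && nrow(log)) animals <- c(animals, unique(log$animal_id))
  }
  if (!is.null(cfg$counts)) {
    if (!file.exists(cfg$counts)) note("ensembles", cfg$counts, "file not found")
    else {
      counts <- utils::read.csv(cfg$counts)
      err <- tryCatch({ validate_slice_counts(counts); NULL },
                      error = function(e) conditionMessage(e))
      if (!is.null(err)) note("ensembles", cfg$counts, err)
      else animals <- c(animals, unique(counts$animal_id))
    }
  }
  if (!is.null(cfg$spines)) {
    if (!file.exists(cfg$spines)) note("spines", cfg$spines, "file not found")
    else {
      sp <- utils::read.csv(cfg$spines)
      need <- c("neuron_id", "segment_id", "length", "head_max_diameter")
      miss <- setdiff(need, names(sp))
      if (length(miss))
        note("spines", cfg$spines,
             paste("missing columns:", paste(miss, collapse = ", ")))
      else {
        present <- intersect(spine_feature_names()[1:9], names(sp))
        neg <- vapply(present, function(cc) any(sp[[cc]] <= 0, na.rm = TRUE),
                      logical(1))
        if (any(neg))
          note("spines", cfg$spines,
               paste("non-positive feature values in:",
                     paste(present[neg], collapse = ", ")))
        if ("animal_id" %in% names(sp))
          animals <- c(animals, unique(sp$animal_id))
      }
    }
  }
  unmapped <- setdiff(unique(animals), names(cfg$groups))
  if (length(cfg$groups) && length(unmapped))
    note("groups", paste(unmapped, collapse = ", "),
         "animal(s) missing from the group map")
  if (length(v) == 0L)
    return(data.frame(stage = character(), item = character(),
                      problem = character()))
  do.call(rbind, v)
}

mean_sem <- function(x) {
  x <- x[!is.na(x)]
  data.frame(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)),
             n = length(x))
}

group_table <- function(values, groups, stat_name) {
  out <- do.call(rbind, lapply(split(values, groups), mean_sem))
  out <- data.frame(group = rownames(out), statistic = stat_name, out,
                    row.names = NULL)
  out
}

write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Scores every behavior log, summarizes the slice-count table into per-animal
#' reactivation statistics, classifies and clusters the spine table, and
#' writes per-animal audit tables, group tables (mean +/- SEM with animals as
#' the statistical unit), and a JSON manifest with an MD5 hash of every output
#' file. Deterministic given the config seed. Stages whose inputs are absent
#' are skipped and noted in the manifest.
#'
#' @param cfg a `run_config`.
#' @return (invisibly) a `group_report` list: `behavior`, `reactivation`,
#'   `spines`, `group_tables`, `tests`, `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  problems <- validate_inputs(cfg)
  if (nrow(problems) > 0L) {
    print(problems)
    stop("input validation failed with ", nrow(problems), " problem(s)")
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  stages <- character()
  group_of <- function(ids) {
    if (length(cfg$groups) == 0L) rep("all", length(ids))
    else unname(cfg$groups[ids])
  }
  report <- list()
  group_tables <- list()
  tests <- list()

  if (length(cfg$behavior_logs)) {
    stages <- c(stages, "behavior")
    summaries <- do.call(rbind, lapply(cfg$behavior_logs, function(p)
      summarize_trial(suppressWarnings(read_event_log(p)))))
    summaries$group <- group_of(summaries$animal_id)
    report$behavior <- summaries
    files <- c(files, write_table(summaries,
                                  file.path(cfg$out_dir, "behavior_per_animal.csv")))
    group_tables$di <- group_table(summaries$di, summaries$group, "di")
    for (g in unique(summaries$group)) {
      di <- summaries$di[summaries$group == g]
      if (sum(!is.na(di)) >= 2) {
        tt <- di_vs_chance(di)
        tests[[length(tests) + 1L]] <- data.frame(
          group = g, test = "one-sample t, DI vs 0",
          statistic = tt$statistic, df = tt$df, p.value = tt$p.value,
          n = tt$n)
      }
    }
  }

  if (!is.null(cfg$counts)) {
    stages <- c(stages, "ensembles")
    counts <- utils::read.csv(cfg$counts)
    rs <- suppressWarnings(reactivation_summary(counts))
    pa <- rs$per_animal
    pa$group <- group_of(pa$animal_id)
    report$reactivation <- pa
    files <- c(files,
               write_table(rs$per_slice,
                           file.path(cfg$out_dir, "reactivation_per_slice.csv")),
               write_table(pa,
                           file.path(cfg$out_dir, "reactivation_per_animal.csv")))
    for (s in c("density_cfos", "coloc_pct", "enrichment"))
      group_tables[[s]] <- group_table(pa[[s]],
                                       interaction(pa$group, pa$region), s)
  }

  if (!is.null(cfg$spines)) {
    stages <- c(stages, "spines")
    sp <- utils::read.csv(cfg$spines)
    ref <- refine_spines(sp)
    if (ref$report[["removed"]] > 0)
      warning("refinement removed ", ref$report[["removed"]], " spine(s) (",
              paste(names(ref$report)[1:3], ref$report[1:3], collapse = ", "),
              ")")
    sp <- classify_spines(spine_geometry(ref$spines))
    counts20 <- per_segment_counts(sp, cfg$segment_length_um, per = "animal")
    counts20$group <- group_of(counts20$animal_id)
    report$spines <- counts20
    fm <- suppressWarnings(spine_feature_matrix(sp))
    cl <- cluster_spines(fm, k = cfg$k, seed = cfg$seed)
    used <- sp[attr(fm, "spine_rows"), ]
    assignments <- data.frame(spine_id = used$spine_id,
                              cluster = cl$cluster,
                              class_label = used$class_label)
    xtab <- cluster_class_crosstab(cl$cluster, used$class_label)
    report$spine_clusters <- cl
    files <- c(files,
               write_table(sp, file.path(cfg$out_dir, "spines_classified.csv")),
               write_table(counts20,
                           file.path(cfg$out_dir, "spine_counts_per_20um.csv")),
               write_table(assignments,
                           file.path(cfg$out_dir, "spine_cluster_assignments.csv")),
               write_table(as.data.frame.matrix(xtab),
                           file.path(cfg$out_dir, "spine_cluster_class_crosstab.csv")))
    for (cls in spine_classes())
      group_tables[[paste0("spines_", cls)]] <-
        group_table(counts20[[cls]], counts20$group, paste0(cls, "_per_20um"))
  }

  gt <- do.call(rbind, c(group_tables, list(make.row.names = FALSE)))
  report$group_tables <- gt
  report$tests <- if (length(tests)) do.call(rbind, tests) else NULL
  if (!is.null(gt))
    files <- c(files, write_table(gt, file.path(cfg$out_dir, "group_tables.csv")))
  if (!is.null(report$tests))
    files <- c(files, write_table(report$tests,
                                  file.path(cfg$out_dir, "tests.csv")))

  manifest <- list(seed = cfg$seed, stages = stages,
                   skipped = setdiff(c("behavior", "ensembles", "spines"),
                                     stages),
                   files = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  report$manifest <- manifest
  class(report) <- "group_report"
  invisible(report)
}

#' @export
print.group_report <- function(x, ...) {
  cat("Pipeline report; stages run:", paste(x$manifest$stages, collapse = ", "),
      "\n")
  if (!is.null(x$group_tables)) {
    cat("Group tables (mean +/- SEM, animals as unit):\n")
    print(x$group_tables, digits = 4)
  }
  if (!is.null(x$tests)) {
    cat("Tests:\n")
    print(x$tests, digits = 4)
  }
  invisible(x)
}

#' Simulate a complete demo study and analyze it end to end
#'
#' Generates two groups of animals (an `enriched` group whose tagged ensemble
#' reactivates far above chance and shows a novel-object preference, and a
#' `chance` group at independence with no preference), writes the CSV inputs,
#' runs [run_pipeline()], and returns the report together with the
#' ground-truth generative parameters for recovery checks.
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param n_animals animals per group.
#' @param slices_per_animal slices per animal.
#' @param cells_per_slice DAPI cells per slice.
#' @param n_spines spines in the shared spine table.
#' @return list with `report` (the `group_report`), `config` (the
#'   `run_config`) and `truth` (generative parameters).
#' @export
simulate_study <- function(out_dir, seed = 1L, n_animals = 6,
                           slices_per_animal = 5, cells_per_slice = 2000,
                           n_spines = 1000) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- list(
    enriched = list(preference_novel = 0.75, tag_fraction = 0.05,
                    p_react_tagged = 0.42, p_active_untagged = 0.08275),
    chance = list(preference_novel = 0.5, tag_fraction = 0.05,
                  p_react_tagged = 0.09, p_active_untagged = 0.09)
  )
  groups <- character()
  logs <- character()
  counts <- list()
  i <- 0L
  for (g in names(truth)) {
    p <- truth[[g]]
    for (a in seq_len(n_animals)) {
      i <- i + 1L
      id <- sprintf("%s_%02d", g, a)
      groups[id] <- g
      log <- simulate_trial_log(behavior_sim_config(
        preference_novel = p$preference_novel, n_bouts = 40,
        animal_id = id, seed = seed + 13L * i))
      logs[i] <- file.path(out_dir, paste0("log_", id, ".csv"))
      utils::write.csv(log, logs[i], row.names = FALSE)
      counts[[i]] <- simulate_slice_counts(ensemble_sim_config(
        n_slices = slices_per_animal, cells_per_slice = cells_per_slice,
        tag_fraction = p$tag_fraction, p_react_tagged = p$p_react_tagged,
        p_active_untagged = p$p_active_untagged, animal_id = id,
        seed = seed + 13L * i + 7L))
    }
  }
  counts_path <- file.path(out_dir, "slice_counts.csv")
  utils::write.csv(do.call(rbind, counts), counts_path, row.names = FALSE)
  spines <- simulate_spine_table(spine_sim_config(
    n_spines = n_spines, animal_id = names(groups)[1], seed = seed + 3L))
  spines_path <- file.path(out_dir, "spines.csv")
  utils::write.csv(spines, spines_path, row.names = FALSE)
  cfg <- run_config(out_dir = file.path(out_dir, "results"), seed = seed,
                    groups = groups, behavior_logs = logs,
                    counts = counts_path, spines = spines_path)
  list(report = run_pipeline(cfg), config = cfg, truth = truth)
}
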