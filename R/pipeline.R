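#' Configuration for the end-to-end analysis pipeline
#'
#' Bundles the inputs (either a synthetic-cohort [sim_config()] or paths to
#' visits/characteristics CSVs) with the analysis settings: linkage rule,
#' dendrogram cut fraction (default 0.9, the 90%-height cut), connectivity
#' neighbourhood (default 10), DTW open-end flag, bootstrap iterations
#' (default 1000 iterations of an 80/20 patient split) and the seed.
#'
#' @param sim a [sim_config()], or `NULL` to read CSV input.
#' @param visits_path,characteristics_path CSV input paths (used when `sim`
#'   is `NULL`).
#' @param min_visits inclusion threshold for [filter_cohort()].
#' @param linkage linkage rule for clustering.
#' @param cut_fraction dendrogram height-cut fraction.
#' @param neighbors connectivity neighbourhood size.
#' @param open_end DTW open-end flag.
#' @param bootstrap_iter bootstrap iterations for model comparison.
#' @param train_frac bootstrap training fraction.
#' @param seed integer seed governing every stochastic step.
#' @param out_dir optional directory for CSV/JSON artifacts; created if
#'   missing. `NULL` keeps everything in memory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            visits_path = NULL, characteristics_path = NULL,
                            min_visits = 3L,
                            linkage = "complete", cut_fraction = 0.9,
                            neighbors = 10L, open_end = TRUE,
                            bootstrap_iter = 1000L, train_frac = 0.8,
                            seed = 1L, out_dir = NULL) {
  if (is.null(sim) && is.null(visits_path)) {
    stop("either a simulator config or a visits CSV path is required")
  }
  structure(list(sim = sim, visits_path = visits_path,
                 characteristics_path = characteristics_path,
                 min_visits = as.integer(min_visits),
                 linkage = linkage, cut_fraction = cut_fraction,
                 neighbors = as.integer(neighbors), open_end = open_end,
                 bootstrap_iter = as.integer(bootstrap_iter),
                 train_frac = train_frac,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full time-aware analysis pipeline
#'
#' Executes, in order: (1) data acquisition and preprocessing (simulate or
#' read, filter to >= `min_visits` visits, cohort-wide z-normalization);
#' (2) magnitude-based clustering of all patients (per-patient summary
#' vectors, Euclidean distances, agglomerative clustering, height-fraction
#' cut, connectivity/Dunn, classical and isotonic MDS); (3) per-group
#' time-agnostic LOPO regression; (4) time-dependent vs time-agnostic
#' regression of the large group with paired bootstrap comparison; (5) DTW
#' clustering of the large group into subgroups; (6) per-subgroup LOPO
#' regression; (7) association of the subgroup labels with the binary
#' clinical characteristics. The same seed yields an identical report.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `pipeline_report` with one entry per stage, each
#'   carrying `status` ("ok"/"failed") and that stage's results. When
#'   `config$out_dir` is set, intermediate artifacts and `report.json` are
#'   written there.
#' @export
run_full_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  report <- list()
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      report[[name]] <<- list(status = "failed",
                              error = conditionMessage(res))
    } else {
      report[[name]] <<- c(list(status = "ok"), res)
    }
    invisible(NULL)
  }

  run_stage("preprocess", function() {
    if (!is.null(config$sim)) {
      simmed <- simulate_cohort(config$sim)
      raw <- simmed$cohort
      state$truth <- simmed$truth
    } else {
      raw <- read_cohort(config$visits_path, config$characteristics_path)
    }
    filtered <- suppressMessages(filter_cohort(raw, config$min_visits))
    state$cohort <- z_normalize(filtered)
    if (!is.null(out_dir)) {
      write_cohort(state$cohort, file.path(out_dir, "normalized_visits.csv"),
                   file.path(out_dir, "characteristics.csv"))
    }
    list(n_patients = n_patients(state$cohort),
         n_visits = nrow(state$cohort$visits),
         n_excluded = n_patients(raw) - n_patients(state$cohort))
  })

  run_stage("magnitude_clustering", function() {
    cohort <- state$cohort
    summ <- summarize_patients(cohort)
    dmat <- euclidean_distance_matrix(summ)
    hc <- agglomerative_cluster(dmat, config$linkage)
    labels <- cut_at_height_fraction(hc, config$cut_fraction)
    state$group_labels <- labels
    sizes <- sort(table(labels), decreasing = TRUE)
    state$main_group <- names(labels)[labels == as.integer(names(sizes)[1])]
    conn <- connectivity(dmat, labels,
                         min(config$neighbors, nrow(dmat) - 1))
    dn <- tryCatch(dunn_index(dmat, labels), error = function(e) NA_real_)
    cmds <- classical_mds(dmat)
    imds <- isotonic_mds(dmat)
    if (!is.null(out_dir)) {
      write_distance_matrix(dmat, file.path(out_dir, "euclidean_dist.csv"))
      utils::write.csv(data.frame(patient_id = names(labels),
                                  cluster = as.vector(labels)),
                       file.path(out_dir, "group_labels.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(data.frame(patient_id = imds$ids, imds$coords),
                       file.path(out_dir, "isotonic_mds.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    list(k = attr(labels, "k"),
         cluster_sizes = as.list(setNames(as.integer(sizes), names(sizes))),
         connectivity = conn, dunn = dn,
         isotonic_stress = imds$stress)
  })

  run_stage("regression_by_group", function() {
    cohort <- state$cohort
    labels <- state$group_labels
    res <- list(all = error_summary(suppressWarnings(
      lopo_cv(cohort, "time_agnostic"))))
    for (g in sort(unique(labels))) {
      ids <- names(labels)[labels == g]
      if (length(ids) < 3) next
      sub <- subset_cohort(cohort, ids)
      res[[paste0("group", g)]] <- tryCatch(
        error_summary(suppressWarnings(lopo_cv(sub, "time_agnostic"))),
        error = function(e) list(note = conditionMessage(e)))
    }
    res
  })

  run_stage("time_dependent_regression", function() {
    sub <- subset_cohort(state$cohort, state$main_group)
    state$group1 <- sub
    sa <- bootstrap_error(sub, "time_agnostic", config$bootstrap_iter,
                          config$train_frac, seed = config$seed)
    sd_ <- bootstrap_error(sub, "time_dependent", config$bootstrap_iter,
                           config$train_frac, seed = config$seed)
    cmp <- compare_models(sa, sd_)
    lopo_a <- error_summary(suppressWarnings(lopo_cv(sub, "time_agnostic")))
    lopo_d <- error_summary(suppressWarnings(lopo_cv(sub, "time_dependent")))
    list(free_parameters_agnostic = 18L, free_parameters_dependent = 35L,
         lopo_mse_agnostic = lopo_a$mean_square,
         lopo_mse_dependent = lopo_d$mean_square,
         bootstrap_mean_diff = cmp$mean_diff,
         bootstrap_ci = c(cmp$ci_low, cmp$ci_high),
         bootstrap_p = cmp$p)
  })

  run_stage("dtw_clustering", function() {
    sub <- state$group1
    dmat <- dtw_distance_matrix(sub, config$open_end)
    hc <- agglomerative_cluster(dmat, config$linkage)
    labels <- cut_at_height_fraction(hc, config$cut_fraction)
    state$subgroup_labels <- labels
    conn <- connectivity(dmat, labels, min(config$neighbors, nrow(dmat) - 1))
    dn <- tryCatch(dunn_index(dmat, labels), error = function(e) NA_real_)
    if (!is.null(out_dir)) {
      write_distance_matrix(dmat, file.path(out_dir, "dtw_dist.csv"))
      utils::write.csv(data.frame(patient_id = names(labels),
                                  subgroup = as.vector(labels)),
                       file.path(out_dir, "subgroup_labels.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    sizes <- sort(table(labels), decreasing = TRUE)
    list(k = attr(labels, "k"),
         subgroup_sizes = as.list(setNames(as.integer(sizes), names(sizes))),
         connectivity = conn, dunn = dn)
  })

  run_stage("regression_by_subgroup", function() {
    labels <- state$subgroup_labels
    res <- list()
    for (g in sort(unique(labels))) {
      ids <- names(labels)[labels == g]
      if (length(ids) < 3) next
      sub <- subset_cohort(state$cohort, ids)
      mse <- function(mode) tryCatch(
        error_summary(suppressWarnings(lopo_cv(sub, mode)))$mean_square,
        error = function(e) NA_real_)  # too few rows for the mode
      res[[paste0("subgroup", g)]] <- list(
        n_patients = length(ids),
        time_agnostic = mse("time_agnostic"),
        time_dependent = mse("time_dependent"))
    }
    res
  })

  run_stage("association", function() {
    labels <- state$subgroup_labels
    ch <- state$cohort$characteristics
    if (is.null(ch) || ncol(ch) < 2) {
      return(list(note = "no characteristics table; association skipped"))
    }
    two <- labels
    if (length(unique(two)) != 2) {
      # collapse to largest-vs-rest when the cut produced more than 2 groups
      main <- names(which.max(table(two)))
      two <- setNames(ifelse(two == as.integer(main), 1L, 2L), names(two))
    }
    tab <- associate_all(two, ch)
    if (!is.null(out_dir)) {
      utils::write.csv(tab, file.path(out_dir, "association.csv"),
                       row.names = FALSE, quote = FALSE)
    }
    list(table = tab)
  })

  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) {
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", force = TRUE)
  }
  report
}

#' Restrict a cohort to a subset of patients
#'
#' @param cohort an `sle_cohort`.
#' @param ids patient ids to keep.
#' @return The restricted `sle_cohort` (normalization flag preserved; values
#'   are NOT re-normalized).
#' @export
subset_cohort <- function(cohort, ids) {
  stopifnot(inherits(cohort, "sle_cohort"))
  missing_ids <- setdiff(ids, cohort_ids(cohort))
  if (length(missing_ids) > 0) {
    stop("unknown patient id(s): ", paste(missing_ids, collapse = ", "))
  }
  visits <- cohort$visits[cohort$visits$patient_id %in% ids, , drop = FALSE]
  ch <- cohort$characteristics
  if (!is.null(ch)) ch <- ch[ch$patient_id %in% ids, , drop = FALSE]
  out <- sle_cohort(visits, ch, normalized = cohort$normalized)
  # subsetting breaks the pooled mean-0/sd-1 property; keep the flag but do
  # not re-validate it downstream
  attr(out, "subset") <- TRUE
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-26s %s\n", nm, x[[nm]]$status))
  }
  invisible(x)
}
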