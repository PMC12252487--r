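#' Default pipeline configuration
#'
#' Returns the full configuration of an end-to-end run with every stage at
#' its documented default: 60-pair simulated cohort (or a manifest of RR
#' files), 333-2000 ms outlier screen, 4 Hz resampling, Table-style entropy
#' hyperparameters, FRP with c = 3 / m = 2, 8-level horizontal GLCM at
#' distance 1, FDR threshold 0.95, correlation threshold 0.9, six
#' classifiers, 10-fold CV. One global `seed` fans out to every stochastic
#' stage through documented sub-seed derivation.
#'
#' @param seed global seed (mandatory for simulation mode).
#' @param n_subjects cohort size when simulating.
#' @param classifiers character vector of [classifier_spec()] names.
#' @param ... overrides merged into the config list.
#' @return A named list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1, n_subjects = 60,
                           classifiers = c("svm", "lda", "ibk", "dt", "mlp", "rf"),
                           ...) {
  cfg <- list(
    seed = seed,
    simulate = list(n_subjects = n_subjects),
    manifest = NULL,
    preprocess = list(lo = 333, hi = 2000, fs = 4),
    frp = list(c = 3, m = 2, dim = 1L, tau = 1L),
    glcm = list(levels = 8L, d = 1L, angle = 0),
    entropy = entropy_config(),
    selection = list(fdr_threshold = 0.95, cor_threshold = 0.9),
    classifiers = classifiers,
    cv_folds = 10L,
    learning_curve = list(holdouts = seq(0.9, 0.1, by = -0.1), reps = 20L)
  )
  cfg <- utils::modifyList(cfg, list(...))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys mirror [default_config()]; unspecified keys
#' keep their defaults. Simulation mode requires an explicit `seed`.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed) && is.null(raw$manifest)) {
    stop_frphrv("config must set a seed when running in simulation mode")
  }
  cfg <- default_config(seed = raw$seed %||% 1)
  cfg <- utils::modifyList(cfg, raw)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> preprocess -> featurize (classic + entropy
#' + FRP/GLCM) -> paired statistics -> selection cascade -> classifier
#' evaluation, entirely determined by the config's global seed.
#'
#' @param config a [default_config()] / [read_config()] configuration.
#' @param out_dir optional directory for report artifacts (CSV/JSON/PNG);
#'   `NULL` computes in memory only.
#' @param verbose print stage progress.
#' @return An object of class `pipeline_run`: `config`, `cohort`, `features`,
#'   `stats`, `selection`, `evaluation` (per classifier), `learning_curve`,
#'   `artifacts` (paths, when `out_dir` given).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  seed <- config$seed
  if (is.null(seed)) stop_frphrv("config$seed is required")

  say("[1/6] input: %s",
      if (is.null(config$manifest)) "simulating cohort" else config$manifest)
  cohort <- if (is.null(config$manifest)) {
    simulate_cohort(n_subjects = config$simulate$n_subjects,
                    seed = derive_seed(seed, 1))
  } else {
    read_cohort(config$manifest)
  }

  say("[2/6] preprocessing + feature extraction (%d recordings)",
      length(cohort$recordings))
  feats <- cohort_features(cohort, seed = derive_seed(seed, 2),
                           frp_c = config$frp$c, frp_m = config$frp$m,
                           levels = config$glcm$levels, glcm_d = config$glcm$d,
                           glcm_angle = config$glcm$angle,
                           fs = config$preprocess$fs,
                           lo = config$preprocess$lo, hi = config$preprocess$hi,
                           entropy = config$entropy)

  say("[3/6] paired statistics")
  stats_tab <- paired_feature_stats(feats)

  say("[4/6] selection cascade")
  specs <- lapply(config$classifiers, function(nm) {
    classifier_spec(nm, seed = derive_seed(seed, 4))
  })
  sel <- select_features(feats, specs = specs,
                         fdr_threshold = config$selection$fdr_threshold,
                         cor_threshold = config$selection$cor_threshold,
                         folds = config$cv_folds, seed = derive_seed(seed, 3))

  say("[5/6] classifier evaluation")
  z <- zscore(feats)
  evaluation <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    subset <- sel$greedy[[sp$name]]$subset
    if (length(subset) == 0L) subset <- sel$nonredundant
    cross_validate(z, spec = sp, features = subset, k = config$cv_folds,
                   seed = derive_seed(seed, 5))
  })
  names(evaluation) <- config$classifiers

  say("[6/6] learning curves")
  lc <- learning_curve(z, specs = specs,
                       features = sel$nonredundant,
                       holdouts = config$learning_curve$holdouts,
                       reps = config$learning_curve$reps,
                       seed = derive_seed(seed, 6))

  run <- structure(list(config = config, cohort = cohort, features = feats,
                        stats = stats_tab, selection = sel,
                        evaluation = evaluation, learning_curve = lc,
                        artifacts = NULL),
                   class = "pipeline_run")
  if (!is.null(out_dir)) run$artifacts <- write_run(run, out_dir)
  run
}

# Serialize the run's tables and an FRP gallery into out_dir.
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    features = file.path(out_dir, "features.csv"),
    stats = file.path(out_dir, "statistics.csv"),
    selection = file.path(out_dir, "selection.json"),
    evaluation = file.path(out_dir, "evaluation.csv"),
    learning_curve = file.path(out_dir, "learning_curve.csv")
  )
  utils::write.csv(run$features, paths$features, row.names = FALSE)
  utils::write.csv(run$stats, paths$stats, row.names = FALSE)
  sel <- run$selection
  sel_json <- list(
    ranking = sel$ranking,
    fdr_survivors = sel$fdr_survivors,
    nonredundant = sel$nonredundant,
    greedy = lapply(sel$greedy, function(g) g[c("subset", "accuracy")])
  )
  writeLines(simple_json(sel_json), paths$selection)
  ev <- do.call(rbind, lapply(names(run$evaluation), function(nm) {
    e <- run$evaluation[[nm]]
    data.frame(classifier = nm, accuracy = e$accuracy,
               sensitivity = e$sensitivity, specificity = e$specificity,
               f1 = e$f1, auc = e$auc,
               features = paste(e$features, collapse = "+"),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(ev, paths$evaluation, row.names = FALSE)
  utils::write.csv(run$learning_curve, paths$learning_curve, row.names = FALSE)
  paths
}

# Minimal JSON writer for the selection artifact (keeps jsonlite optional).
simple_json <- function(x) {
  esc <- function(s) gsub('"', '\\\\"', s)
  render <- function(v) {
    if (is.null(v)) return("null")
    if (is.data.frame(v)) {
      rows <- vapply(seq_len(nrow(v)), function(i) {
        render(as.list(v[i, , drop = FALSE]))
      }, character(1))
      return(paste0("[", paste(rows, collapse = ","), "]"))
    }
    if (is.list(v)) {
      if (is.null(names(v))) {
        return(paste0("[", paste(vapply(v, render, character(1)),
                                 collapse = ","), "]"))
      }
      kv <- vapply(names(v), function(k) {
        paste0('"', esc(k), '":', render(v[[k]]))
      }, character(1))
      return(paste0("{", paste(kv, collapse = ","), "}"))
    }
    if (is.character(v)) {
      out <- paste0('"', esc(v), '"')
    } else if (is.logical(v)) {
      out <- ifelse(v, "true", "false")
    } else {
      out <- ifelse(is.finite(v), format(v, digits = 15),
                    paste0('"', as.character(v), '"'))
    }
    if (length(out) == 1L) out else paste0("[", paste(out, collapse = ","), "]")
  }
  render(x)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("FRP-HRV pipeline run\n")
  print(x$cohort)
  print(x$features)
  print(x$selection)
  for (e in x$evaluation) print(e)
  invisible(x)
}

#' @export
summary.pipeline_run <- function(object, ...) {
  sig <- object$stats[object$stats$significant, , drop = FALSE]
  cat(sprintf("Significant features (p < 0.05): %d of %d\n",
              nrow(sig), nrow(object$stats)))
  print(object$selection)
  best <- which.max(vapply(object$evaluation, `[[`, numeric(1), "accuracy"))
  cat("Best classifier by CV accuracy:\n  ")
  print(object$evaluation[[best]])
  invisible(object)
}

#' Markdown report of a pipeline run
#'
#' @param run a [run_pipeline()] result.
#' @param path output Markdown path.
#' @return `path`, invisibly.
#' @export
report_run <- function(run, path) {
  stopifnot(inherits(run, "pipeline_run"))
  lines <- c("# FRP-HRV pipeline report", "",
             sprintf("Seed: %s; recordings: %d; features: %d",
                     format(run$config$seed), nrow(run$features),
                     ncol(run$features) - 2L), "",
             "## FDR survivors", "",
             "| Feature | FDR |", "|---|---|")
  rk <- run$selection$ranking
  surv <- rk[rk$survivor, , drop = FALSE]
  lines <- c(lines, sprintf("| %s | %.4f |", surv$feature, surv$fdr), "",
             "## Nonredundant features (with paired effect sizes)", "",
             "| Feature | FDR | RBC |", "|---|---|---|")
  for (f in run$selection$nonredundant) {
    lines <- c(lines, sprintf("| %s | %.4f | %.3f |", f,
                              rk$fdr[rk$feature == f],
                              run$stats$rbc[run$stats$feature == f]))
  }
  lines <- c(lines, "", "## Classifier performance (10-fold CV)", "",
             "| Classifier | ACC% | SEN% | SPE% | F1 | AUC% | Subset |",
             "|---|---|---|---|---|---|---|")
  for (nm in names(run$evaluation)) {
    e <- run$evaluation[[nm]]
    lines <- c(lines, sprintf("| %s | %.1f | %.1f | %.1f | %.3f | %.1f | %s |",
                              toupper(nm), e$accuracy, e$sensitivity,
                              e$specificity, e$f1, e$auc,
                              paste(e$features, collapse = ", ")))
  }
  writeLines(lines, path)
  invisible(path)
}
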