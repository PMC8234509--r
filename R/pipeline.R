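# File-based pipeline: simulate -> score -> grade -> evaluate.
#
# Every stage reads and writes plain files (PNG frames, CSV manifests
# and score tables, JSON reports), so stages are independently runnable
# and resumable. All randomness flows from one global seed, split per
# case, and reports carry provenance (scoring method, config hash,
# seed) but no timestamps, so a re-run with the same seed is
# byte-identical.

#' Pipeline configuration
#'
#' @param seed Global seed; all per-case seeds are derived from it.
#' @param out_dir Output directory of the pipeline run.
#' @param generator List: `n_cases`, `n_frames`, `image_size`,
#'   `occluder_mix`, and `trajectory`. The default trajectory,
#'   `list(type = "random-walk", start_range = c(0.25, 0.98), sd = 0.05)`,
#'   draws each case's baseline cleanliness uniformly from
#'   `start_range` and lets it drift smoothly along the case; any
#'   [case_spec()] trajectory may be given instead.
#' @param preprocessing List: `circular_mask` flag.
#' @param scoring List: `method` (`"rule-based"` or `"model"`),
#'   `model_path` (required for `"model"`), `thresholds`
#'   (see [rule_thresholds()]).
#' @param grading List: `use_fractions` — apply the >50%-invisible test
#'   to raw estimated fractions instead of binned scores (rule-based
#'   scoring only).
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(seed = 1L,
                            out_dir = file.path(tempdir(), "cescore-run"),
                            generator = list(),
                            preprocessing = list(),
                            scoring = list(),
                            grading = list()) {
  defaults <- list(
    seed = 1L,
    out_dir = out_dir,
    generator = list(
      n_cases = 5L, n_frames = 60L, image_size = 64L,
      occluder_mix = c(bubble = 1, bile = 1, debris = 1) / 3,
      trajectory = list(type = "random-walk",
                        start_range = c(0.25, 0.98), sd = 0.05)
    ),
    preprocessing = list(circular_mask = FALSE),
    scoring = list(method = "rule-based", model_path = NULL,
                   thresholds = rule_thresholds()),
    grading = list(use_fractions = FALSE)
  )
  config <- defaults
  config$seed <- as.integer(seed)
  config$out_dir <- out_dir
  merge_section <- function(section, given) {
    bad <- setdiff(names(given), names(defaults[[section]]))
    if (length(bad)) {
      stop_validation("unknown ", section, " config key(s): ",
                      paste(bad, collapse = ", "))
    }
    utils::modifyList(defaults[[section]], given, keep.null = TRUE)
  }
  config$generator <- merge_section("generator", generator)
  config$generator$occluder_mix <- stats::setNames(
    as.numeric(unlist(config$generator$occluder_mix)),
    c("bubble", "bile", "debris")
  )
  config$preprocessing <- merge_section("preprocessing", preprocessing)
  config$scoring <- merge_section("scoring", scoring)
  config$grading <- merge_section("grading", grading)
  if (!config$scoring$method %in% c("rule-based", "model")) {
    stop_validation("scoring$method must be 'rule-based' or 'model'")
  }
  if (config$scoring$method == "model" && is.null(config$scoring$model_path)) {
    stop_validation("scoring$method = 'model' requires scoring$model_path")
  }
  structure(config, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The on-disk form round-trips losslessly; unknown keys are rejected on
#' read.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `read_config` returns a `pipeline_config`; `write_config`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 12L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_validation("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- c("seed", "out_dir", "generator", "preprocessing", "scoring",
             "grading")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop_validation("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(raw$generator$occluder_mix)) {
    raw$generator$occluder_mix <- unlist(raw$generator$occluder_mix)
  }
  pipeline_config(
    seed = if (is.null(raw$seed)) 1L else raw$seed,
    out_dir = if (is.null(raw$out_dir)) file.path(tempdir(), "cescore-run")
              else raw$out_dir,
    generator = raw$generator %||% list(),
    preprocessing = raw$preprocessing %||% list(),
    scoring = raw$scoring %||% list(),
    grading = raw$grading %||% list()
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(config)[setdiff(names(config), "out_dir")], f)
  unname(tools::md5sum(f))
}

#' Read a frame manifest
#'
#' The manifest lists a case's frames in time order with columns
#' `case_id`, `frame_index`, `filename`. Frame indices must be 0-based
#' and contiguous.
#'
#' @param path Manifest CSV path.
#' @return Data frame sorted by `frame_index`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_validation("manifest not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "frame_index", "filename")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols)) {
    stop_validation("manifest ", path, " lacks column(s): ",
                    paste(missing_cols, collapse = ", "))
  }
  m <- m[order(m$frame_index), , drop = FALSE]
  expected <- seq(0L, max(m$frame_index))
  gap <- setdiff(expected, m$frame_index)
  if (length(gap) || min(m$frame_index) != 0L || anyDuplicated(m$frame_index)) {
    stop_validation(
      "manifest ", path, " frame_index must be 0-based and contiguous",
      if (length(gap)) paste0("; missing index ",
                              paste(gap, collapse = ", ")) else ""
    )
  }
  m
}

#' Read a per-frame score table
#'
#' @param path CSV with columns `frame_index`, `p1..p5`, `score` (as
#'   written by the scoring stage).
#' @return Data frame sorted by `frame_index`.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop_validation("score table not found: ", path)
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_index", paste0("p", 1:5), "score")
  missing_cols <- setdiff(need, names(s))
  if (length(missing_cols)) {
    stop_validation("score table ", path, " lacks column(s): ",
                    paste(missing_cols, collapse = ", "))
  }
  bad <- which(!(s$score %in% 1:5))
  if (length(bad)) {
    stop_validation("score table ", path, ", row ", bad[1L],
                    ": score ", s$score[bad[1L]], " outside 1..5")
  }
  s[order(s$frame_index), , drop = FALSE]
}

#' Write / read a case report
#'
#' A case report is the pipeline's end product for one case: frame
#' count, final average cleansing score, per-segment >50%-invisible
#' fractions and grades, overall grade, adequacy, and provenance
#' (scoring method or model hash, configuration hash, seed).
#'
#' @param report A case report list (see [run_pipeline()]).
#' @param path JSON file path.
#' @return `read_case_report` returns the report list; `write_case_report`
#'   returns `path` invisibly.
#' @export
write_case_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_case_report
#' @export
read_case_report <- function(path) {
  if (!file.exists(path)) stop_validation("case report not found: ", path)
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

case_report <- function(grading, provenance) {
  list(
    case_id = grading$case_id,
    n_frames = grading$n_frames,
    final_score = grading$final_score,
    segments = list(
      invisible_fractions = grading$segment_invisible_fractions,
      grades = grading$segmental_grades
    ),
    grade_sum = grading$grade_sum,
    overall_grade = grading$overall_grade,
    adequate = grading$adequate,
    provenance = provenance
  )
}

stage_log <- function(log_path, ...) {
  line <- paste0(...)
  message(line)
  cat(line, "\n", sep = "", file = log_path, append = TRUE)
}

# Remove a stage's partial outputs when it fails, then rethrow.
with_stage_cleanup <- function(outputs, expr) {
  tryCatch(expr, error = function(e) {
    for (f in outputs) unlink(f, recursive = TRUE)
    stop(e)
  })
}

#' Run the scoring pipeline end to end
#'
#' Executes the requested stages in order over a case cohort under
#' `out_dir`:
#'
#' * `simulate` — generate `n_cases` synthetic cases
#'   (`cases/<id>/frames/*.png`, `manifest.csv`, `ground_truth.csv`).
#' * `score` — score every manifest frame (rule-based or trained model)
#'   into `scores.csv`.
#' * `grade` — aggregate `scores.csv` into `report.json` per case.
#' * `evaluate` — frame-level agreement against ground truth
#'   (confusion matrix, Top-1, kappa) and case-level ROC of the final
#'   score against ground-truth adequacy, into `evaluation.json`.
#'
#' Each stage's inputs and outputs are files, so stages can be re-run
#' individually; a stage that fails removes its partial outputs. A run
#' log (`run_log.txt`) records the package version, seed and config
#' hash. With a fixed seed the full run is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param stages Character vector of stages to run, in pipeline order.
#' @return Invisibly, a list with `reports` (one case report per case)
#'   and, when the evaluate stage ran, `evaluation`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "score", "grade", "evaluate")) {
  if (!inherits(config, "pipeline_config")) {
    stop_validation("config must be a pipeline_config")
  }
  stages <- match.arg(stages, c("simulate", "score", "grade", "evaluate"),
                      several.ok = TRUE)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  if ("simulate" %in% stages) unlink(log_path)
  hash <- config_hash(config)
  stage_log(log_path, "cescore ", as.character(utils::packageVersion("cescore")),
            " | seed ", config$seed, " | config ", hash)

  gen <- config$generator
  n_cases <- gen$n_cases
  case_ids <- sprintf("case_%02d", seq_len(n_cases))
  case_dirs <- file.path(out_dir, "cases", case_ids)
  case_seeds <- derive_seeds(config$seed, n_cases + 1L)
  model <- NULL
  if (config$scoring$method == "model") {
    if (!file.exists(config$scoring$model_path)) {
      stop_validation("missing stage input: model file ",
                      config$scoring$model_path)
    }
    model <- load_model(config$scoring$model_path)
  }
  provenance <- list(
    scoring = if (config$scoring$method == "model") {
      paste0("model:", unname(tools::md5sum(config$scoring$model_path)))
    } else "rule-based",
    config_hash = hash,
    seed = config$seed
  )

  if ("simulate" %in% stages) {
    for (i in seq_len(n_cases)) {
      with_stage_cleanup(case_dirs[i], {
        traj <- gen$trajectory
        if (identical(traj$type, "random-walk") &&
            !is.null(traj$start_range)) {
          traj <- list(
            type = "random-walk",
            start = with_seed(case_seeds[i],
                              stats::runif(1, traj$start_range[1],
                                           traj$start_range[2])),
            sd = traj$sd %||% 0.05
          )
        }
        generate_case(
          case_spec(n_frames = gen$n_frames, trajectory = traj,
                    image_size = gen$image_size,
                    occluder_mix = gen$occluder_mix,
                    seed = case_seeds[i], case_id = case_ids[i]),
          out_dir = case_dirs[i]
        )
      })
      stage_log(log_path, "simulate: ", case_ids[i], " (", gen$n_frames,
                " frames)")
    }
  }

  if ("score" %in% stages) {
    for (i in seq_len(n_cases)) {
      manifest_path <- file.path(case_dirs[i], "manifest.csv")
      if (!file.exists(manifest_path)) {
        stop_validation("missing stage input: ", manifest_path,
                        " (run the simulate stage or provide frames)")
      }
      scores_path <- file.path(case_dirs[i], "scores.csv")
      with_stage_cleanup(scores_path, {
        manifest <- read_manifest(manifest_path)
        frames <- lapply(seq_len(nrow(manifest)), function(k) {
          read_frame(file.path(case_dirs[i], manifest$filename[k]),
                     case_id = manifest$case_id[k],
                     frame_index = manifest$frame_index[k])
        })
        tab <- if (is.null(model)) {
          score_frames_rule_based(
            frames, thresholds = config$scoring$thresholds,
            circular_mask = config$preprocessing$circular_mask
          )
        } else {
          score_frames_model(
            frames, model,
            circular_mask = config$preprocessing$circular_mask
          )
        }
        utils::write.csv(tab, scores_path, row.names = FALSE)
      })
      stage_log(log_path, "score: ", case_ids[i], " (",
                provenance$scoring, ")")
    }
  }

  reports <- list()
  if ("grade" %in% stages) {
    for (i in seq_len(n_cases)) {
      scores_path <- file.path(case_dirs[i], "scores.csv")
      if (!file.exists(scores_path)) {
        stop_validation("missing stage input: ", scores_path,
                        " (run the score stage first)")
      }
      report_path <- file.path(case_dirs[i], "report.json")
      with_stage_cleanup(report_path, {
        tab <- read_scores(scores_path)
        fractions <- if (config$grading$use_fractions &&
                         "estimated_fraction" %in% names(tab)) {
          tab$estimated_fraction
        } else NULL
        grading <- grade_case(tab$score, fractions = fractions,
                              case_id = case_ids[i])
        report <- case_report(grading, provenance)
        write_case_report(report, report_path)
        reports[[case_ids[i]]] <- report
      })
      stage_log(log_path, "grade: ", case_ids[i], " -> ",
                reports[[case_ids[i]]]$overall_grade)
    }
  } else {
    for (i in seq_len(n_cases)) {
      report_path <- file.path(case_dirs[i], "report.json")
      if (file.exists(report_path)) {
        reports[[case_ids[i]]] <- read_case_report(report_path)
      }
    }
  }

  evaluation <- NULL
  if ("evaluate" %in% stages) {
    eval_path <- file.path(out_dir, "evaluation.json")
    with_stage_cleanup(eval_path, {
      ref_all <- integer(0)
      pred_all <- integer(0)
      case_final <- numeric(0)
      case_adequate_truth <- logical(0)
      for (i in seq_len(n_cases)) {
        gt_path <- file.path(case_dirs[i], "ground_truth.csv")
        scores_path <- file.path(case_dirs[i], "scores.csv")
        if (!file.exists(gt_path) || !file.exists(scores_path)) {
          stop_validation("missing stage input: ",
                          if (!file.exists(gt_path)) gt_path else scores_path)
        }
        gt <- utils::read.csv(gt_path)
        tab <- read_scores(scores_path)
        ref_all <- c(ref_all, gt$true_score)
        pred_all <- c(pred_all, tab$score)
        case_final <- c(case_final, final_score(tab$score))
        truth_grading <- grade_case(gt$true_score, case_id = case_ids[i])
        case_adequate_truth <- c(case_adequate_truth, truth_grading$adequate)
      }
      cm <- confusion_matrix(ref_all, pred_all)
      # kappa is undefined when all mass sits in one cell (Pe = 1)
      agreement <- tryCatch(cohen_kappa(cm), error = function(e) NULL)
      if (is.null(agreement)) {
        agreement <- list(
          top1 = top1_accuracy(cm), kappa = NA,
          misclassification = 1 - top1_accuracy(cm),
          underestimation = sum(cm[lower.tri(cm)]) / sum(cm),
          overestimation = sum(cm[upper.tri(cm)]) / sum(cm)
        )
      }
      roc <- if (length(unique(case_adequate_truth)) == 2L) {
        roc_analysis(case_final, case_adequate_truth)
      } else NULL
      evaluation <- list(
        n_frames = sum(cm),
        confusion_matrix = unname(apply(cm, 1L, identity, simplify = FALSE)),
        top1 = agreement$top1,
        kappa = agreement$kappa,
        misclassification = agreement$misclassification,
        underestimation = agreement$underestimation,
        overestimation = agreement$overestimation,
        roc = if (is.null(roc)) {
          "not computed: only one adequacy class in the cohort"
        } else {
          list(auc = roc$auc, cutoff = roc$cutoff,
               cutoff_sensitivity = roc$cutoff_sensitivity,
               cutoff_specificity = roc$cutoff_specificity)
        },
        provenance = provenance
      )
      jsonlite::write_json(evaluation, eval_path, auto_unbox = TRUE,
                           pretty = TRUE, digits = NA)
    })
    stage_log(log_path, "evaluate: ", sum(lengths(reports) > 0), " cases")
  }

  invisible(list(reports = reports, evaluation = evaluation))
}
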