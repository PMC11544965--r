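#' End-to-end pipeline: simulate two synthetic cohorts
#'
#' Builds the calibrated ground-truth network, forward-samples the
#' combined cohort, applies the block-missingness mask and writes all
#' artifacts: masked data CSV, pre-mask truth CSV, dictionary JSON,
#' ground-truth model `.net` and default constraints YAML.
#'
#' @param out_dir output directory (created if needed).
#' @param cfg a [generator_config()].
#' @return list with the written `paths`, the `achieved_prevalence` and
#'   the simulation objects (invisible).
#' @export
pipeline_simulate <- function(out_dir, cfg = generator_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohorts(cfg)
  paths <- list(
    data = file.path(out_dir, "cohorts.csv"),
    truth_data = file.path(out_dir, "cohorts_truth.csv"),
    dictionary = file.path(out_dir, "dictionary.json"),
    model = file.path(out_dir, "truth.net"),
    constraints = file.path(out_dir, "constraints.yaml"))
  write_dataset(sim$data, paths$data)
  write_dataset(attr(sim$data, "truth"), paths$truth_data)
  write_dictionary(sim$dictionary, paths$dictionary)
  write_net(sim$network, paths$model)
  write_constraints(default_constraints(sim$dictionary), paths$constraints)
  message("simulated ", nrow(sim$data), " records (seed ", cfg$seed,
          "); marginal P(cvds=Yes) calibrated to ",
          signif(sim$achieved_prevalence, 4))
  invisible(c(list(paths = paths,
                   achieved_prevalence = sim$achieved_prevalence), sim))
}

#' End-to-end pipeline: train a model with Structural EM
#'
#' Reads the training data, dictionary and constraints, runs the
#' knowledge-constrained Structural EM from the required-arc prior DAG,
#' and writes the fitted model plus a training report (score and
#' log-likelihood traces, arcs added beyond the prior for expert
#' review).
#'
#' @param data data frame (or CSV path) of training records.
#' @param dict a `bn_dictionary` (or path to one).
#' @param constraints a `knowledge_constraints` (or path).
#' @param out_model path for the fitted `.net` model (optional).
#' @param out_report path for the JSON training report (optional).
#' @param cfg an [em_config()].
#' @param max_parents hill-climb parent cap.
#' @return the `bn_learn_result` (invisible).
#' @export
pipeline_train <- function(data, dict, constraints = NULL,
                           out_model = NULL, out_report = NULL,
                           cfg = em_config(), max_parents = 5L) {
  if (is.character(dict)) dict <- read_dictionary(dict)
  if (is.character(data)) data <- read_dataset(data, dict)
  if (is.null(constraints)) constraints <- default_constraints(dict)
  if (is.character(constraints)) constraints <- read_constraints(constraints)
  unobserved <- dict_names(dict)[vapply(dict_names(dict), function(v)
    all(is.na(data[[v]])), logical(1))]
  if (length(unobserved))
    warning("variable(s) never observed in the training data: ",
            paste(unobserved, collapse = ", "),
            "; their CPTs rest on the smoothing prior and model-based ",
            "completions", call. = FALSE)
  prior <- dag(dict_names(dict), constraints$required_arcs)
  res <- structural_em(prior, data, constraints, cfg = cfg, dict = dict,
                       max_parents = max_parents)
  if (!is.null(out_model)) write_net(res$network, out_model)
  if (!is.null(out_report)) {
    report <- list(
      seed = cfg$seed,
      n_rows = nrow(data),
      score_trace = res$score_trace,
      loglik_trace = res$loglik_trace,
      added_arcs = if (nrow(res$added_arcs))
        apply(res$added_arcs, 1, paste, collapse = "->") else character(0))
    jsonlite::write_json(report, out_report, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  message("trained model: ", nrow(res$network$dag$arcs), " arcs (",
          nrow(res$added_arcs), " beyond the prior DAG)")
  invisible(res)
}

# evidence for one patient row: observed covariates minus the target
# block; cohort and vital status are marginalized by default.
row_evidence <- function(row, dict, evidence_cohort = FALSE,
                         evidence_death = FALSE) {
  drop <- dict_vars_in_group(dict, "target")
  if (!evidence_cohort) drop <- c(drop, dict$selection)
  if (!evidence_death) drop <- c(drop, dict_vars_in_group(dict, "prognosis"))
  keep <- setdiff(dict_names(dict), drop)
  ev <- unlist(row[keep])
  ev[!is.na(ev)]
}

#' End-to-end pipeline: evaluate a fitted model on held-out patients
#'
#' Predicts the individual 5-year CVD risk for every validation record
#' with an observed outcome (evidence: the record's observed covariates
#' outside the target block; the cohort context node and vital status
#' are marginalized by default), then computes classification metrics
#' with normal-approximation intervals and the cumulative-gain curve.
#'
#' @param model a `bn` (or `.net` path).
#' @param data validation data frame (or CSV path) with observed
#'   outcomes.
#' @param dict a `bn_dictionary` (or path); defaults to the model's.
#' @param threshold classification threshold (default: the model's
#'   marginal outcome prevalence).
#' @param engine `"exact"` or `"lw"`.
#' @param evidence_cohort,evidence_death also condition on the cohort /
#'   vital-status nodes where observed.
#' @param out_metrics,out_lift,out_plot optional output paths (JSON
#'   metrics, CSV lift curve, PDF with both plots).
#' @param target,positive outcome variable and positive state.
#' @param seed seed for the approximate engine.
#' @return list with `predictions` (data frame: risk, label),
#'   `metrics`, `auc`, `curve`, `threshold` (invisible).
#' @export
pipeline_evaluate <- function(model, data, dict = NULL, threshold = NULL,
                              engine = c("exact", "lw"),
                              evidence_cohort = FALSE,
                              evidence_death = FALSE,
                              out_metrics = NULL, out_lift = NULL,
                              out_plot = NULL,
                              target = "cvds", positive = "Yes",
                              seed = 1L) {
  engine <- match.arg(engine)
  if (is.character(dict) && !is.null(dict)) dict <- read_dictionary(dict)
  if (is.character(model)) model <- read_net(model, dictionary = dict)
  if (is.null(dict)) dict <- bn_as_dict(model)
  if (is.character(data)) data <- read_dataset(data, dict)
  obs <- which(!is.na(data[[target]]))
  if (!length(obs))
    stop("the validation set has no observed '", target, "' outcomes")
  if (is.null(threshold)) {
    prior <- eliminate_posterior(model, target)
    threshold <- unname(prior$probabilities[positive])
  }
  # one exact query per unique evidence pattern
  ev_list <- lapply(obs, function(i)
    row_evidence(data[i, , drop = FALSE], dict,
                 evidence_cohort = evidence_cohort,
                 evidence_death = evidence_death))
  keys <- vapply(ev_list, function(e)
    paste(names(e), e, sep = "=", collapse = ";"), character(1))
  uk <- unique(keys)
  risk_of <- vapply(uk, function(k) {
    ev <- ev_list[[match(k, keys)]]
    predict_risk(model, ev, threshold = threshold, engine = engine,
                 target = target, positive = positive,
                 seed = seed)$probability
  }, numeric(1))
  risks <- unname(risk_of[match(keys, uk)])
  labels <- data[[target]][obs]
  preds <- data.frame(row = obs, risk = risks, label = labels,
                      classified = ifelse(risks >= threshold,
                                          "at_risk", "not_at_risk"))
  cm <- confusion(labels == positive, preds$classified == "at_risk")
  metrics <- classification_metrics(cm)
  auc <- auc_score(risks, labels == positive)
  metrics <- rbind(
    data.frame(metric = "auc", value = auc, ci_low = NA_real_,
               ci_high = NA_real_, n = length(obs)),
    metrics)
  class(metrics) <- c("metric_report", "data.frame")
  curve <- lift_curve(risks, labels == positive)
  if (!is.null(out_metrics))
    jsonlite::write_json(metrics, out_metrics, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  if (!is.null(out_lift))
    utils::write.csv(data.frame(fraction = curve$fractions,
                                cumulative_tpr = curve$cumulative_tpr),
                     out_lift, row.names = FALSE)
  if (!is.null(out_plot)) {
    grDevices::pdf(out_plot, width = 9, height = 4.5)
    graphics::par(mfrow = c(1, 2))
    plot_metric_report(metrics[-1, ])
    plot_lift_curve(curve)
    grDevices::dev.off()
  }
  message("evaluated ", length(obs), " patients: AUC ", signif(auc, 3),
          ", threshold ", signif(threshold, 3))
  invisible(list(predictions = preds, metrics = metrics, auc = auc,
                 curve = curve, threshold = threshold,
                 confusion = cm))
}

#' End-to-end pipeline: individual risk prediction
#'
#' Posterior 5-year CVD risk for one patient given partial evidence.
#'
#' @param model a `bn` (or `.net` path).
#' @param evidence named character vector/list `variable = state`.
#' @param threshold classification threshold (default: model marginal
#'   prevalence).
#' @param engine `"exact"` or `"lw"`.
#' @param target,positive outcome variable and positive state.
#' @param n_samples,seed approximate-engine settings.
#' @return list with `probability`, `classified`, `threshold`, `engine`.
#' @export
pipeline_predict <- function(model, evidence = NULL, threshold = NULL,
                             engine = c("exact", "lw"),
                             target = "cvds", positive = "Yes",
                             n_samples = 10000L, seed = 1L) {
  engine <- match.arg(engine)
  if (is.character(model)) model <- read_net(model)
  predict_risk(model, evidence, threshold = threshold, engine = engine,
               target = target, positive = positive,
               n_samples = n_samples, seed = seed)
}
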