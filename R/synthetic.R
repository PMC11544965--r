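#' Configuration of the synthetic two-cohort generator
#'
#' Defaults mirror the study conditions the generator emulates: a
#' population-based cohort (PBC) of 1036 patients, a clinic-based cohort
#' (CBC) of 339 patients, a rare 5-year CVD outcome with 2% marginal
#' prevalence (the outcome is described as rare; no rate is printed, so
#' 2% is a documented stand-in), and strong generative effects at the
#' treatment-to-toxicity links.
#'
#' @param n_pbc,n_cbc cohort sizes (their sum must be positive).
#' @param target_prevalence marginal probability of `cvds = Yes`, in
#'   (0, 0.5).
#' @param effect_strength scalar >= 0 scaling how strongly parents shift
#'   child CPTs; 0 makes every non-root variable independent of its
#'   parents. The default 3 corresponds to an odds ratio of about 11 per
#'   cardiotoxic exposure.
#' @param seed integer seed for CPT generation.
#' @param reduced use the 10-variable [reduced_dictionary()] sub-network.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(n_pbc = 1036L, n_cbc = 339L,
                             target_prevalence = 0.02,
                             effect_strength = 3, seed = 1L,
                             reduced = FALSE) {
  stopifnot(n_pbc >= 0, n_cbc >= 0)
  if (n_pbc + n_cbc <= 0) stop("n_pbc + n_cbc must be positive")
  if (!(target_prevalence > 0 && target_prevalence < 0.5))
    stop("target_prevalence must lie in (0, 0.5)")
  if (effect_strength < 0) stop("effect_strength must be >= 0")
  structure(list(n_pbc = as.integer(n_pbc), n_cbc = as.integer(n_cbc),
                 target_prevalence = target_prevalence,
                 effect_strength = effect_strength,
                 seed = as.integer(seed), reduced = isTRUE(reduced)),
            class = "generator_config")
}

#' Temporal tiers of the model variables
#'
#' The causal flow of the model: cohort context first, then tumour
#' prognostic factors, neoadjuvant treatments, surgery, adjuvant
#' treatments, cardiovascular risk factors and treatment toxicities, and
#' finally the CVD outcome together with 5-year vital status. Arcs may
#' only run from earlier to later tiers (or within a tier).
#'
#' @param dict a `bn_dictionary`.
#' @return list of character vectors (one per non-empty tier).
#' @export
model_tiers <- function(dict) {
  nm <- dict_names(dict)
  tiers <- list(
    dict$selection,
    dict_vars_in_group(dict, "prognostic"),
    intersect(c("chemo_neo", "radio_neo", "target_neo", "hormon_neo"), nm),
    intersect("surgery", nm),
    intersect(c("chemo_adju", "radio_adju", "target_adju", "hormons_adiu"), nm),
    c(intersect(dict_vars_in_group(dict, "risk_factor"), nm),
      intersect(c("cardiotoxicity", "ischemic_heart_disease"), nm)),
    c(intersect("cvds", nm), intersect(dict_vars_in_group(dict, "prognosis"), nm))
  )
  tiers[vapply(tiers, length, integer(1)) > 0]
}

#' Prior-knowledge DAG (tier skeleton)
#'
#' The domain-knowledge structure used both as the ground truth of the
#' synthetic generator and as the prior DAG of the learner: the cohort
#' context node is the root; prognostic factors feed treatment choices
#' and 5-year survival; treatments feed the cardiac toxicities; hormone
#' therapy and the cardiovascular risk factors feed ischemic heart
#' disease; cardiotoxicity and ischemic heart disease point to the CVD
#' target.
#'
#' @param dict a `bn_dictionary` ([cvd_dictionary()] or
#'   [reduced_dictionary()]).
#' @return a `bn_dag`.
#' @export
knowledge_dag <- function(dict) {
  nm <- dict_names(dict)
  a <- function(from, to) if (from %in% nm && to %in% nm) cbind(from, to) else NULL
  arcs <- rbind(
    a("cohort", "age35"), a("cohort", "histology"), a("cohort", "grade"),
    a("cohort", "vascular"), a("cohort", "ki67"), a("cohort", "receptors"),
    a("cohort", "pT"), a("cohort", "pN"),
    a("grade", "chemo_neo"), a("receptors", "chemo_neo"), a("pT", "chemo_neo"),
    a("age35", "chemo_neo"),
    a("pT", "radio_neo"),
    a("receptors", "target_neo"),
    a("receptors", "hormon_neo"), a("age35", "hormon_neo"),
    a("chemo_neo", "surgery"), a("pT", "surgery"),
    a("surgery", "chemo_adju"), a("grade", "chemo_adju"),
    a("surgery", "radio_adju"),
    a("target_neo", "target_adju"), a("surgery", "target_adju"),
    a("hormon_neo", "hormons_adiu"), a("receptors", "hormons_adiu"),
    a("cohort", "hypertension"), a("hormons_adiu", "hypertension"),
    a("chemo_adju", "hypertension"),
    a("cohort", "dyslipidemia"), a("hormons_adiu", "dyslipidemia"),
    a("cohort", "t2db"),
    a("chemo_neo", "cardiotoxicity"), a("chemo_adju", "cardiotoxicity"),
    a("radio_adju", "cardiotoxicity"), a("target_adju", "cardiotoxicity"),
    a("hormons_adiu", "ischemic_heart_disease"),
    a("hypertension", "ischemic_heart_disease"),
    a("dyslipidemia", "ischemic_heart_disease"),
    a("t2db", "ischemic_heart_disease"),
    a("cardiotoxicity", "cvds"), a("ischemic_heart_disease", "cvds"),
    a("grade", "death_in_5y"), a("pT", "death_in_5y"), a("pN", "death_in_5y")
  )
  dag(nm, arcs)
}

# 1 if the state denotes a cardiotoxic / at-risk exposure, else 0
exposure_level <- function(state) {
  as.integer(state %in% c("Yes", "Radical", "Pre", "Post"))
}

# 1 if the state denotes an adverse prognostic feature or an intensive
# preceding treatment (drives treatment escalation and 5-year survival)
adverse_level <- function(state) {
  as.integer(state %in% c("Grade 3", "pT3", "pT4", "pN+",
                          "triple-negative", "HER2-enriched",
                          "Yes", "Radical"))
}

#' Ground-truth network for the synthetic cohorts
#'
#' Builds the knowledge DAG over `dict` and fills it with seeded-random
#' CPTs: generic nodes get Dirichlet baselines perturbed per parent
#' configuration on the logit scale (scaled by `effect_strength`);
#' cardiotoxicity and ischemic heart disease get logistic CPTs that
#' increase with the number of exposed parents; the CVD target is a
#' leaky noisy-OR of its two toxicity parents. A shared baseline
#' parameter is calibrated by bisection on the exact (variable
#' elimination) marginal so that P(cvds = Yes) matches
#' `target_prevalence`.
#'
#' @param cfg a [generator_config()].
#' @param dict optional dictionary; defaults to [cvd_dictionary()] or
#'   [reduced_dictionary()] according to `cfg$reduced`.
#' @param max_iterations bisection iteration cap.
#' @return a `bn` with attributes `achieved_prevalence` and `baseline`.
#' @export
ground_truth_network <- function(cfg = generator_config(), dict = NULL,
                                 max_iterations = 50L) {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.null(dict))
    dict <- if (cfg$reduced) reduced_dictionary() else cvd_dictionary()
  dg <- knowledge_dag(dict)
  s <- cfg$effect_strength
  p_pbc <- cfg$n_pbc / (cfg$n_pbc + cfg$n_cbc)
  if (p_pbc == 0 || p_pbc == 1) p_pbc <- min(max(p_pbc, 0.01), 0.99)

  # seeded random material for the generic nodes, fixed across the
  # bisection so only the target block moves during calibration
  generic_material <- with_seed(cfg$seed, {
    lapply(stats::setNames(dict_names(dict), dict_names(dict)), function(v) {
      r <- dict_arity(dict, v)
      pa <- dag_parents(dg, v)
      nc <- prod(vapply(pa, function(p) dict_arity(dict, p), integer(1)))
      list(base = stats::rgamma(r, shape = 4),
           shift = matrix(stats::rnorm(r * nc), nrow = r),
           p_base = stats::runif(1, 0.10, 0.35),
           # per-parent weights on the toxicity exposure ladder, so risk
           # varies continuously across treatment combinations
           exposure_wt = stats::runif(max(length(pa), 1), 0.6, 1.4))
    })
  })

  build <- function(baseline) {
    cpts <- list()
    for (v in dict_names(dict)) {
      pa <- dag_parents(dg, v)
      pa_states <- lapply(stats::setNames(pa, pa),
                          function(p) dict_states(dict, p))
      states <- dict_states(dict, v)
      r <- length(states)
      grid <- if (length(pa))
        expand.grid(pa_states, KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
      else data.frame(row.names = 1)
      nc <- nrow(grid)
      exposures <- if (length(pa))
        rowSums(vapply(pa, function(p) exposure_level(grid[[p]]),
                       numeric(nc)))
      else 0
      severity <- if (length(pa))
        rowSums(vapply(pa, function(p) as.numeric(adverse_level(grid[[p]])),
                       numeric(nc)))
      else 0
      group <- dict_group(dict, v)
      if (v == dict$selection) {
        pm <- matrix(c(p_pbc, 1 - p_pbc), nrow = r)
      } else if (group %in% c("treatment", "prognosis")) {
        # treatment escalates (and 5-year death risk grows) with the
        # number of adverse prognostic features / intensive treatments
        mat <- generic_material[[v]]
        pb <- if (group == "prognosis") 0.06 else mat$p_base
        py <- stats::plogis(stats::qlogis(pb) + 0.4 * s * severity)
        active <- match(if ("Radical" %in% states) "Radical" else "Yes",
                        states)
        pm <- matrix(0, nrow = r, ncol = nc)
        pm[active, ] <- py
        pm[-active, ] <- 1 - py
      } else if (v %in% c("cardiotoxicity", "ischemic_heart_disease")) {
        wt <- generic_material[[v]]$exposure_wt[seq_along(pa)]
        wexp <- if (length(pa))
          as.vector(vapply(pa, function(p) exposure_level(grid[[p]]),
                           numeric(nc)) %*% wt)
        else 0
        py <- stats::plogis(stats::qlogis(baseline) + 0.8 * s * wexp)
        pm <- rbind(py, 1 - py)
      } else if (v == "cvds") {
        w <- 1 - exp(-0.6 * s)
        hit <- vapply(pa, function(p) as.numeric(grid[[p]] == "Yes"),
                      numeric(nc))
        if (nc == 1) hit <- matrix(hit, nrow = 1)
        py <- 1 - (1 - baseline / 2) * apply((1 - w)^hit, 1, prod)
        pm <- rbind(py, 1 - py)
      } else if (group == "risk_factor") {
        # cardiovascular risk factors: exposure to hormone/chemotherapy
        # shifts mass toward a post-diagnosis onset ("Post")
        mat <- generic_material[[v]]
        base <- log(mat$base / sum(mat$base))
        pm <- vapply(seq_len(nc), function(ci) {
          x <- base + 0.6 * s * exposures[ci] * (states == "Post")
          e <- exp(x - max(x)); e / sum(e)
        }, numeric(r))
        if (r == 1) pm <- matrix(pm, nrow = 1)
      } else {
        mat <- generic_material[[v]]
        logit <- log(mat$base / sum(mat$base)) + 0.5 * s * mat$shift[, seq_len(nc), drop = FALSE]
        pm <- apply(logit, 2, function(x) { e <- exp(x - max(x)); e / sum(e) })
      }
      # pm: r x nc with configs in expand.grid (first parent fastest)
      # order == the CPT array's natural layout
      cpts[[v]] <- cpt(v, states, as.vector(pm), parents = pa,
                       parent_states = pa_states)
    }
    bayes_net(dg, cpts, dictionary = dict)
  }

  marg <- function(bn) {
    unname(eliminate_posterior(bn, "cvds")$probabilities["Yes"])
  }

  lo <- 1e-9; hi <- 0.5
  target <- cfg$target_prevalence
  bn_lo <- build(lo); bn_hi <- build(hi)
  m_lo <- marg(bn_lo); m_hi <- marg(bn_hi)
  if (target <= m_lo || target >= m_hi)
    stop("prevalence calibration failed: target ", target,
         " outside achievable range [", signif(m_lo, 4), ", ",
         signif(m_hi, 4), "]")
  achieved <- NA_real_; bn_mid <- NULL; mid <- NA_real_
  for (i in seq_len(max_iterations)) {
    mid <- (lo + hi) / 2
    bn_mid <- build(mid)
    achieved <- marg(bn_mid)
    if (abs(achieved - target) / target < 0.01) break
    if (achieved < target) lo <- mid else hi <- mid
  }
  if (abs(achieved - target) / target > 0.2)
    stop("prevalence calibration failed after ", max_iterations,
         " iterations: achieved ", signif(achieved, 4),
         " for target ", target)
  attr(bn_mid, "achieved_prevalence") <- achieved
  attr(bn_mid, "baseline") <- mid
  bn_mid
}

#' Ancestral (forward) sampling from a network
#'
#' Samples `n` complete records in topological order, each variable
#' drawn from its CPT given its sampled parents.
#'
#' @param bn a `bn`.
#' @param n number of records (0 gives an empty table with the right
#'   columns).
#' @param seed integer RNG seed.
#' @return data frame of character state labels, columns in node order,
#'   with the dictionary attached as attribute `"dictionary"`.
#' @export
sample_network <- function(bn, n, seed = 1L) {
  ord <- topological_order(bn$dag)
  nodes <- bn$dag$nodes
  n <- as.integer(n)
  samp <- matrix(0L, nrow = n, ncol = length(nodes),
                 dimnames = list(NULL, nodes))
  if (n > 0) with_seed(seed, {
    for (v in ord) {
      ct <- bn$cpts[[v]]
      r <- length(ct$states)
      if (length(ct$parents)) {
        pidx <- samp[, ct$parents, drop = FALSE]
        probs <- vapply(seq_len(r), function(k)
          cpt_lookup(ct, rep(k, n), pidx), numeric(n))
        if (n == 1) probs <- matrix(probs, nrow = 1)
      } else {
        probs <- matrix(as.vector(ct$prob), nrow = n, ncol = r, byrow = TRUE)
      }
      u <- stats::runif(n)
      cum <- probs %*% upper.tri(diag(r), diag = TRUE)
      cum[, r] <- 1
      samp[, v] <- r + 1L - as.integer(rowSums(u <= cum))
    }
  })
  out <- as.data.frame(lapply(stats::setNames(nodes, nodes), function(v)
    bn_states(bn, v)[samp[, v]]), optional = TRUE,
    stringsAsFactors = FALSE)
  if (n == 0) {
    out <- as.data.frame(lapply(stats::setNames(nodes, nodes),
                                function(v) character(0)))
  }
  attr(out, "dictionary") <- bn$dictionary
  out
}

#' Block missingness masks driven by the cohort node
#'
#' A cohort mask maps each cohort state to the set of variables that are
#' deterministically missing for records of that cohort. The default
#' reproduces the structure of the two study-like cohorts: PBC records
#' lose the tumour prognostic factors (age is registry-recorded and
#' stays), CBC records lose the CVD follow-up block.
#'
#' @param dict a `bn_dictionary`.
#' @param missing_when named list: cohort state -> character vector of
#'   masked variables.
#' @return object of class `cohort_mask`.
#' @export
cohort_mask <- function(dict, missing_when) {
  cohort_var <- dict$selection
  states <- dict_states(dict, cohort_var)
  bad <- setdiff(names(missing_when), states)
  if (length(bad))
    stop("mask references unknown cohort state(s): ",
         paste(bad, collapse = ", "))
  for (st in names(missing_when)) {
    vars <- missing_when[[st]]
    unknown <- setdiff(vars, dict_names(dict))
    if (length(unknown))
      stop("mask references unknown variable(s): ",
           paste(unknown, collapse = ", "))
    if (cohort_var %in% vars)
      stop("the cohort variable itself cannot be masked")
  }
  structure(list(cohort_var = cohort_var, missing_when = missing_when),
            class = "cohort_mask")
}

#' @rdname cohort_mask
#' @export
default_cohort_mask <- function(dict) {
  cohort_mask(dict, list(
    PBC = setdiff(dict_vars_in_group(dict, "prognostic"), "age35"),
    CBC = dict_vars_in_group(dict, "target")
  ))
}

#' Apply deterministic cohort-driven missingness
#'
#' Blanks, in every record, exactly the variables the mask lists for
#' that record's cohort state; all other cells are unchanged. The
#' pre-mask table is kept in attribute `"truth"` so recovery can be
#' evaluated against it.
#'
#' @param data complete data frame (cohort column fully observed).
#' @param mask a [cohort_mask()].
#' @return data frame with `NA` cells and attribute `"truth"`.
#' @export
apply_cohort_missingness <- function(data, mask) {
  stopifnot(inherits(mask, "cohort_mask"))
  cv <- mask$cohort_var
  if (!cv %in% names(data)) stop("data lacks cohort column '", cv, "'")
  if (anyNA(data[[cv]])) stop("cohort column must be fully observed")
  truth <- data
  attr(truth, "truth") <- NULL
  for (st in names(mask$missing_when)) {
    rows <- data[[cv]] == st
    for (v in mask$missing_when[[st]]) data[rows, v] <- NA_character_
  }
  attr(data, "truth") <- truth
  data
}

#' Train / validation split with a training-only cohort
#'
#' The clinic-based cohort has no observed outcome and can only train
#' the model, so every CBC-style record goes to the training set; the
#' validation set is a simple random sample of the requested size from
#' the PBC-style records. The split is an exact partition of the input
#' rows.
#'
#' @param data data frame containing the cohort column.
#' @param validation_fraction fraction of ALL rows to hold out
#'   (validation size = `round(validation_fraction * nrow(data))`).
#' @param seed integer RNG seed.
#' @param cohort_var,validation_state cohort column name and the state
#'   eligible for validation (defaults `"cohort"`, `"PBC"`).
#' @return list with data frames `train` and `validation`; any
#'   `"truth"` attribute is split alongside.
#' @export
train_validation_split <- function(data, validation_fraction, seed = 1L,
                                   cohort_var = "cohort",
                                   validation_state = "PBC") {
  if (!(validation_fraction > 0 && validation_fraction < 1))
    stop("validation_fraction must lie in (0, 1)")
  if (!cohort_var %in% names(data)) stop("no cohort column '", cohort_var, "'")
  n <- nrow(data)
  size <- round(validation_fraction * n)
  pbc_rows <- which(data[[cohort_var]] == validation_state)
  if (size < 1 || size > length(pbc_rows))
    stop("requested validation size (", size, ") exceeds the ",
         length(pbc_rows), " available '", validation_state, "' rows")
  val_idx <- with_seed(seed, sort(sample(pbc_rows, size)))
  truth <- attr(data, "truth")
  subset_keep <- function(idx) {
    out <- data[idx, , drop = FALSE]
    if (!is.null(truth)) attr(out, "truth") <- truth[idx, , drop = FALSE]
    attr(out, "dictionary") <- attr(data, "dictionary")
    out
  }
  list(train = subset_keep(setdiff(seq_len(n), val_idx)),
       validation = subset_keep(val_idx))
}

#' One-call synthetic study: truth network, masked data, mask
#'
#' Builds the calibrated ground-truth network, forward-samples the two
#' cohorts and applies the default block-missingness mask.
#'
#' @param cfg a [generator_config()].
#' @return list with `network`, `data` (masked, with `"truth"`
#'   attribute), `dictionary`, `mask` and `achieved_prevalence`.
#' @export
simulate_cohorts <- function(cfg = generator_config()) {
  bn <- ground_truth_network(cfg)
  dict <- bn$dictionary
  data <- sample_network(bn, cfg$n_pbc + cfg$n_cbc,
                         seed = derive_seed(cfg$seed, 1L))
  mask <- default_cohort_mask(dict)
  masked <- apply_cohort_missingness(data, mask)
  attr(masked, "dictionary") <- dict
  list(network = bn, data = masked, dictionary = dict, mask = mask,
       achieved_prevalence = attr(bn, "achieved_prevalence"))
}
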