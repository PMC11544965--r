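#' Data dictionaries for discrete patient variables
#'
#' A data dictionary is the ordered list of discrete variables a network is
#' defined over, each with its ordered state labels and a variable group.
#' Groups partition the variables into: `selection` (the cohort context
#' node), `prognostic` (tumour prognostic factors), `prognosis` (5-year
#' vital status), `treatment`, `risk_factor` (cardiovascular risk factors)
#' and `target` (cardiac toxicities and the CVD outcome).
#'
#' @param variables a list; each element a list with components `name`
#'   (character scalar), `states` (character vector, length >= 2) and
#'   `group` (one of the six group labels).
#' @return an object of class `bn_dictionary`.
#' @export
data_dictionary <- function(variables) {
  stopifnot(is.list(variables), length(variables) > 0)
  groups_ok <- c("selection", "prognostic", "prognosis", "treatment",
                 "risk_factor", "target")
  nm <- vapply(variables, function(v) v$name, character(1))
  if (anyDuplicated(nm))
    stop("duplicate variable names: ", paste(nm[duplicated(nm)], collapse = ", "))
  for (v in variables) {
    if (!is.character(v$states) || length(v$states) < 2)
      stop("variable '", v$name, "' must have at least 2 states")
    if (anyDuplicated(v$states))
      stop("variable '", v$name, "' has duplicate state labels")
    if (!v$group %in% groups_ok)
      stop("variable '", v$name, "' has unknown group '", v$group, "'")
  }
  sel <- nm[vapply(variables, function(v) v$group == "selection", logical(1))]
  if (length(sel) != 1L)
    stop("exactly one variable must be in group 'selection' (found ",
         length(sel), ")")
  names(variables) <- nm
  structure(list(variables = variables, selection = sel),
            class = "bn_dictionary")
}

#' @export
print.bn_dictionary <- function(x, ...) {
  cat("Data dictionary with", length(x$variables), "variables\n")
  for (v in x$variables)
    cat(sprintf("  %-24s [%s] %s\n", v$name, v$group,
                paste(v$states, collapse = "; ")))
  invisible(x)
}

dict_names  <- function(dict) names(dict$variables)
dict_states <- function(dict, var) dict$variables[[var]]$states
dict_arity  <- function(dict, var) length(dict$variables[[var]]$states)
dict_group  <- function(dict, var) dict$variables[[var]]$group

dict_vars_in_group <- function(dict, group) {
  nm <- dict_names(dict)
  nm[vapply(nm, function(v) dict_group(dict, v) %in% group, logical(1))]
}

yn <- c("Yes", "No")
ppn <- c("Pre", "Post", "No")

#' The full 25-variable cardio-oncology dictionary
#'
#' Returns the dictionary of the 25 discrete variables the cardiovascular
#' risk model is built over: the cohort context node, eight tumour
#' prognostic factors, 5-year vital status, nine treatment variables
#' (neoadjuvant and adjuvant), three cardiovascular risk factors and the
#' three target variables (cardiotoxicity, ischemic heart disease and the
#' composite 5-year CVD outcome).
#'
#' @return a `bn_dictionary` with 25 variables.
#' @export
#' @examples
#' d <- cvd_dictionary()
#' length(d$variables)
cvd_dictionary <- function() {
  v <- function(name, states, group) list(name = name, states = states, group = group)
  data_dictionary(list(
    v("cohort", c("PBC", "CBC"), "selection"),
    v("age35", yn, "prognostic"),
    v("histology",
      c("Ductal and lobular neoplasm", "Epithelial neoplasms, NOS",
        "Adenocarcinomas", "Neoplasms, NOS", "Other histologies"),
      "prognostic"),
    v("grade", c("Grade 1", "Grade 2", "Grade 3"), "prognostic"),
    v("vascular", yn, "prognostic"),
    v("ki67", yn, "prognostic"),
    v("receptors",
      c("Luminal", "Luminal A", "Luminal B", "Luminal HER2",
        "HER2-enriched", "triple-negative"),
      "prognostic"),
    v("pT", c("pT1", "pT2", "pT3", "pT4"), "prognostic"),
    v("pN", c("pN0", "pN+"), "prognostic"),
    v("death_in_5y", yn, "prognosis"),
    v("chemo_neo", yn, "treatment"),
    v("radio_neo", yn, "treatment"),
    v("target_neo", yn, "treatment"),
    v("hormon_neo", yn, "treatment"),
    v("surgery", c("Conservative", "Radical"), "treatment"),
    v("chemo_adju", yn, "treatment"),
    v("radio_adju", yn, "treatment"),
    v("target_adju", yn, "treatment"),
    v("hormons_adiu", yn, "treatment"),
    v("dyslipidemia", ppn, "risk_factor"),
    v("hypertension", ppn, "risk_factor"),
    v("t2db", ppn, "risk_factor"),
    v("cardiotoxicity", yn, "target"),
    v("ischemic_heart_disease", yn, "target"),
    v("cvds", yn, "target")
  ))
}

#' A 10-variable reduced dictionary for fast exact computation
#'
#' A sub-model preserving the tier skeleton (cohort, a prognostic block,
#' neoadjuvant chemotherapy, surgery, adjuvant chemotherapy, hypertension,
#' and the target block) whose full joint state space is small enough for
#' enumeration, so exact oracles are feasible in tests.
#'
#' @return a `bn_dictionary` with 10 variables.
#' @export
reduced_dictionary <- function() {
  v <- function(name, states, group) list(name = name, states = states, group = group)
  data_dictionary(list(
    v("cohort", c("PBC", "CBC"), "selection"),
    v("age35", yn, "prognostic"),
    v("grade", c("Grade 1", "Grade 2", "Grade 3"), "prognostic"),
    v("chemo_neo", yn, "treatment"),
    v("surgery", c("Conservative", "Radical"), "treatment"),
    v("chemo_adju", yn, "treatment"),
    v("hypertension", ppn, "risk_factor"),
    v("cardiotoxicity", yn, "target"),
    v("ischemic_heart_disease", yn, "target"),
    v("cvds", yn, "target")
  ))
}
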