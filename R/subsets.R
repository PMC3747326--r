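# Clinically defined case subsets. Each definition carries the predicate
# over individual attributes and the control-pool rule its test design
# requires (population controls for the classical GIF; all cases for the
# SubsetGIF; death-certificate-linked cases for phenotypes defined from
# death certificates).

#' Built-in case subset definitions
#'
#' Returns the catalogue of clinical subset definitions:
#' \describe{
#'   \item{all}{every case}
#'   \item{early_onset}{age at diagnosis < 50 years (strict)}
#'   \item{metastatic_at_dx}{metastatic disease at diagnosis}
#'   \item{other_primary}{at least one primary cancer of another site}
#'   \item{gleason_gt7}{Gleason score > 7 at diagnosis (strict)}
#'   \item{short_survival}{survival 0-9 months inclusive}
#'   \item{long_survival}{survival 240+ months}
#'   \item{high_bmi}{BMI >= 30 (inclusive)}
#'   \item{lethal}{the phenotype contributed to death (death-certificate
#'     cause); its control pool is restricted to cases with a linked death
#'     record}
#' }
#' A missing attribute always excludes a case from a subset (no imputation).
#'
#' @return Named list of definitions, each with `name`, `label`, `predicate`
#'   (a function of the individual table returning a logical vector) and
#'   `control_pool_rule` (`"population"`, `"all_cases"` or
#'   `"death_certificate_cases"`).
#' @export
subset_definitions <- function() {
  def <- function(name, label, predicate,
                  control_pool_rule = "all_cases") {
    list(name = name, label = label, predicate = predicate,
         control_pool_rule = control_pool_rule)
  }
  nz <- function(x) !is.na(x) & x     # missing => excluded
  list(
    all = def("all", "All cases", function(ind) rep(TRUE, nrow(ind)),
              control_pool_rule = "population"),
    early_onset = def("early_onset", "Age at diagnosis <50 years",
                      function(ind) nz(ind$age_at_diagnosis < 50)),
    metastatic_at_dx = def("metastatic_at_dx",
                           "Metastatic disease at diagnosis",
                           function(ind) nz(ind$metastatic)),
    other_primary = def("other_primary",
                        "At least 1 primary cancer of other site",
                        function(ind) nz(ind$other_primary_count >= 1)),
    gleason_gt7 = def("gleason_gt7", "Gleason score >7 at diagnosis",
                      function(ind) nz(ind$gleason > 7)),
    short_survival = def("short_survival", "Short survival (0-9 months)",
                         function(ind) nz(ind$survival_months >= 0 &
                                          ind$survival_months <= 9)),
    long_survival = def("long_survival", "Long survival (240+ months)",
                        function(ind) nz(ind$survival_months >= 240)),
    high_bmi = def("high_bmi", "High BMI (>=30)",
                   function(ind) nz(ind$bmi >= 30)),
    lethal = def("lethal", "Phenotype cause of death (lethal)",
                 function(ind) nz(ind$cause_of_death_phenotype),
                 control_pool_rule = "death_certificate_cases")
  )
}

#' Case ids of a genealogy
#'
#' @param g a [genealogy].
#' @param within optional id set to intersect with (e.g. the
#'   [ancestral_subset()]).
#' @return Character vector of ids with `is_case` TRUE.
#' @export
case_ids <- function(g, within = NULL) {
  stopifnot(inherits(g, "genealogy"))
  ids <- g$ind$id[!is.na(g$ind$is_case) & g$ind$is_case]
  if (!is.null(within)) ids <- intersect(ids, within)
  ids
}

#' Build a clinical subset of a case cohort
#'
#' Applies a subset definition's predicate to the case cohort. Cases missing
#' the attribute the predicate needs are excluded, never imputed.
#'
#' @param g a [genealogy].
#' @param cases character vector of case ids.
#' @param def a definition from [subset_definitions()], or its name.
#' @return Character vector of subset ids, with attributes `n`, `label` and
#'   `control_pool_rule`.
#' @examples
#' ped <- data.frame(id = c("a", "b"), father = "0", mother = "0",
#'                   sex = 1)
#' at <- data.frame(id = c("a", "b"), is_case = TRUE,
#'                  age_at_diagnosis = c(49, 50))
#' build_subset(genealogy(ped, at), c("a", "b"), "early_onset")  # "a"
#' @export
build_subset <- function(g, cases, def) {
  stopifnot(inherits(g, "genealogy"))
  if (is.character(def)) {
    defs <- subset_definitions()
    if (!def %in% names(defs))
      stop("unknown subset name: ", def, " (known: ",
           paste(names(defs), collapse = ", "), ")", call. = FALSE)
    def <- defs[[def]]
  }
  idx <- .gidx(g, cases)
  keep <- def$predicate(g$ind[idx, , drop = FALSE])
  out <- as.character(cases)[keep]
  structure(out, n = length(out), label = def$label,
            control_pool_rule = def$control_pool_rule)
}

#' Overlap between two case subsets
#'
#' Reports the overlap count and the percentage of `b` that also belongs to
#' `a`, the form in which subset overlaps are usually quoted (e.g. the share
#' of lethal cases with high BMI).
#'
#' @param a,b character id vectors.
#' @return List with `n_overlap`, `n_a`, `n_b` and `pct_of_b`
#'   (`100 * n_overlap / n_b`).
#' @export
subset_overlap <- function(a, b) {
  ov <- length(intersect(a, b))
  list(n_overlap = ov, n_a = length(unique(a)), n_b = length(unique(b)),
       pct_of_b = overlap_pct(ov, length(unique(b))))
}

#' Overlap percentage from counts
#'
#' @param n_overlap overlap count.
#' @param n_total denominator count.
#' @return `100 * n_overlap / n_total` (`NaN` when `n_total` is 0).
#' @export
overlap_pct <- function(n_overlap, n_total) 100 * n_overlap / n_total

#' Subset size table for a case cohort
#'
#' Applies every definition in [subset_definitions()] to the cohort and
#' tabulates the sizes, the usual first table of a familial clustering
#' report.
#'
#' @param g a [genealogy].
#' @param cases character vector of case ids.
#' @return data.frame with columns `name`, `label`, `n`.
#' @export
subset_sizes <- function(g, cases) {
  defs <- subset_definitions()
  data.frame(
    name = names(defs),
    label = vapply(defs, `[[`, "", "label"),
    n = vapply(defs, function(d) length(build_subset(g, cases, d)), 0L),
    row.names = NULL
  )
}
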