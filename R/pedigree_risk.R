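# High-risk pedigree identification: observed vs expected case counts among
# a founder's descendants, with a one-sided exact Poisson excess probability.

#' Sex- and birth-cohort-specific case rates
#'
#' Rates are computed internally from the analysed population (person-based
#' registry-style rates, not person-years): for each (sex, five-year birth
#' cohort) stratum, the rate is cases-in-stratum / persons-in-stratum.
#' Individuals with missing birth year or unknown sex are left out; strata
#' with no eligible persons carry no rate.
#'
#' @param g a [genealogy].
#' @param cases character vector of case ids.
#' @param population character vector of ids forming the reference
#'   population; `cases` must be contained in it.
#' @return An object of class `"rate_table"`: a data.frame with columns
#'   `sex`, `cohort`, `n`, `n_cases`, `rate`.
#' @export
cohort_rates <- function(g, cases, population) {
  stopifnot(inherits(g, "genealogy"), length(population) > 0)
  population <- unique(as.character(population))
  cases <- unique(as.character(cases))
  if (!all(cases %in% population))
    stop("cases must be contained in the reference population", call. = FALSE)
  idx <- .gidx(g, population)
  ok <- !is.na(g$ind$birth_year[idx]) & g$ind$sex[idx] != "unknown"
  idx <- idx[ok]; population <- population[ok]
  sex <- g$ind$sex[idx]
  cohort <- floor(g$ind$birth_year[idx] / 5) * 5
  is_case <- population %in% cases
  key <- paste(sex, cohort, sep = "|")
  tab <- data.frame(
    sex = vapply(split(sex, key), `[`, "", 1L),
    cohort = vapply(split(cohort, key), `[`, 0, 1L),
    n = vapply(split(is_case, key), length, 0L),
    n_cases = vapply(split(is_case, key), sum, 0L),
    row.names = NULL
  )
  tab$rate <- tab$n_cases / tab$n
  structure(tab[order(tab$sex, tab$cohort), ], class =
              c("rate_table", "data.frame"))
}

# Stratum rate per individual index; 0 where the stratum carries no rate
# (the individual then contributes nothing to the expectation).
.rate_lookup <- function(g, rates, idx) {
  key <- paste(g$ind$sex[idx], floor(g$ind$birth_year[idx] / 5) * 5,
               sep = "|")
  rkey <- paste(rates$sex, rates$cohort, sep = "|")
  r <- rates$rate[match(key, rkey)]
  r[is.na(r)] <- 0
  r
}

#' Expected case count among a founder's descendants
#'
#' Descendants are the transitive closure of child links below the founder,
#' intersected with the eligible (ancestrally complete) set; the expectation
#' is the sum of each descendant's (sex, cohort) stratum rate.
#'
#' @param g a [genealogy].
#' @param founder founder id.
#' @param rates a [cohort_rates()] table.
#' @param eligible character vector of eligible ids (e.g.
#'   [ancestral_subset()] output).
#' @return List with `descendants` (character ids) and `expected` (real).
#' @export
expected_cases <- function(g, founder, rates, eligible) {
  stopifnot(inherits(g, "genealogy"))
  desc <- intersect(descendants(g, founder), eligible)
  if (!length(desc)) return(list(descendants = character(), expected = 0))
  list(descendants = desc,
       expected = sum(.rate_lookup(g, rates, .gidx(g, desc))))
}

#' One-sided excess probability for an observed case count
#'
#' Exact upper-tail Poisson probability `P(X >= observed)` for `X` with mean
#' `expected`: the chance of seeing at least the observed number of cases in
#' a descendant set whose members' summed stratum rates give the expectation.
#'
#' @param observed nonnegative integer case count.
#' @param expected positive real expected count.
#' @return Probability in `(0, 1]`.
#' @examples
#' excess_p(56, 36)     # ~0.001
#' excess_p(76, 51.5)   # ~0.0008
#' @export
excess_p <- function(observed, expected) {
  if (observed < 0 || observed != round(observed))
    stop("observed must be a nonnegative integer", call. = FALSE)
  if (expected <= 0) {
    if (observed == 0) return(1)
    stop("expected must be positive when cases are observed", call. = FALSE)
  }
  stats::ppois(observed - 1, expected, lower.tail = FALSE)
}

#' Identify high-risk pedigrees by observed vs expected case counts
#'
#' For each founder, counts the phenotype cases among its eligible
#' descendants, computes the expected count from internal sex/birth-cohort
#' rates and reports the one-sided Poisson excess probability. Probabilities
#' are reported raw, with no correction for testing many founders.
#'
#' @param g a [genealogy].
#' @param cases character vector of case ids.
#' @param eligible character vector of eligible ids; rates are computed on
#'   this population unless `rates` is supplied.
#' @param rates optional [cohort_rates()] table.
#' @param founder_ids founders to test (default: all founders).
#' @param min_descendants only report founders with at least this many
#'   eligible descendants (default 2).
#' @return An object of class `"pedigree_risk"`: a data.frame with columns
#'   `founder`, `n_descendants`, `observed`, `expected`, `p`, sorted by `p`.
#' @export
pedigree_excess_test <- function(g, cases, eligible, rates = NULL,
                                 founder_ids = NULL, min_descendants = 2L) {
  stopifnot(inherits(g, "genealogy"))
  cases <- intersect(unique(as.character(cases)), eligible)
  if (is.null(rates)) rates <- cohort_rates(g, cases, eligible)
  if (is.null(founder_ids)) founder_ids <- founders(g)
  rows <- lapply(founder_ids, function(fid) {
    ec <- expected_cases(g, fid, rates, eligible)
    nd <- length(ec$descendants)
    if (nd < min_descendants) return(NULL)
    obs <- length(intersect(ec$descendants, cases))
    p <- if (ec$expected > 0) excess_p(obs, ec$expected) else 1
    data.frame(founder = fid, n_descendants = nd, observed = obs,
               expected = ec$expected, p = p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(founder = character(), n_descendants = integer(),
                      observed = integer(), expected = numeric(),
                      p = numeric())
  out <- out[order(out$p, -out$observed), ]
  rownames(out) <- NULL
  structure(out, class = c("pedigree_risk", "data.frame"))
}

#' @export
print.pedigree_risk <- function(x, n = 10L, ...) {
  cat("High-risk pedigree test:", nrow(x), "founders tested",
      "(one-sided Poisson excess, uncorrected)\n")
  print.data.frame(utils::head(x, n), digits = 4, row.names = FALSE)
  if (nrow(x) > n) cat("  ...", nrow(x) - n, "more founders\n")
  invisible(x)
}
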