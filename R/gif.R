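# Genealogical Index of Familiality: scaled mean pairwise kinship of a case
# set, referred to matched-control resampling for empirical significance.

#' Scale constant of the GIF statistic
#'
#' The GIF is the mean pairwise Malecot kinship over all unordered pairs in a
#' set, multiplied by 1e5 so that population-typical values land near the
#' printed magnitudes of the familiality literature (mean control GIF around
#' 5 in deep founder genealogies).
#' @export
GIF_SCALE <- 1e5

#' GIF statistic of a set of individuals
#'
#' `GIF(S) = GIF_SCALE * sum(phi(a, b)) / (n(n-1)/2)` over all unordered
#' pairs of `S`. Pairs with no common ancestor contribute zero.
#'
#' @param pk a [kinship_pairs()] result, or a kinship matrix from
#'   [kinship_matrix()] covering `ids`.
#' @param ids ids to evaluate (default: all ids covered by `pk`). At least 2.
#' @return Nonnegative scalar.
#' @examples
#' ped <- data.frame(id = c("f", "m", "s1", "s2"),
#'                   father = c("0", "0", "f", "f"),
#'                   mother = c("0", "0", "m", "m"), sex = c(1, 2, 1, 2))
#' g <- genealogy(ped)
#' gif_statistic(kinship_pairs(g, c("s1", "s2")))  # 25000
#' @export
gif_statistic <- function(pk, ids = NULL) {
  if (is.matrix(pk)) {
    if (is.null(ids)) ids <- rownames(pk)
    n <- length(ids)
    if (n < 2L) stop("GIF requires at least 2 individuals", call. = FALSE)
    K <- pk[ids, ids]
    return(GIF_SCALE * sum(K[upper.tri(K)]) / (n * (n - 1) / 2))
  }
  stopifnot(inherits(pk, "pair_kinship"))
  if (is.null(ids)) ids <- attr(pk, "ids")
  n <- length(ids)
  if (n < 2L) stop("GIF requires at least 2 individuals", call. = FALSE)
  keep <- pk$id1 %in% ids & pk$id2 %in% ids
  GIF_SCALE * sum(pk$phi[keep]) / (n * (n - 1) / 2)
}

#' Contribution to the GIF statistic by pairwise genetic distance
#'
#' Splits the GIF into additive per-distance terms: the entry for distance d
#' is `GIF_SCALE * sum(phi over pairs at distance d) / (n(n-1)/2)`.
#' Unreachable pairs contribute to no entry, so the entries sum to the total
#' GIF of the set.
#'
#' @param pk a [kinship_pairs()] result covering `ids`.
#' @param ids ids to evaluate (default: all ids covered by `pk`).
#' @return Named numeric vector, names = genetic distance.
#' @export
gif_by_distance <- function(pk, ids = NULL) {
  stopifnot(inherits(pk, "pair_kinship"))
  if (is.null(ids)) ids <- attr(pk, "ids")
  n <- length(ids)
  if (n < 2L) stop("GIF requires at least 2 individuals", call. = FALSE)
  keep <- pk$id1 %in% ids & pk$id2 %in% ids
  if (!any(keep)) return(stats::setNames(numeric(), character()))
  s <- vapply(split(pk$phi[keep], pk$distance[keep]), sum, 0)
  s <- s[order(as.numeric(names(s)))]
  GIF_SCALE * s / (n * (n - 1) / 2)
}

#' Matching key of an individual for control selection
#'
#' Controls are matched on sex, five-year birth cohort (the bin
#' `floor(birth_year / 5) * 5`), birth state (in-state or not) and, when the
#' case set was defined from death-certificate data, on the presence of a
#' linked death record.
#'
#' @param g a [genealogy].
#' @param ids individual ids.
#' @param need_death_record logical: does the design require controls with a
#'   death record?
#' @return Character vector of keys, `NA` where a matching variable is
#'   missing (such individuals are excluded from control pools).
#' @export
match_key <- function(g, ids, need_death_record = FALSE) {
  idx <- .gidx(g, ids)
  ind <- g$ind
  cohort <- floor(ind$birth_year[idx] / 5) * 5
  key <- paste(ind$sex[idx], cohort, ind$birth_in_state[idx],
               need_death_record, sep = "|")
  bad <- is.na(ind$birth_year[idx]) | ind$sex[idx] == "unknown" |
    is.na(ind$birth_in_state[idx])
  if (need_death_record)
    bad <- bad | is.na(ind$has_death_record[idx]) | !ind$has_death_record[idx]
  key[bad] <- NA_character_
  key
}

#' Draw matched control sets for a case set
#'
#' Each replicate draws, without replacement within the replicate, one
#' control per case from the pool, matching the case's key ([match_key()]).
#' When a stratum cannot supply enough controls the birth cohort window is
#' widened stepwise by +/- 5 years (recorded on the result) before failing
#' hard. Draws are reproducible from `seed` and independent across
#' replicates.
#'
#' @param g a [genealogy].
#' @param cases character vector of case ids (all matching variables must be
#'   present).
#' @param pool character vector of candidate control ids; members with
#'   missing matching variables are dropped (recorded on the result).
#' @param R number of control sets.
#' @param seed integer seed.
#' @param need_death_record restrict the pool to individuals with a death
#'   record and match on that fact.
#' @return List of `R` character vectors, each of length `length(cases)`,
#'   with attributes `widening` (per-stratum maximum cohort widening used, in
#'   years) and `excluded` (pool ids dropped for missing variables).
#' @export
draw_control_sets <- function(g, cases, pool, R, seed,
                              need_death_record = FALSE) {
  stopifnot(inherits(g, "genealogy"), R >= 1)
  cases <- as.character(cases); pool <- as.character(pool)

  ckey <- match_key(g, cases, need_death_record)
  if (anyNA(ckey))
    stop("case ", cases[is.na(ckey)][1L],
         " is missing a matching variable (birth year, sex or birth state)",
         call. = FALSE)
  pkey <- match_key(g, pool, need_death_record)
  excluded <- pool[is.na(pkey)]
  pool <- pool[!is.na(pkey)]; pkey <- pkey[!is.na(pkey)]

  pidx <- .gidx(g, pool)
  p_sex <- g$ind$sex[pidx]
  p_state <- g$ind$birth_in_state[pidx]
  p_cohort <- floor(g$ind$birth_year[pidx] / 5) * 5

  strata <- split(seq_along(cases), ckey)
  cidx <- .gidx(g, cases)
  # per stratum: the (sex, state) margin and target cohort
  s_info <- lapply(strata, function(ii) {
    i <- cidx[ii[1L]]
    list(k = length(ii), sex = g$ind$sex[i],
         state = g$ind$birth_in_state[i],
         cohort = floor(g$ind$birth_year[i] / 5) * 5)
  })
  # pool candidates per stratum per widening level w (|cohort - c| <= 5w)
  max_w <- ceiling(diff(range(c(p_cohort, vapply(s_info, `[[`, 0, "cohort")))) / 5) + 1L
  cand <- lapply(s_info, function(s) {
    margin <- which(p_sex == s$sex & p_state == s$state)
    lapply(0:max_w, function(w)
      margin[abs(p_cohort[margin] - s$cohort) <= 5 * w])
  })
  ord <- order(vapply(cand, function(cc) length(cc[[1L]]), 0L))

  widen_used <- stats::setNames(rep(0L, length(strata)), names(strata))
  sets <- .with_seed(seed, {
    lapply(seq_len(R), function(r) {
      used <- logical(length(pool))
      out <- character(length(cases))
      for (s in ord) {
        k <- s_info[[s]]$k
        w <- 0L
        repeat {
          avail <- cand[[s]][[w + 1L]]
          avail <- avail[!used[avail]]
          if (length(avail) >= k) break
          if (w >= max_w)
            stop("control stratum exhausted even after maximal cohort ",
                 "widening: ", names(strata)[s], call. = FALSE)
          w <- w + 1L
        }
        if (w > widen_used[s]) widen_used[s] <<- w
        pick <- avail[sample.int(length(avail), k)]
        used[pick] <- TRUE
        out[strata[[s]]] <- pool[pick]
      }
      out
    })
  })
  attr(sets, "widening") <- 5L * widen_used
  attr(sets, "excluded") <- excluded
  sets
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Empirical significance of a case GIF against control GIFs
#'
#' `p = #(control GIF >= case GIF) / R`; ties count as exceedances
#' (conservative). With zero exceedances the result is below the resolution
#' of the replicate count and is displayed as `"<1/R"` (e.g. `<0.001` at
#' R = 1000).
#'
#' @param case_gif scalar case statistic.
#' @param control_gifs numeric vector of control statistics (length `R >= 1`).
#' @return List with `p`, `below_resolution`, `n_exceed`, `R` and a `display`
#'   string.
#' @export
empirical_p <- function(case_gif, control_gifs) {
  R <- length(control_gifs)
  stopifnot(R >= 1)
  k <- sum(control_gifs >= case_gif)
  list(p = k / R, below_resolution = k == 0L, n_exceed = k, R = R,
       display = if (k == 0L) paste0("<", format(1 / R)) else
         format(round(k / R, max(3L, ceiling(log10(R)))), nsmall = 3L))
}

# Shared engine behind gif_test and subset_gif_test.
.gif_engine <- function(g, cases, pool, R, seed, by_distance,
                        include_cases, need_death_record, test_type,
                        label, call) {
  cases <- unique(as.character(cases))
  pool <- unique(as.character(pool))
  if (length(cases) < 2L)
    stop("GIF test requires at least 2 cases", call. = FALSE)
  if (R < 1L) stop("R must be at least 1", call. = FALSE)
  draw_pool <- if (include_cases) union(pool, cases) else setdiff(pool, cases)

  sets <- draw_control_sets(g, cases, draw_pool, R, seed,
                            need_death_record = need_death_record)
  members <- union(cases, unique(unlist(sets, use.names = FALSE)))
  K <- kinship_matrix(g, members)

  case_gif <- gif_statistic(K, cases)
  control_gifs <- vapply(sets, function(s) gif_statistic(K, s), 0)
  ep <- empirical_p(case_gif, control_gifs)

  bd <- NULL
  if (by_distance) {
    midx <- .gidx(g, members)
    clo <- .ancestor_closure(g, midx)
    maps <- .ancestor_dist_maps(g, clo)
    mem_maps <- stats::setNames(maps[match(midx, clo)], members)
    contrib <- function(set) {
      D <- .pair_distance_matrix(mem_maps[set])
      Ks <- K[set, set]
      ut <- upper.tri(D)
      fin <- ut & is.finite(D)
      s <- vapply(split(Ks[fin], D[fin]), sum, 0)
      GIF_SCALE * s / (length(set) * (length(set) - 1) / 2)
    }
    case_bd <- contrib(cases)
    ctrl_bd_list <- lapply(sets, contrib)
    dists <- sort(unique(as.numeric(c(names(case_bd),
                                      unlist(lapply(ctrl_bd_list, names))))))
    at <- function(v, d) ifelse(is.na(v[as.character(d)]), 0,
                                v[as.character(d)])
    bd <- data.frame(
      distance = dists,
      case = vapply(dists, function(d) unname(at(case_bd, d)), 0),
      control = vapply(dists, function(d)
        mean(vapply(ctrl_bd_list, function(v) unname(at(v, d)), 0)), 0)
    )
  }

  structure(list(
    test = test_type, label = label,
    n_cases = length(cases), cases = cases,
    case_gif = case_gif, control_gifs = control_gifs,
    mean_control_gif = mean(control_gifs),
    p = ep$p, below_resolution = ep$below_resolution,
    p_display = ep$display, R = R, seed = seed,
    by_distance = bd,
    pool_size = length(draw_pool), include_cases = include_cases,
    need_death_record = need_death_record,
    widening = attr(sets, "widening"),
    pool_excluded = attr(sets, "excluded"),
    call = call
  ), class = "gif_test")
}

#' Genealogical Index of Familiality test for excess relatedness
#'
#' Tests whether a set of cases is more related than expected for matched
#' members of the population. The case GIF (scaled mean pairwise Malecot
#' kinship, [gif_statistic()]) is compared with the GIF of `R` control sets
#' drawn from `pool` matched on sex, five-year birth cohort and birth state
#' ([draw_control_sets()]); significance is the fraction of control sets at
#' least as related as the cases ([empirical_p()]).
#'
#' @param g a [genealogy].
#' @param cases character vector of case ids (at least 2), normally a subset
#'   of [ancestral_subset()] output.
#' @param pool control pool ids; default `ancestral_subset(g)`. Cases are
#'   included in the pool by default (`include_cases`): the null hypothesis
#'   is that the case set is a random matched draw from the pool.
#' @param R number of matched control sets (default 1000).
#' @param seed integer seed for the control draws.
#' @param by_distance also decompose case and mean control GIF by pairwise
#'   genetic distance (slower; see [gif_by_distance()]).
#' @param include_cases keep case individuals in the control pool.
#' @param need_death_record restrict the control pool to individuals with a
#'   linked death record and match on that fact (used when the phenotype is
#'   defined from death-certificate data).
#' @return An object of class `"gif_test"` with `print`, `summary` and
#'   `plot` methods; fields include `case_gif`, `control_gifs`,
#'   `mean_control_gif`, `p`, `below_resolution` and (optionally) the
#'   per-distance decomposition `by_distance`.
#' @examples
#' cfg <- sim_config(n_founder_couples = 8, n_generations = 4, seed = 11)
#' g <- assign_phenotypes(simulate_genealogy(cfg), cfg)
#' cases <- case_ids(g)
#' pool <- eligible_pool(g, birth_cutoff_year = 3000)
#' if (length(cases) >= 2) {
#'   res <- gif_test(g, cases, pool, R = 50, seed = 1, by_distance = FALSE)
#'   print(res)
#' }
#' @export
gif_test <- function(g, cases, pool = NULL, R = 1000, seed = 1,
                     by_distance = TRUE, include_cases = TRUE,
                     need_death_record = FALSE) {
  stopifnot(inherits(g, "genealogy"))
  if (is.null(pool)) pool <- ancestral_subset(g)
  .gif_engine(g, cases, pool, R, seed, by_distance, include_cases,
              need_death_record, test_type = "population",
              label = "cases vs matched population controls",
              call = match.call())
}

#' SubsetGIF test: excess relatedness of a case subset over all cases
#'
#' The classical GIF test shows whether cases cluster more than the
#' population, but cannot say which clinical subset of cases clusters most.
#' The SubsetGIF draws the matched control sets from the full case cohort
#' instead of the population: a significant result means the subset is more
#' related than same-sized matched draws of cases at large, pointing to a
#' homogeneous subgroup worth targeting for predisposition-gene searches.
#' The subset's own GIF is identical to its value in the classical test
#' (same pairs); only the control distribution changes.
#'
#' @param g a [genealogy].
#' @param subset character vector of subset case ids; must be contained in
#'   `all_cases`.
#' @param all_cases the full case cohort that supplies the controls. When
#'   `need_death_record = TRUE` the pool is further restricted to cases with
#'   a linked death record (the convention for phenotypes defined from death
#'   certificates).
#' @inheritParams gif_test
#' @return A `"gif_test"` object with `test = "subset"`.
#' @export
subset_gif_test <- function(g, subset, all_cases, R = 1000, seed = 1,
                            by_distance = TRUE, include_cases = TRUE,
                            need_death_record = FALSE) {
  stopifnot(inherits(g, "genealogy"))
  subset <- unique(as.character(subset))
  all_cases <- unique(as.character(all_cases))
  if (!all(subset %in% all_cases))
    stop("subset must be contained in the case cohort", call. = FALSE)
  .gif_engine(g, subset, all_cases, R, seed, by_distance, include_cases,
              need_death_record, test_type = "subset",
              label = "case subset vs matched draws from all cases",
              call = match.call())
}

#' @export
print.gif_test <- function(x, ...) {
  cat(if (x$test == "subset") "SubsetGIF test" else "GIF test",
      "of excess relatedness\n")
  cat("  ", x$label, "\n", sep = "")
  cat(sprintf("  cases: %d   control sets: %d   pool: %d\n",
              x$n_cases, x$R, x$pool_size))
  cat(sprintf("  case GIF: %.2f   mean control GIF: %.2f\n",
              x$case_gif, x$mean_control_gif))
  cat("  empirical significance:",
      if (x$below_resolution) x$p_display else format(x$p), "\n")
  invisible(x)
}

#' @export
summary.gif_test <- function(object, ...) {
  print(object)
  q <- stats::quantile(object$control_gifs, c(.025, .5, .975))
  cat(sprintf("  control GIF quantiles: 2.5%% %.2f | median %.2f | 97.5%% %.2f\n",
              q[1], q[2], q[3]))
  if (any(object$widening > 0))
    cat("  cohort widening used (years):",
        paste0(names(object$widening)[object$widening > 0], "=",
               object$widening[object$widening > 0], collapse = ", "), "\n")
  if (!is.null(object$by_distance)) {
    cat("  contribution by genetic distance:\n")
    print(object$by_distance, row.names = FALSE, digits = 4)
  }
  invisible(object)
}

#' Plot the contribution to the GIF by genetic distance
#'
#' Side-by-side bars of the case contribution and the mean control
#' contribution at each pairwise genetic distance, the usual display for
#' judging how deep into the genealogy the excess relatedness extends.
#'
#' @param x a `"gif_test"` fitted with `by_distance = TRUE`.
#' @param ... passed to [graphics::barplot()].
#' @return The bar midpoints, invisibly.
#' @export
plot.gif_test <- function(x, ...) {
  if (is.null(x$by_distance))
    stop("refit with by_distance = TRUE to plot the decomposition",
         call. = FALSE)
  bd <- x$by_distance
  h <- rbind(case = bd$case, control = bd$control)
  mp <- graphics::barplot(h, beside = TRUE, names.arg = bd$distance,
                          xlab = "pairwise genetic distance",
                          ylab = "contribution to GIF",
                          legend.text = c("cases", "mean controls"), ...)
  invisible(mp)
}
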