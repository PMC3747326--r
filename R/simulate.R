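# Synthetic multigeneration founder populations with sex/birth-year
# structure and a familially clustered binary phenotype driven by a rare
# dominant variant dropped from founders. Used for calibration and power
# studies of the relatedness tests, and as the substrate for the
# gene-dropping kinship oracle.

#' Simulation configuration
#'
#' Collects every knob of the genealogy and phenotype simulator. The
#' defaults emulate a deep founder population of the registry kind: founder
#' couples born around 1850, a mean generation gap of 27 years (sd 4),
#' Poisson(2.6) offspring per couple, 85% marriage, and a 30% rate of
#' immigrant spouses who enter as new unrelated founders (an open
#' population). Spouse choice avoids pairs with kinship above 1/16,
#' reflecting an outbred population. The phenotype is male-only with
#' baseline risk 0.08; a rare dominant variant (founder allele frequency
#' 0.03) raises penetrance to 0.7 and strongly increases the probability
#' that the phenotype contributes to death (0.75 vs 0.12), so carrier-rich
#' subsets cluster in the genealogy.
#'
#' Setting `penetrance_carrier = penetrance_noncarrier` (or
#' `variant_founder_freq = 0`) gives an exact null in which case status is
#' independent of pedigree structure.
#'
#' @param n_founder_couples founder couples in generation 0.
#' @param n_generations total generations simulated (>= 2).
#' @param offspring_mean Poisson mean offspring per couple.
#' @param immigrant_spouse_rate probability a marrying individual takes an
#'   immigrant (new-founder) spouse outright.
#' @param marriage_rate probability an individual of a non-final generation
#'   marries at all.
#' @param max_spouse_kinship spouses with kinship above this are not paired
#'   within the population (an immigrant spouse is used instead).
#' @param founder_birth_year mean birth year of generation-0 founders.
#' @param generation_gap_mean,generation_gap_sd child birth year offset from
#'   the parents' mean birth year.
#' @param sex_ratio probability male.
#' @param p_in_state_founder probability a founder/immigrant was born
#'   in-state (native-born descendants always are).
#' @param p_death_record probability an individual has a linked death
#'   record (forced TRUE when the phenotype contributes to death).
#' @param variant_founder_freq founder allele frequency of the dominant risk
#'   variant.
#' @param penetrance_carrier,penetrance_noncarrier male phenotype
#'   probability by carrier status.
#' @param attribute_model named list of clinical attribute distributions;
#'   see Details. Any entry supplied overrides the default.
#' @param seed integer seed; the whole simulation is deterministic given the
#'   config.
#'
#' @details The attribute model entries (defaults in parentheses): normal
#' age at diagnosis `age_mean` (72), `age_sd` (9) with carrier shift
#' `age_carrier_shift` (-12); normal BMI `bmi_mean` (27), `bmi_sd` (4.5),
#' carrier shift `bmi_carrier_shift` (1), observed with probability
#' `p_bmi_observed` (0.65); Gleason categorical `gleason_probs` over scores
#' 6-10 (0.40, 0.30, 0.15, 0.10, 0.05); lognormal survival months with
#' `survival_meanlog`/`survival_sdlog` (log 120, 0.7) and
#' `survival_meanlog_lethal`/`survival_sdlog_lethal` (log 30, 0.8) for
#' lethal cases; metastatic probability `p_metastatic` (0.06) /
#' `p_metastatic_carrier` (0.12); Poisson other-primary count
#' `other_primary_mean` (0.18); lethal probability `lethal_carrier` (0.75) /
#' `lethal_noncarrier` (0.12).
#'
#' @return An object of class `"sim_config"` (a validated named list).
#' @export
sim_config <- function(n_founder_couples = 25,
                       n_generations = 5,
                       offspring_mean = 2.6,
                       immigrant_spouse_rate = 0.3,
                       marriage_rate = 0.85,
                       max_spouse_kinship = 1 / 16,
                       founder_birth_year = 1850,
                       generation_gap_mean = 27,
                       generation_gap_sd = 4,
                       sex_ratio = 0.5,
                       p_in_state_founder = 0.3,
                       p_death_record = 0.75,
                       variant_founder_freq = 0.03,
                       penetrance_carrier = 0.7,
                       penetrance_noncarrier = 0.08,
                       attribute_model = list(),
                       seed = 1L) {
  am <- list(age_mean = 72, age_sd = 9, age_carrier_shift = -12,
             bmi_mean = 27, bmi_sd = 4.5, bmi_carrier_shift = 1,
             p_bmi_observed = 0.65,
             gleason_probs = c(`6` = .40, `7` = .30, `8` = .15,
                               `9` = .10, `10` = .05),
             survival_meanlog = log(120), survival_sdlog = 0.7,
             survival_meanlog_lethal = log(30), survival_sdlog_lethal = 0.8,
             p_metastatic = 0.06, p_metastatic_carrier = 0.12,
             other_primary_mean = 0.18,
             lethal_carrier = 0.75, lethal_noncarrier = 0.12)
  am[names(attribute_model)] <- attribute_model

  cfg <- list(n_founder_couples = as.integer(n_founder_couples),
              n_generations = as.integer(n_generations),
              offspring_mean = offspring_mean,
              immigrant_spouse_rate = immigrant_spouse_rate,
              marriage_rate = marriage_rate,
              max_spouse_kinship = max_spouse_kinship,
              founder_birth_year = founder_birth_year,
              generation_gap_mean = generation_gap_mean,
              generation_gap_sd = generation_gap_sd,
              sex_ratio = sex_ratio,
              p_in_state_founder = p_in_state_founder,
              p_death_record = p_death_record,
              variant_founder_freq = variant_founder_freq,
              penetrance_carrier = penetrance_carrier,
              penetrance_noncarrier = penetrance_noncarrier,
              attribute_model = am,
              seed = as.integer(seed))
  probs <- c(cfg$immigrant_spouse_rate, cfg$marriage_rate, cfg$sex_ratio,
             cfg$p_in_state_founder, cfg$p_death_record,
             cfg$variant_founder_freq, cfg$penetrance_carrier,
             cfg$penetrance_noncarrier, am$p_bmi_observed, am$p_metastatic,
             am$p_metastatic_carrier, am$lethal_carrier, am$lethal_noncarrier)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (cfg$n_generations < 2L)
    stop("n_generations must be at least 2", call. = FALSE)
  if (cfg$n_founder_couples < 1L || cfg$offspring_mean <= 0)
    stop("need at least one founder couple and positive offspring mean",
         call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", x$n_founder_couples, "founder couples,",
      x$n_generations, "generations, Poisson(", x$offspring_mean,
      ") offspring, seed", x$seed, "\n")
  cat(sprintf("  variant freq %.3f, penetrance %.2f (carrier) / %.2f, lethal %.2f / %.2f\n",
              x$variant_founder_freq, x$penetrance_carrier,
              x$penetrance_noncarrier, x$attribute_model$lethal_carrier,
              x$attribute_model$lethal_noncarrier))
  invisible(x)
}

#' Simulate a multigeneration genealogy
#'
#' Generation 0 consists of unrelated founder couples. Each later generation
#' is produced by Poisson offspring of the previous generation's couples;
#' marrying individuals are paired within their generation subject to the
#' kinship ceiling, and the remainder (or those drawn as such outright)
#' receive immigrant spouses who enter the genealogy as new founders.
#' Native-born individuals are born in-state; founder/immigrant in-state
#' status and death-record linkage are Bernoulli. The result is fully
#' deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return A [genealogy] with `birth_year`, `birth_in_state`,
#'   `has_death_record` and sex filled in (no phenotype yet; see
#'   [assign_phenotypes()]).
#' @export
simulate_genealogy <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, .simulate_genealogy_impl(cfg))
}

.simulate_genealogy_impl <- function(cfg) {
  cap <- 512L
  K <- matrix(0, cap, cap)
  sex <- character(cap); by <- integer(cap); instate <- logical(cap)
  father <- integer(cap); mother <- integer(cap)
  n <- 0L

  grow <- function() {
    cap2 <- 2L * cap
    K2 <- matrix(0, cap2, cap2); K2[1:cap, 1:cap] <- K
    K <<- K2
    length(sex) <<- cap2; length(by) <<- cap2; length(instate) <<- cap2
    length(father) <<- cap2; length(mother) <<- cap2
    cap <<- cap2
  }
  add <- function(f, m, sx, b, st) {
    if (n + 1L > cap) grow()
    i <- n + 1L
    if (is.na(f)) {                      # founder: unrelated, non-inbred
      K[i, i] <<- 0.5
    } else {
      if (i > 1L) {
        prev <- seq_len(i - 1L)
        v <- 0.5 * (K[f, prev] + K[m, prev])
        K[i, prev] <<- v; K[prev, i] <<- v
      }
      K[i, i] <<- 0.5 * (1 + K[f, m])
    }
    father[i] <<- f; mother[i] <<- m
    sex[i] <<- sx; by[i] <<- b; instate[i] <<- st
    n <<- i
    i
  }
  new_founder <- function(sx, b) {
    add(NA_integer_, NA_integer_, sx, b,
        stats::runif(1) < cfg$p_in_state_founder)
  }

  couples <- matrix(NA_integer_, 0L, 2L)   # father, mother columns
  for (ci in seq_len(cfg$n_founder_couples)) {
    b <- round(cfg$founder_birth_year + stats::rnorm(1, 0, 5))
    couples <- rbind(couples, c(new_founder("male", b),
                                new_founder("female", b + round(stats::rnorm(1, 0, 3)))))
  }

  for (gen in seq_len(cfg$n_generations - 1L)) {
    kids <- integer()
    for (r in seq_len(nrow(couples))) {
      f <- couples[r, 1L]; m <- couples[r, 2L]
      nk <- stats::rpois(1, cfg$offspring_mean)
      if (nk == 0L) next
      bmid <- mean(c(by[f], by[m]))
      for (k in seq_len(nk)) {
        sx <- if (stats::runif(1) < cfg$sex_ratio) "male" else "female"
        b <- round(bmid + stats::rnorm(1, cfg$generation_gap_mean,
                                       cfg$generation_gap_sd))
        kids <- c(kids, add(f, m, sx, b, TRUE))
      }
    }
    if (!length(kids))
      stop("simulated population died out before generation ",
           cfg$n_generations, "; raise offspring_mean or founder couples",
           call. = FALSE)
    if (gen == cfg$n_generations - 1L) break

    marrying <- kids[stats::runif(length(kids)) < cfg$marriage_rate]
    males <- sample(marrying[sex[marrying] == "male"])
    females <- marrying[sex[marrying] == "female"]
    couples <- matrix(NA_integer_, 0L, 2L)
    for (mi in males) {
      spouse <- NA_integer_
      if (stats::runif(1) >= cfg$immigrant_spouse_rate && length(females)) {
        ok <- females[K[mi, females] <= cfg$max_spouse_kinship]
        if (length(ok)) {
          spouse <- ok[sample.int(length(ok), 1L)]
          females <- setdiff(females, spouse)
        }
      }
      if (is.na(spouse))
        spouse <- new_founder("female", by[mi] + round(stats::rnorm(1, 0, 3)))
      couples <- rbind(couples, c(mi, spouse))
    }
    for (fi in females) {             # remaining marrying females
      spouse <- new_founder("male", by[fi] + round(stats::rnorm(1, 0, 3)))
      couples <- rbind(couples, c(spouse, fi))
    }
    if (!nrow(couples))
      stop("no couples formed in generation ", gen, call. = FALSE)
  }

  ids <- paste0("I", seq_len(n))
  ped <- data.frame(
    id = ids,
    father = ifelse(is.na(father[1:n]), "0", paste0("I", father[1:n])),
    mother = ifelse(is.na(mother[1:n]), "0", paste0("I", mother[1:n])),
    sex = ifelse(sex[1:n] == "male", "1", "2")
  )
  attrs <- data.frame(
    id = ids,
    birth_year = by[1:n],
    birth_in_state = instate[1:n],
    has_death_record = stats::runif(n) < cfg$p_death_record
  )
  genealogy(ped, attrs)
}

#' Drop a rare dominant variant and assign phenotypes
#'
#' A biallelic variant is dropped from the founders (each founder allele is
#' the risk allele with probability `variant_founder_freq`) through Mendelian
#' inheritance. Male phenotype status is Bernoulli with penetrance by carrier
#' status (equal penetrances give an exact null); only males are eligible
#' cases. Cases receive clinical attributes from the configured attribute
#' model, with carrier-dependent early-onset and lethality enrichment; a
#' lethal case always has a death record. Attributes are missing where the
#' registry realistically would not observe them (e.g. BMI).
#'
#' @param g a [genealogy] from [simulate_genealogy()].
#' @param cfg the [sim_config()] used to build it.
#' @param seed seed for the phenotype draw (default `cfg$seed + 1`).
#' @return The genealogy with phenotype/attribute columns filled in, plus a
#'   `carriers` attribute: a data.frame of `id`, `n_variant_alleles`,
#'   `carrier` (the simulation truth, for power evaluation).
#' @export
assign_phenotypes <- function(g, cfg, seed = cfg$seed + 1L) {
  stopifnot(inherits(g, "genealogy"), inherits(cfg, "sim_config"))
  .with_seed(seed, .assign_phenotypes_impl(g, cfg))
}

.assign_phenotypes_impl <- function(g, cfg) {
  n <- nrow(g$ind)
  am <- cfg$attribute_model
  a1 <- logical(n); a2 <- logical(n)
  for (d in sort(unique(g$depth))) {
    at <- which(g$depth == d)
    fo <- at[is.na(g$father[at]) & is.na(g$mother[at])]
    a1[fo] <- stats::runif(length(fo)) < cfg$variant_founder_freq
    a2[fo] <- stats::runif(length(fo)) < cfg$variant_founder_freq
    nf <- setdiff(at, fo)
    if (length(nf)) {
      pf <- g$father[nf]; pm <- g$mother[nf]
      # a missing parent acts as a fresh founder at the population frequency
      from_f <- ifelse(stats::runif(length(nf)) < 0.5,
                       a1[ifelse(is.na(pf), 1L, pf)],
                       a2[ifelse(is.na(pf), 1L, pf)])
      from_f[is.na(pf)] <- stats::runif(sum(is.na(pf))) <
        cfg$variant_founder_freq
      from_m <- ifelse(stats::runif(length(nf)) < 0.5,
                       a1[ifelse(is.na(pm), 1L, pm)],
                       a2[ifelse(is.na(pm), 1L, pm)])
      from_m[is.na(pm)] <- stats::runif(sum(is.na(pm))) <
        cfg$variant_founder_freq
      a1[nf] <- from_f
      a2[nf] <- from_m
    }
  }
  carrier <- a1 | a2

  ind <- g$ind
  male <- ind$sex == "male"
  pen <- ifelse(carrier, cfg$penetrance_carrier, cfg$penetrance_noncarrier)
  ind$is_case <- male & stats::runif(n) < pen
  ci <- which(ind$is_case)
  nc <- length(ci)
  if (nc) {
    carc <- carrier[ci]
    ind$age_at_diagnosis[ci] <- pmax(35, round(stats::rnorm(
      nc, am$age_mean + ifelse(carc, am$age_carrier_shift, 0), am$age_sd), 1))
    bmi <- round(stats::rnorm(
      nc, am$bmi_mean + ifelse(carc, am$bmi_carrier_shift, 0), am$bmi_sd), 1)
    bmi[stats::runif(nc) >= am$p_bmi_observed] <- NA_real_
    ind$bmi[ci] <- bmi
    ind$gleason[ci] <- as.integer(names(am$gleason_probs))[
      sample.int(length(am$gleason_probs), nc, replace = TRUE,
                 prob = am$gleason_probs)]
    ind$metastatic[ci] <- stats::runif(nc) <
      ifelse(carc, am$p_metastatic_carrier, am$p_metastatic)
    ind$other_primary_count[ci] <- stats::rpois(nc, am$other_primary_mean)

    lethal <- stats::runif(nc) <
      ifelse(carc, am$lethal_carrier, am$lethal_noncarrier)
    ind$has_death_record[ci[lethal]] <- TRUE
    cod <- rep(NA, nc)
    cod[ind$has_death_record[ci]] <- lethal[ind$has_death_record[ci]]
    ind$cause_of_death_phenotype[ci] <- cod
    surv <- ifelse(lethal,
                   stats::rlnorm(nc, am$survival_meanlog_lethal,
                                 am$survival_sdlog_lethal),
                   stats::rlnorm(nc, am$survival_meanlog, am$survival_sdlog))
    ind$survival_months[ci] <- pmin(480, round(surv))
  }
  # non-case decedents: phenotype did not contribute to death
  dc <- !is.na(ind$has_death_record) & ind$has_death_record &
    is.na(ind$cause_of_death_phenotype)
  ind$cause_of_death_phenotype[dc] <- FALSE

  out <- g
  out$ind <- ind
  attr(out, "carriers") <- data.frame(
    id = ind$id, n_variant_alleles = a1 + a2, carrier = carrier)
  out
}

#' Documented power configuration for the subset relatedness test
#'
#' The reference alternative-hypothesis configuration used by the package's
#' power study: a deep open population (80 founder couples, 6 generations,
#' Poisson(3) offspring) segregating a rare dominant variant (founder allele
#' frequency 0.005) with penetrance 0.9 against a 0.10 sporadic male
#' baseline, and a strongly carrier-dependent probability that the phenotype
#' contributes to death (0.9 vs 0.05). Under this configuration the lethal
#' subset is dominated by members of one or two carrier lineages and should
#' show excess relatedness over the case cohort at large.
#'
#' @param seed integer seed.
#' @param ... overrides passed on to [sim_config()].
#' @return A [sim_config()].
#' @export
power_config <- function(seed = 1L, ...) {
  args <- list(n_founder_couples = 80, n_generations = 6,
               offspring_mean = 3.0, variant_founder_freq = 0.005,
               penetrance_carrier = 0.9, penetrance_noncarrier = 0.10,
               attribute_model = list(lethal_carrier = 0.9,
                                      lethal_noncarrier = 0.05),
               seed = seed)
  ovr <- list(...)
  args[names(ovr)] <- ovr
  do.call(sim_config, args)
}

#' Simulate one power-study cohort with a segregating variant
#'
#' Power of the subset test is evaluated conditional on the alternative
#' actually being present in the analysable sample: a cohort in which the
#' variant never reached the eligible cases carries no signal whatever the
#' test does. This helper therefore redraws cohorts (advancing the seed)
#' until the eligible case set contains at least `min_carrier_cases`
#' carriers, the lethal subset has at least `min_subset` members and the
#' case cohort is at least twice the subset, then returns the pieces the
#' test needs.
#'
#' @param seed starting seed; each retry increments it by 1.
#' @param cfg_fun function mapping a seed to a [sim_config()] (default
#'   [power_config()]).
#' @param min_carrier_cases,min_subset,max_tries acceptance thresholds and
#'   retry bound.
#' @return List with the phenotyped genealogy `g`, `cases` (eligible case
#'   ids), `subset` (lethal subset ids), `n_carrier_cases`, and `seed_used`;
#'   errors if no acceptable cohort arises within `max_tries`.
#' @export
simulate_power_cohort <- function(seed, cfg_fun = power_config,
                                  min_carrier_cases = 6L, min_subset = 5L,
                                  max_tries = 40L) {
  for (k in seq_len(max_tries)) {
    s <- seed + k - 1L
    cfg <- cfg_fun(s)
    g <- assign_phenotypes(simulate_genealogy(cfg), cfg)
    cases <- case_ids(g, within = eligible_pool(g, sex = "male"))
    tr <- attr(g, "carriers")
    ncarr <- sum(tr$carrier[match(cases, tr$id)])
    if (ncarr < min_carrier_cases) next
    subset <- build_subset(g, cases, "lethal")
    if (length(subset) < min_subset || length(cases) < 2L * length(subset))
      next
    return(list(g = g, cases = cases, subset = as.character(subset),
                n_carrier_cases = ncarr, seed_used = s))
  }
  stop("no cohort with a segregating variant arose within ", max_tries,
       " tries", call. = FALSE)
}

#' Gene-dropping Monte Carlo estimate of the kinship coefficient
#'
#' An independent oracle for [kinship()]: founders receive globally unique
#' allele labels, alleles are transmitted by fair Mendelian choice down the
#' pedigree `reps` times, and the kinship estimate is the average over
#' replicates of the fraction of the four cross-individual allele pairings
#' that are identical by descent.
#'
#' @param g a [genealogy].
#' @param a,b individual ids (may be equal, giving self-kinship).
#' @param reps number of gene-drop replicates.
#' @param seed integer seed.
#' @return List with `estimate`, `se` (sample standard error) and `reps`.
#' @export
kinship_mc_oracle <- function(g, a, b, reps = 1e5, seed = 1L) {
  stopifnot(inherits(g, "genealogy"), reps >= 1)
  i <- .gidx(g, a); j <- .gidx(g, b)
  clo <- .ancestor_closure(g, c(i, j))
  ord <- clo[order(g$depth[clo])]
  loc <- match(seq_len(nrow(g$ind)), clo)

  .with_seed(seed, {
    A1 <- vector("list", length(clo)); A2 <- vector("list", length(clo))
    for (gi in ord) {
      li <- loc[gi]
      f <- g$father[gi]; m <- g$mother[gi]
      # a missing parent contributes a unique (never-IBD) allele label
      A1[[li]] <- if (is.na(f)) rep.int(2L * gi - 1L, reps) else {
        pick <- stats::runif(reps) < 0.5
        ifelse(pick, A1[[loc[f]]], A2[[loc[f]]])
      }
      A2[[li]] <- if (is.na(m)) rep.int(2L * gi, reps) else {
        pick <- stats::runif(reps) < 0.5
        ifelse(pick, A1[[loc[m]]], A2[[loc[m]]])
      }
    }
    x1 <- A1[[loc[i]]]; x2 <- A2[[loc[i]]]
    y1 <- A1[[loc[j]]]; y2 <- A2[[loc[j]]]
    ibd <- ((x1 == y1) + (x1 == y2) + (x2 == y1) + (x2 == y2)) / 4
    list(estimate = mean(ibd),
         se = stats::sd(ibd) / sqrt(reps),
         reps = reps)
  })
}
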