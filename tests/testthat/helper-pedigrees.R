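# Canonical relationship fixtures, built in code. All founders unrelated.

ped_trio <- function() {
  genealogy(data.frame(id = c("f", "m", "c"),
                       father = c("0", "0", "f"),
                       mother = c("0", "0", "m"),
                       sex = c(1, 2, 1)))
}

# two full siblings of unrelated founder parents
ped_siblings <- function() {
  genealogy(data.frame(id = c("f", "m", "s1", "s2"),
                       father = c("0", "0", "f", "f"),
                       mother = c("0", "0", "m", "m"),
                       sex = c(1, 2, 1, 2)))
}

# uncle "u" and nephew "n" (u is full sib of n's father "p")
ped_avuncular <- function() {
  genealogy(data.frame(id = c("gf", "gm", "u", "p", "sp", "n"),
                       father = c("0", "0", "gf", "gf", "0", "p"),
                       mother = c("0", "0", "gm", "gm", "0", "sp"),
                       sex = c(1, 2, 1, 1, 2, 1)))
}

# first cousins "c1","c2" (their fathers are full sibs)
ped_cousins <- function() {
  genealogy(data.frame(
    id = c("gf", "gm", "p1", "p2", "w1", "w2", "c1", "c2"),
    father = c("0", "0", "gf", "gf", "0", "0", "p1", "p2"),
    mother = c("0", "0", "gm", "gm", "0", "0", "w1", "w2"),
    sex = c(1, 2, 1, 1, 2, 2, 1, 2)))
}

# cousins pedigree extended one generation: c2's child "k" is c1's first
# cousin once removed
ped_cousins_once_removed <- function() {
  base <- data.frame(
    id = c("gf", "gm", "p1", "p2", "w1", "w2", "c1", "c2"),
    father = c("0", "0", "gf", "gf", "0", "0", "p1", "p2"),
    mother = c("0", "0", "gm", "gm", "0", "0", "w1", "w2"),
    sex = c(1, 2, 1, 1, 2, 2, 1, 2))
  ext <- data.frame(id = c("h", "k"), father = c("0", "h"),
                    mother = c("0", "c2"), sex = c(1, 1))
  genealogy(rbind(base, ext))
}

# child of first cousins (inbred)
ped_inbred_child <- function() {
  base <- data.frame(
    id = c("gf", "gm", "p1", "p2", "w1", "w2", "c1", "c2"),
    father = c("0", "0", "gf", "gf", "0", "0", "p1", "p2"),
    mother = c("0", "0", "gm", "gm", "0", "0", "w1", "w2"),
    sex = c(1, 2, 1, 1, 2, 2, 1, 2))
  genealogy(rbind(base, data.frame(id = "k", father = "c1", mother = "c2",
                                   sex = 1)))
}

# parent couple with two children: pairs at distance 1 (parent/child) and 2
ped_nuclear3 <- function() {
  genealogy(data.frame(id = c("p", "q", "a", "b"),
                       father = c("0", "0", "p", "p"),
                       mother = c("0", "0", "q", "q"),
                       sex = c(1, 2, 1, 1)))
}

# a small random genealogy via the simulator (deterministic per seed)
random_genealogy <- function(seed, couples = 6, generations = 4,
                             offspring = 2.5) {
  simulate_genealogy(sim_config(n_founder_couples = couples,
                                n_generations = generations,
                                offspring_mean = offspring,
                                seed = seed))
}

# 3-generation fully recorded pedigree with configurable birth years, used
# for the ancestral-completeness filter. Returns the genealogy; the proband
# is "x". drop_ggp: how many of the 8 great-grandparent links to sever.
ped_ancestry <- function(proband_birth = 1950, drop_ggp = 0,
                         proband_birth_missing = FALSE) {
  ggp_ids <- paste0("g", 1:8)   # great-grandparents (4 couples)
  gp_ids <- paste0("G", 1:4)    # grandparents
  ped <- data.frame(
    id = c(ggp_ids, gp_ids, "pa", "mo", "x"),
    father = c(rep("0", 8),
               "g1", "g3", "g5", "g7",
               "G1", "G3", "pa"),
    mother = c(rep("0", 8),
               "g2", "g4", "g6", "g8",
               "G2", "G4", "mo"),
    sex = c(rep(c(1, 2), 4), 1, 2, 1, 2, 1, 2, 1))
  if (drop_ggp > 0) {
    # sever great-grandparent links positionally, keep individuals out
    sever <- c("g2", "g4", "g6", "g8", "g1", "g3", "g5", "g7")[seq_len(drop_ggp)]
    ped$father[ped$father %in% sever] <- "0"
    ped$mother[ped$mother %in% sever] <- "0"
    ped <- ped[!ped$id %in% sever, ]
  }
  attrs <- data.frame(id = "x",
                      birth_year = if (proband_birth_missing) NA_integer_
                                   else proband_birth)
  genealogy(ped, attrs)
}

# small cohort with known attributes for subset-definition tests
attr_cohort <- function() {
  ids <- paste0("c", 1:8)
  ped <- data.frame(id = ids, father = "0", mother = "0", sex = 1)
  attrs <- data.frame(
    id = ids,
    is_case = TRUE,
    age_at_diagnosis = c(49, 50, 62, NA, 70, 45, 80, 66),
    gleason = c(7, 8, 6, 9, NA, 7, 10, 6),
    survival_months = c(9, 10, 0, 250, 240, NA, 100, 239),
    bmi = c(30.0, 29.9, 35, NA, 28, 31, 30.0, 25),
    metastatic = c(TRUE, FALSE, NA, TRUE, FALSE, FALSE, TRUE, FALSE),
    other_primary_count = c(0, 1, 2, 0, NA, 0, 1, 0),
    has_death_record = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE),
    cause_of_death_phenotype = c(TRUE, FALSE, NA, TRUE, FALSE, NA, TRUE, FALSE),
    birth_year = c(1920, 1921, 1933, 1928, 1930, 1941, 1925, 1935),
    birth_in_state = TRUE)
  genealogy(ped, attrs)
}
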