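# Attribute columns the package knows about; anything else in an attribute
# table is carried along untouched.
.famgif_attr_cols <- c(
  "birth_year", "birth_in_state", "has_death_record", "is_case",
  "age_at_diagnosis", "gleason", "metastatic", "survival_months",
  "other_primary_count", "bmi", "cause_of_death_phenotype"
)

.famgif_attr_types <- c(
  birth_year = "integer", birth_in_state = "logical",
  has_death_record = "logical", is_case = "logical",
  age_at_diagnosis = "numeric", gleason = "integer", metastatic = "logical",
  survival_months = "numeric", other_primary_count = "integer",
  bmi = "numeric", cause_of_death_phenotype = "logical"
)

#' Construct a genealogy from pedigree and attribute tables
#'
#' A genealogy is a directed acyclic parent-link graph over individuals. Each
#' individual carries an opaque string id, optional father/mother links, a sex
#' code and an open set of per-individual attributes (birth year, case status,
#' clinical variables, ...). Founders are individuals with no recorded
#' parents; they are assumed mutually unrelated and non-inbred, which is the
#' usual convention for registry genealogies whose records simply stop.
#'
#' Structural validation is strict: duplicate ids, parent ids that do not
#' resolve, self-parenthood, identical father and mother, cycles, and
#' sex-inconsistent parental roles (an individual recorded as female listed as
#' a father, or vice versa) are all rejected at construction with an
#' informative error.
#'
#' @param pedigree data.frame with columns `id`, `father`, `mother`, `sex`.
#'   `"0"`, `""` and `NA` denote a missing parent. Sex may be coded `1`/`2`/`0`
#'   or `"male"`/`"female"`/`"unknown"`.
#' @param attributes optional data.frame keyed by an `id` column, one row per
#'   individual; every id must be present in `pedigree`. Recognised columns:
#'   `birth_year`, `birth_in_state`, `has_death_record`, `is_case`,
#'   `age_at_diagnosis`, `gleason`, `metastatic`, `survival_months`,
#'   `other_primary_count`, `bmi`, `cause_of_death_phenotype`.
#'
#' @return An object of class `"genealogy"`: a list with the individual table
#'   (`$ind`), integer parent indices (`$father`, `$mother`) and the
#'   generation depth of every individual (`$depth`, length of the longest
#'   parent chain above it; founders have depth 0).
#'
#' @examples
#' ped <- data.frame(id = c("f", "m", "c"), father = c("0", "0", "f"),
#'                   mother = c("0", "0", "m"), sex = c(1, 2, 1))
#' g <- genealogy(ped)
#' founders(g)
#' @seealso [read_genealogy()], [kinship()], [genetic_distance()],
#'   [ancestral_subset()]
#' @export
genealogy <- function(pedigree, attributes = NULL) {
  req <- c("id", "father", "mother", "sex")
  if (!all(req %in% names(pedigree)))
    stop("pedigree table must have columns id, father, mother, sex",
         call. = FALSE)

  id <- as.character(pedigree$id)
  if (anyNA(id) || any(id == "" | id == "0"))
    stop("invalid individual id (empty, '0' or NA)", call. = FALSE)
  if (anyDuplicated(id))
    stop("duplicate individual id: ", id[duplicated(id)][1L], call. = FALSE)

  norm_parent <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "0" | x == ""] <- NA_character_
    x
  }
  father_id <- norm_parent(pedigree$father)
  mother_id <- norm_parent(pedigree$mother)

  sex <- .parse_sex(pedigree$sex)

  self_par <- which(!is.na(father_id) & father_id == id |
                    !is.na(mother_id) & mother_id == id)
  if (length(self_par))
    stop("individual ", id[self_par[1L]], " is recorded as its own parent",
         call. = FALSE)
  same_par <- which(!is.na(father_id) & !is.na(mother_id) &
                    father_id == mother_id)
  if (length(same_par))
    stop("individual ", id[same_par[1L]],
         " has identical father and mother ids", call. = FALSE)

  father <- match(father_id, id)
  mother <- match(mother_id, id)
  dangling <- which((!is.na(father_id) & is.na(father)) |
                    (!is.na(mother_id) & is.na(mother)))
  if (length(dangling))
    stop("parent id of individual ", id[dangling[1L]],
         " does not resolve within the genealogy", call. = FALSE)

  bad_f <- which(!is.na(father) & sex[father] == "female")
  if (length(bad_f))
    stop("individual ", id[father[bad_f[1L]]],
         " is recorded as female but listed as a father", call. = FALSE)
  bad_m <- which(!is.na(mother) & sex[mother] == "male")
  if (length(bad_m))
    stop("individual ", id[mother[bad_m[1L]]],
         " is recorded as male but listed as a mother", call. = FALSE)

  depth <- .generation_depth(father, mother, id)

  ind <- data.frame(id = id, father_id = father_id, mother_id = mother_id,
                    sex = sex, stringsAsFactors = FALSE)
  for (col in .famgif_attr_cols) ind[[col]] <- .blank_attr(col, length(id))

  if (!is.null(attributes)) {
    if (!"id" %in% names(attributes))
      stop("attribute table must have an id column", call. = FALSE)
    aid <- as.character(attributes$id)
    unknown <- setdiff(aid, id)
    if (length(unknown))
      stop("attribute table contains ids absent from the pedigree: ",
           paste(utils::head(unknown, 3L), collapse = ", "), call. = FALSE)
    rows <- match(id, aid)
    for (col in setdiff(names(attributes), "id")) {
      v <- attributes[[col]][rows]
      ind[[col]] <- if (col %in% .famgif_attr_cols) .coerce_attr(col, v) else v
    }
  }

  structure(list(ind = ind, father = father, mother = mother, depth = depth),
            class = "genealogy")
}

.parse_sex <- function(x) {
  if (is.numeric(x)) x <- as.character(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("1", "m", "male")] <- "male"
  out[x %in% c("2", "f", "female")] <- "female"
  bad <- !(x %in% c("1", "2", "0", "m", "f", "male", "female", "unknown",
                    "", NA_character_)) & !is.na(x)
  if (any(bad))
    stop("unrecognised sex code: ", x[bad][1L], call. = FALSE)
  out
}

.blank_attr <- function(col, n) {
  switch(.famgif_attr_types[[col]],
         integer = rep(NA_integer_, n),
         logical = rep(NA, n),
         numeric = rep(NA_real_, n))
}

.coerce_attr <- function(col, v) {
  switch(.famgif_attr_types[[col]],
         integer = as.integer(v),
         logical = .as_flag(v),
         numeric = as.numeric(v))
}

.as_flag <- function(v) {
  if (is.logical(v)) return(v)
  x <- tolower(trimws(as.character(v)))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "t", "yes")] <- TRUE
  out[x %in% c("0", "false", "f", "no")] <- FALSE
  out
}

# Longest parent chain above each individual; detects cycles (an individual
# never becomes resolvable) and names one member of the offending cycle.
.generation_depth <- function(father, mother, id) {
  n <- length(father)
  depth <- rep(NA_integer_, n)
  pending <- rep(TRUE, n)
  repeat {
    fd <- ifelse(is.na(father), -1L, depth[father])
    md <- ifelse(is.na(mother), -1L, depth[mother])
    ready <- pending & !is.na(fd) & !is.na(md)
    if (!any(ready)) break
    depth[ready] <- pmax(fd[ready], md[ready]) + 1L
    pending[ready] <- FALSE
  }
  if (any(pending))
    stop("cycle detected in parent links involving individual ",
         id[which(pending)[1L]], call. = FALSE)
  depth
}

#' Read a genealogy from a pedigree file and an optional attribute file
#'
#' The pedigree file is whitespace-delimited FAM-like text with four columns
#' (id, father, mother, sex), `"0"` meaning a missing parent and sex coded
#' 1 = male, 2 = female, 0 = unknown. The attribute file is a CSV with a
#' header and one row per id.
#'
#' @param ped_file path to the pedigree table.
#' @param attr_file optional path to the attribute CSV.
#' @return A [genealogy] object.
#' @export
read_genealogy <- function(ped_file, attr_file = NULL) {
  ped <- utils::read.table(ped_file, header = FALSE,
                           col.names = c("id", "father", "mother", "sex"),
                           colClasses = "character")
  attrs <- if (!is.null(attr_file))
    utils::read.csv(attr_file, colClasses = c(id = "character"))
  genealogy(ped, attrs)
}

#' Write a genealogy as a pedigree file plus attribute CSV
#'
#' Emits the same dialect [read_genealogy()] consumes, so a written genealogy
#' round-trips to an identical object.
#'
#' @param g a [genealogy].
#' @param ped_file output path for the pedigree table.
#' @param attr_file optional output path for the attribute CSV.
#' @return `g`, invisibly.
#' @export
write_genealogy <- function(g, ped_file, attr_file = NULL) {
  stopifnot(inherits(g, "genealogy"))
  ind <- g$ind
  ped <- data.frame(
    id = ind$id,
    father = ifelse(is.na(ind$father_id), "0", ind$father_id),
    mother = ifelse(is.na(ind$mother_id), "0", ind$mother_id),
    sex = c(male = "1", female = "2", unknown = "0")[ind$sex]
  )
  utils::write.table(ped, ped_file, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(attr_file)) {
    keep <- c("id", names(ind)[!(names(ind) %in%
               c("id", "father_id", "mother_id", "sex")) &
               vapply(ind, function(v) !all(is.na(v)), TRUE)])
    utils::write.csv(ind[, unique(keep), drop = FALSE], attr_file,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(g)
}

#' Founders of a genealogy
#'
#' @param g a [genealogy].
#' @return Character vector of ids with neither parent recorded.
#' @export
founders <- function(g) {
  stopifnot(inherits(g, "genealogy"))
  g$ind$id[is.na(g$father) & is.na(g$mother)]
}

#' Generation depth of every individual
#'
#' Depth is the length of the longest chain of parent links above an
#' individual; founders have depth 0.
#'
#' @param g a [genealogy].
#' @return Named integer vector over all ids.
#' @export
generation_depth <- function(g) {
  stopifnot(inherits(g, "genealogy"))
  stats::setNames(g$depth, g$ind$id)
}

#' @export
print.genealogy <- function(x, ...) {
  n <- nrow(x$ind)
  nf <- sum(is.na(x$father) & is.na(x$mother))
  cat("Genealogy:", n, "individuals,", nf, "founders,",
      max(x$depth) + 1L, "generations\n")
  ncase <- sum(x$ind$is_case, na.rm = TRUE)
  if (ncase > 0) cat("  cases:", ncase, "\n")
  invisible(x)
}

#' @export
summary.genealogy <- function(object, ...) {
  ind <- object$ind
  cat("Genealogy with", nrow(ind), "individuals\n")
  cat("  founders:          ", length(founders(object)), "\n")
  cat("  generation depths: ", paste(range(object$depth), collapse = "-"), "\n")
  if (!all(is.na(ind$birth_year)))
    cat("  birth years:       ",
        paste(range(ind$birth_year, na.rm = TRUE), collapse = "-"), "\n")
  cat("  sex:                male", sum(ind$sex == "male"),
      "/ female", sum(ind$sex == "female"),
      "/ unknown", sum(ind$sex == "unknown"), "\n")
  if (any(!is.na(ind$is_case)))
    cat("  cases:             ", sum(ind$is_case, na.rm = TRUE), "\n")
  invisible(object)
}

.gidx <- function(g, ids, arg = "id") {
  i <- match(as.character(ids), g$ind$id)
  if (anyNA(i))
    stop("unknown ", arg, ": ", as.character(ids)[is.na(i)][1L], call. = FALSE)
  i
}

#' Individuals with complete ancestral genealogy data
#'
#' Registry genealogies are only informative for relatedness analysis when an
#' individual's recent ancestry is actually recorded. This eligibility filter
#' keeps individuals born before a cutoff year whose two parents and four
#' grandparents are all recorded and for whom at least six of the eight
#' great-grandparent slots are filled. Slots are counted positionally through
#' the parent links, so in an inbred genealogy one person occupying two slots
#' counts twice. Individuals with a missing birth year are excluded.
#'
#' @param g a [genealogy].
#' @param birth_cutoff_year exclusive upper bound on birth year (default 1972,
#'   the construction date of the original Utah genealogy).
#' @param min_great_grandparents minimum filled great-grandparent slots
#'   (default 6 of 8).
#' @return Character vector of eligible ids.
#' @export
ancestral_subset <- function(g, birth_cutoff_year = 1972,
                             min_great_grandparents = 6L) {
  stopifnot(inherits(g, "genealogy"))
  ind <- g$ind
  born_ok <- !is.na(ind$birth_year) & ind$birth_year < birth_cutoff_year

  f <- g$father; m <- g$mother
  parents_ok <- !is.na(f) & !is.na(m)

  slot <- function(p) cbind(f[p], m[p])          # parent-of-index, NA-safe
  gp <- cbind(slot(f), slot(m))                  # 4 grandparent slots
  gp_ok <- parents_ok & rowSums(!is.na(gp)) == 4L

  ggp <- cbind(slot(gp[, 1L]), slot(gp[, 2L]), slot(gp[, 3L]), slot(gp[, 4L]))
  ggp_n <- rowSums(!is.na(ggp))

  ind$id[born_ok & parents_ok & gp_ok & ggp_n >= min_great_grandparents]
}

#' Control-pool candidates with complete matching data
#'
#' Convenience filter combining the ancestral-completeness rule with the
#' requirement that every control-matching variable (birth year, sex, birth
#' state) is present. Optionally restricted to one sex, which is the usual
#' pool for a sex-limited phenotype.
#'
#' @param g a [genealogy].
#' @param birth_cutoff_year passed to [ancestral_subset()].
#' @param sex optional `"male"` or `"female"` restriction.
#' @return Character vector of ids.
#' @export
eligible_pool <- function(g, birth_cutoff_year = 1972, sex = NULL) {
  ids <- ancestral_subset(g, birth_cutoff_year)
  idx <- .gidx(g, ids)
  ok <- !is.na(g$ind$birth_year[idx]) & g$ind$sex[idx] != "unknown" &
    !is.na(g$ind$birth_in_state[idx])
  if (!is.null(sex)) ok <- ok & g$ind$sex[idx] == sex
  ids[ok]
}

# Children index list: for each individual, integer indices of its children.
.children_index <- function(g) {
  n <- nrow(g$ind)
  kids <- vector("list", n)
  for (pvec in list(g$father, g$mother)) {
    has <- which(!is.na(pvec))
    if (length(has)) {
      sp <- split(has, pvec[has])
      for (nm in names(sp)) {
        i <- as.integer(nm)
        kids[[i]] <- c(kids[[i]], sp[[nm]])
      }
    }
  }
  kids
}

#' Descendants of an individual
#'
#' Transitive closure of child links starting from (but excluding) the given
#' individual.
#'
#' @param g a [genealogy].
#' @param id individual id.
#' @return Character vector of descendant ids.
#' @export
descendants <- function(g, id) {
  i <- .gidx(g, id)
  kids <- .children_index(g)
  seen <- logical(nrow(g$ind))
  frontier <- kids[[i]]
  while (length(frontier)) {
    frontier <- frontier[!seen[frontier]]
    seen[frontier] <- TRUE
    frontier <- unlist(kids[frontier], use.names = FALSE)
  }
  g$ind$id[seen]
}
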