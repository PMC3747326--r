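# Malecot kinship on arbitrary genealogies.
#
# Two independent routes are provided: a memoized pairwise recursion
# (kinship), and a tabular dynamic program that fills a dense kinship matrix
# in one pass over a topological order (kinship_matrix). The recursion is the
# textbook definition and is used for single pairs and as a cross-check; the
# tabular route is what the resampling machinery uses, because a control
# replicate needs thousands of pairwise coefficients at once.

#' Malecot coefficient of kinship between two individuals
#'
#' The kinship coefficient phi(a, b) is the probability that an allele
#' sampled at random from `a` and one sampled from `b` are identical by
#' descent within the genealogy. Canonical values for outbred relatives:
#' siblings 1/4, avunculars 1/8, first cousins 1/16; a non-inbred individual
#' with itself has phi = 1/2.
#'
#' Computed by the standard recursion: phi(a, a) = (1 + phi(father_a,
#' mother_a)) / 2 with missing-parent terms zero, and for a != b, recursing
#' through the parents of whichever member has the greater generation depth
#' (which is therefore not an ancestor of the other):
#' phi(a, b) = (phi(father_a, b) + phi(mother_a, b)) / 2. Distinct founders
#' have phi = 0. Inbreeding loops are handled exactly.
#'
#' @param g a [genealogy].
#' @param a,b individual ids.
#' @return Kinship coefficient in `[0, 1)`.
#' @examples
#' ped <- data.frame(id = c("f", "m", "s1", "s2"),
#'                   father = c("0", "0", "f", "f"),
#'                   mother = c("0", "0", "m", "m"), sex = c(1, 2, 1, 2))
#' kinship(genealogy(ped), "s1", "s2")  # 0.25
#' @export
kinship <- function(g, a, b) {
  stopifnot(inherits(g, "genealogy"))
  i <- .gidx(g, a); j <- .gidx(g, b)
  memo <- new.env(parent = emptyenv(), hash = TRUE)
  .phi_rec(g, i, j, memo)
}

.phi_rec <- function(g, i, j, memo) {
  if (i > j) { t <- i; i <- j; j <- t }
  key <- paste0(i, ":", j)
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)

  f <- g$father; m <- g$mother
  if (i == j) {
    val <- if (!is.na(f[i]) && !is.na(m[i]))
      0.5 * (1 + .phi_rec(g, f[i], m[i], memo)) else 0.5
  } else {
    # recurse through the deeper member; equal depths exclude ancestry
    d <- if (g$depth[i] >= g$depth[j]) i else j
    o <- if (d == i) j else i
    pf <- f[d]; pm <- m[d]
    val <- 0.5 * ((if (is.na(pf)) 0 else .phi_rec(g, pf, o, memo)) +
                  (if (is.na(pm)) 0 else .phi_rec(g, pm, o, memo)))
  }
  memo[[key]] <- val
  val
}

# Ancestor closure (self included) of a set of indices, as sorted indices.
.ancestor_closure <- function(g, idx) {
  seen <- logical(nrow(g$ind))
  frontier <- unique(idx)
  while (length(frontier)) {
    seen[frontier] <- TRUE
    p <- c(g$father[frontier], g$mother[frontier])
    p <- p[!is.na(p)]
    frontier <- unique(p[!seen[p]])
  }
  which(seen)
}

#' Dense kinship matrix over a set of individuals
#'
#' Fills the kinship matrix by dynamic programming over the ancestor closure
#' of `ids` in topological (generation-depth) order: each individual's row is
#' the mean of its parents' rows, and its self-kinship is
#' (1 + phi(father, mother)) / 2. Agrees exactly with [kinship()]; intended
#' for the many-pairs workloads of the resampling tests.
#'
#' @param g a [genealogy].
#' @param ids ids to return (default all). The computation runs over the full
#'   ancestor closure of `ids`, so the result is exact regardless of subset.
#' @return Symmetric numeric matrix with `ids` as dimnames.
#' @export
kinship_matrix <- function(g, ids = NULL) {
  stopifnot(inherits(g, "genealogy"))
  idx <- if (is.null(ids)) seq_len(nrow(g$ind)) else .gidx(g, ids)
  clo <- .ancestor_closure(g, idx)
  m <- length(clo)
  loc <- match(seq_len(nrow(g$ind)), clo)   # global -> local
  lf <- loc[g$father[clo]]; lm <- loc[g$mother[clo]]
  ord <- order(g$depth[clo])

  K <- matrix(0, m, m)
  for (t in seq_len(m)) {
    i <- ord[t]
    f <- lf[i]; mo <- lm[i]
    if (t > 1L) {
      prev <- ord[seq_len(t - 1L)]
      kf <- if (is.na(f)) 0 else K[f, prev]
      km <- if (is.na(mo)) 0 else K[mo, prev]
      v <- 0.5 * (kf + km)
      K[i, prev] <- v
      K[prev, i] <- v
    }
    K[i, i] <- 0.5 * (1 + if (!is.na(f) && !is.na(mo)) K[f, mo] else 0)
  }
  out <- K[loc[idx], loc[idx], drop = FALSE]
  dimnames(out) <- list(g$ind$id[idx], g$ind$id[idx])
  out
}

# Minimum meiosis count from each closure member up to each of its ancestors.
# Returns a list (indexed like clo) of integer vectors named by global index;
# each vector includes the individual itself at distance 0.
.ancestor_dist_maps <- function(g, clo) {
  loc <- match(seq_len(nrow(g$ind)), clo)
  ord <- order(g$depth[clo])
  maps <- vector("list", length(clo))
  for (i in ord) {
    gi <- clo[i]
    v <- c(stats::setNames(0L, gi))
    for (p in c(g$father[gi], g$mother[gi])) {
      if (!is.na(p)) v <- c(v, maps[[loc[p]]] + 1L)
    }
    if (anyDuplicated(names(v)))
      v <- vapply(split(v, names(v)), min, 0L)
    maps[[i]] <- v
  }
  maps
}

#' Genetic distance between two individuals
#'
#' The minimum number of meioses on a genealogical path connecting `a` and
#' `b` through a common ancestor (a path that ascends from each member to the
#' shared ancestor; either member may itself be that ancestor). Distance 1 is
#' parent/offspring, 2 siblings or grandparent/grandchild, 3 avunculars,
#' 4 first cousins, 5 first cousins once removed, and so forth. Pairs with no
#' common ancestor are unreachable.
#'
#' @param g a [genealogy].
#' @param a,b distinct individual ids.
#' @return Integer meiosis count, or `Inf` when the pair shares no ancestor.
#' @export
genetic_distance <- function(g, a, b) {
  stopifnot(inherits(g, "genealogy"))
  i <- .gidx(g, a); j <- .gidx(g, b)
  if (i == j) stop("genetic distance requires two distinct individuals",
                   call. = FALSE)
  clo <- .ancestor_closure(g, c(i, j))
  maps <- .ancestor_dist_maps(g, clo)
  da <- maps[[match(i, clo)]]; db <- maps[[match(j, clo)]]
  common <- intersect(names(da), names(db))
  if (!length(common)) return(Inf)
  min(da[common] + db[common])
}

#' Kinship and genetic distance for all pairs in a set
#'
#' Computes the Malecot kinship and minimum meiotic distance for every
#' unordered pair within `ids`, stored sparsely: only related pairs (those
#' sharing at least one common ancestor, equivalently phi > 0) appear in the
#' table; all remaining pairs implicitly have phi = 0 and unreachable
#' distance. Candidate related pairs are found by intersecting ancestor sets
#' through an ancestor-to-descendant index, so the cost scales with the
#' number of pairs that actually share ancestry rather than with all n^2
#' pairs.
#'
#' @param g a [genealogy].
#' @param ids character vector of ids (may be empty).
#' @return An object of class `"pair_kinship"`: a data.frame with columns
#'   `id1`, `id2`, `phi`, `distance` (related pairs only), with attributes
#'   `ids` (the full set) and `n_pairs` (all unordered pairs, related or not).
#' @export
kinship_pairs <- function(g, ids) {
  stopifnot(inherits(g, "genealogy"))
  ids <- unique(as.character(ids))
  idx <- if (length(ids)) .gidx(g, ids) else integer()
  n <- length(idx)
  empty <- data.frame(id1 = character(), id2 = character(),
                      phi = numeric(), distance = numeric())
  if (n < 2L)
    return(structure(empty, ids = ids, n_pairs = 0, class =
                     c("pair_kinship", "data.frame")))

  clo <- .ancestor_closure(g, idx)
  maps <- .ancestor_dist_maps(g, clo)
  mem_maps <- maps[match(idx, clo)]

  # ancestor -> which members descend from it, at what distance
  anc_members <- list(); anc_dist <- list()
  for (k in seq_len(n)) {
    mp <- mem_maps[[k]]
    for (h in seq_along(mp)) {
      a <- names(mp)[h]
      anc_members[[a]] <- c(anc_members[[a]], k)
      anc_dist[[a]] <- c(anc_dist[[a]], mp[[h]])
    }
  }

  # candidate pairs share >= 1 ancestor; accumulate min path length per pair
  D <- matrix(Inf, n, n)
  for (a in names(anc_members)) {
    mk <- anc_members[[a]]
    if (length(mk) < 2L) next
    v <- anc_dist[[a]]
    s <- outer(v, v, "+")
    cur <- D[mk, mk]
    w <- s < cur
    cur[w] <- s[w]
    D[mk, mk] <- cur
  }

  pr <- which(upper.tri(D) & is.finite(D), arr.ind = TRUE)
  if (!nrow(pr))
    return(structure(empty, ids = ids, n_pairs = n * (n - 1) / 2,
                     class = c("pair_kinship", "data.frame")))

  memo <- new.env(parent = emptyenv(), hash = TRUE)
  phi <- vapply(seq_len(nrow(pr)), function(r)
    .phi_rec(g, idx[pr[r, 1L]], idx[pr[r, 2L]], memo), 0)

  out <- data.frame(id1 = ids[pr[, 1L]], id2 = ids[pr[, 2L]],
                    phi = phi, distance = D[pr])
  structure(out, ids = ids, n_pairs = n * (n - 1) / 2,
            class = c("pair_kinship", "data.frame"))
}

#' @export
print.pair_kinship <- function(x, ...) {
  cat("Pairwise kinship over", length(attr(x, "ids")), "individuals:",
      nrow(x), "related pairs of", format(attr(x, "n_pairs")), "\n")
  if (nrow(x)) {
    cat("  mean phi over all pairs:",
        format(sum(x$phi) / attr(x, "n_pairs"), digits = 4), "\n")
    NextMethod()
  }
  invisible(x)
}

# Pairwise genetic-distance matrix for a member set, given precomputed
# ancestor-distance maps (list aligned with members). Inf = unreachable.
.pair_distance_matrix <- function(mem_maps) {
  n <- length(mem_maps)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  anc_members <- list(); anc_dist <- list()
  for (k in seq_len(n)) {
    mp <- mem_maps[[k]]
    nm <- names(mp)
    for (h in seq_along(mp)) {
      a <- nm[h]
      anc_members[[a]] <- c(anc_members[[a]], k)
      anc_dist[[a]] <- c(anc_dist[[a]], mp[[h]])
    }
  }
  for (a in names(anc_members)) {
    mk <- anc_members[[a]]
    if (length(mk) < 2L) next
    v <- anc_dist[[a]]
    s <- outer(v, v, "+")
    cur <- D[mk, mk]
    w <- s < cur
    cur[w] <- s[w]
    D[mk, mk] <- cur
  }
  D
}
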