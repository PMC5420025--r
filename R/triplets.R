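# Rooted triplets are stored as canonical strings "a,b|c" (cherry pair sorted,
# then the outgroup); a triplet system is a sorted unique character vector of
# class "l1_triplets" with a `taxa` attribute.

#' Make a canonical triplet string ab|c
#'
#' @param a,b the cherry pair (the two taxa whose last common ancestor is
#'   below the root of the triplet).
#' @param c the outgroup taxon.
#' @return character scalar `"a,b|c"` with the cherry pair sorted.
#' @export
triplet <- function(a, b, c) {
  stopifnot(length(unique(c(a, b, c))) == 3L)
  paste0(min(a, b), ",", max(a, b), "|", c)
}

parse_triplet <- function(t) {
  parts <- strsplit(t, "|", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) stop("malformed triplet: ", t)
  cherry <- strsplit(parts[[1L]], ",", fixed = TRUE)[[1L]]
  if (length(cherry) != 2L) stop("malformed triplet: ", t)
  c(cherry, parts[[2L]])
}

as_triplet_system <- function(x, taxa) {
  structure(sort(unique(x)), taxa = sort(taxa), class = "l1_triplets")
}

#' @export
print.l1_triplets <- function(x, ...) {
  cat(sprintf("<triplet system> %d triplets on %d taxa\n",
              length(x), length(attr(x, "taxa"))))
  if (length(x)) cat(" ", paste(unclass(x), collapse = "  "), "\n")
  invisible(x)
}

#' All possible triplet strings on a taxon set
#'
#' Enumerates the `3 * choose(n, 3)` triplets on `taxa`, in a fixed order
#' (used as the index dictionary for set operations on triplet systems).
#'
#' @param taxa character vector of taxon names.
#' @return character vector of canonical triplet strings.
#' @export
all_triplets <- function(taxa) {
  taxa <- sort(taxa)
  if (length(taxa) < 3L) return(character())
  trios <- combn(taxa, 3L)
  out <- character(0L)
  for (i in seq_len(ncol(trios))) {
    y <- trios[, i]
    out <- c(out, triplet(y[1L], y[2L], y[3L]), triplet(y[1L], y[3L], y[2L]),
             triplet(y[2L], y[3L], y[1L]))
  }
  out
}

#' Triplet system induced by a tree
#'
#' Every 3-subset of the taxa of a binary tree carries exactly one triplet, so
#' the result has `choose(n, 3)` elements.
#'
#' @param T an `l1net` tree (level-0 network) on at least 3 taxa.
#' @return an `l1_triplets` system.
#' @export
tree_triplets <- function(T) {
  if (length(hybrid_vertices(T)) > 0L) {
    stop("tree_triplets() expects a tree (level-0 network)")
  }
  X <- taxa(T)
  if (length(X) < 3L) stop("tree_triplets() needs at least 3 taxa")
  out <- character()
  for (v in setdiff(vertices(T), names(T$leaves))) {
    kids <- out_children(T, v)
    b1 <- cluster_below(T, kids[[1L]])
    b2 <- cluster_below(T, kids[[2L]])
    outside <- setdiff(X, c(b1, b2))
    if (length(outside) == 0L) next
    for (a in b1) for (b in b2) for (cc in outside) {
      out <- c(out, triplet(a, b, cc))
    }
  }
  as_triplet_system(out, X)
}

# ---- path-based consistency -------------------------------------------------

# Per-network cache for path enumeration: reachability matrix plus memoised
# lists of all directed paths between vertex pairs (few per pair in a level-1
# network: at most 2 per gall traversed).
paths_cache <- function(N) {
  g <- arcs_igraph(N$arcs)
  reach <- is.finite(igraph::distances(g, mode = "out"))
  adj <- adjacency(N)
  memo <- new.env(parent = emptyenv())
  vn <- rownames(reach)
  list(reach = reach, vn = vn, adj = adj, memo = memo)
}

paths_between <- function(cache, from, to) {
  key <- paste0(from, "\r", to)
  hit <- cache$memo[[key]]
  if (!is.null(hit)) return(hit)
  res <- if (from == to) {
    list(to)
  } else {
    nexts <- get(from, envir = cache$adj)
    nexts <- nexts[cache$reach[match(nexts, cache$vn), match(to, cache$vn)]]
    unlist(lapply(nexts, function(u) {
      lapply(paths_between(cache, u, to), function(p) c(from, p))
    }), recursive = FALSE)
  }
  cache$memo[[key]] <- res
  res
}

#' Is a triplet consistent with a network?
#'
#' The triplet ab|c is consistent with N when there are distinct vertices v, w
#' and directed paths v->c, v->w, w->a and w->b that pairwise share no vertex
#' other than the common endpoints v and w, i.e. when N contains a subdivision
#' of the triplet.
#'
#' @param N an `l1net` network.
#' @param t a triplet string (see [triplet()]) or a character vector
#'   `c(a, b, c)` meaning ab|c.
#' @return logical.
#' @export
is_consistent <- function(N, t) {
  if (length(t) == 1L) t <- parse_triplet(t)
  if (!all(t %in% taxa(N))) stop("triplet taxa must be taxa of the network")
  consistent_abc(N, t[[1L]], t[[2L]], t[[3L]], paths_cache(N))
}

consistent_abc <- function(N, a, b, c, cache) {
  lv <- names(N$leaves)
  va <- lv[N$leaves == a]; vb <- lv[N$leaves == b]; vc <- lv[N$leaves == c]
  reach <- cache$reach
  vn <- cache$vn
  ia <- match(va, vn); ib <- match(vb, vn); ic <- match(vc, vn)
  cand_w <- vn[reach[, ia] & reach[, ib]]
  for (w in cand_w) {
    iw <- match(w, vn)
    p3s <- paths_between(cache, w, va)
    p4s <- paths_between(cache, w, vb)
    cand_v <- vn[reach[, ic] & reach[, iw]]
    cand_v <- setdiff(cand_v, w)
    for (v in cand_v) {
      p1s <- paths_between(cache, v, vc)
      p2s <- paths_between(cache, v, w)
      for (p3 in p3s) for (p4 in p4s) {
        if (any(p3[-1L] %in% p4[-1L])) next
        for (p2 in p2s) {
          mid2 <- setdiff(p2, w)
          if (any(mid2 %in% p3) || any(mid2 %in% p4)) next
          if (w %in% mid2) next
          for (p1 in p1s) {
            mid1 <- setdiff(p1, v)
            if (any(mid1 %in% p2)) next
            if (any(p1 %in% p3) || any(p1 %in% p4)) next
            return(TRUE)
          }
        }
      }
    }
  }
  FALSE
}

#' Triplet system induced by a network
#'
#' Two independent algorithms are provided: `"trees"` takes the union of the
#' triplet systems of all displayed trees, `"paths"` tests every candidate
#' triplet for consistency via internally disjoint path systems.  For binary
#' level-1 networks the two agree; the tests cross-check them.
#'
#' @param N an `l1net` network on at least 3 taxa.
#' @param method `"trees"` (default, faster) or `"paths"`.
#' @return an `l1_triplets` system.
#' @export
triplet_system <- function(N, method = c("trees", "paths")) {
  method <- match.arg(method)
  X <- taxa(N)
  if (length(X) < 3L) stop("triplet_system() needs at least 3 taxa")
  if (method == "trees") {
    out <- unlist(lapply(displayed_trees(N), tree_triplets))
    return(as_triplet_system(out, X))
  }
  cache <- paths_cache(N)
  cand <- all_triplets(X)
  keep <- vapply(cand, function(t) {
    p <- parse_triplet(t)
    consistent_abc(N, p[[1L]], p[[2L]], p[[3L]], cache)
  }, logical(1))
  as_triplet_system(cand[keep], X)
}

# ---- SN-sets ----------------------------------------------------------------

#' SN-sets of a triplet system
#'
#' A subset S of the taxa is an SN-set of R when no triplet xy|z in R has
#' x, z in S and y outside S.  Enumeration is by exhaustive subset test and is
#' guarded to at most 12 taxa.
#'
#' @param R an `l1_triplets` system (or character vector of triplet strings).
#' @param taxa the taxon set; defaults to the system's `taxa` attribute.
#' @param nontrivial_only drop the full set itself.
#' @return list of sorted taxon vectors (all SN-sets, including singletons).
#' @export
sn_sets <- function(R, taxa = attr(R, "taxa"), nontrivial_only = FALSE) {
  if (is.null(taxa)) stop("supply `taxa` when R carries no taxa attribute")
  taxa <- sort(taxa)
  n <- length(taxa)
  if (n > 12L) stop("SN-set enumeration is exponential; guarded to n <= 12")
  trips <- lapply(unclass(R), parse_triplet)
  av <- vapply(trips, `[`, character(1), 1L)
  bv <- vapply(trips, `[`, character(1), 2L)
  cv <- vapply(trips, `[`, character(1), 3L)
  out <- list()
  for (code in seq_len(2L^n - 1L)) {
    inS <- as.logical(bitwAnd(code, 2L^(seq_len(n) - 1L)))
    S <- taxa[inS]
    if (nontrivial_only && length(S) == n) next
    aIn <- av %in% S; bIn <- bv %in% S; cIn <- cv %in% S
    violated <- any((aIn & cIn & !bIn) | (bIn & cIn & !aIn))
    if (!violated) out[[length(out) + 1L]] <- S
  }
  out
}

#' Maximal non-trivial SN-sets
#'
#' The inclusion-maximal SN-sets strictly contained in the taxon set.  When R
#' is the triplet system induced by a level-1 network these partition the taxa
#' and equal the network's Cut partition; when they fail to partition the taxa
#' (a sign that R is not induced by a level-1 network) the sets are still
#' returned, with a warning and `is_partition = FALSE`.
#'
#' @inheritParams sn_sets
#' @return list of sorted taxon vectors with attribute `is_partition`; when
#'   they do partition the taxa the result is also of class `l1_partition`.
#' @export
maximal_sn_sets <- function(R, taxa = attr(R, "taxa")) {
  if (is.null(taxa)) stop("supply `taxa` when R carries no taxa attribute")
  if (length(taxa) < 3L) stop("maximal_sn_sets() needs at least 3 taxa")
  sets <- sn_sets(R, taxa, nontrivial_only = TRUE)
  keep <- vapply(seq_along(sets), function(i) {
    !any(vapply(seq_along(sets), function(j) {
      i != j && length(sets[[i]]) < length(sets[[j]]) &&
        all(sets[[i]] %in% sets[[j]])
    }, logical(1)))
  }, logical(1))
  maxsets <- sets[keep]
  members <- unlist(maxsets)
  is_part <- setequal(members, taxa) && !anyDuplicated(members)
  if (!is_part) {
    warning("maximal non-trivial SN-sets do not partition the taxa; ",
            "the system is not induced by a level-1 network")
    return(structure(maxsets, is_partition = FALSE))
  }
  structure(as_partition(maxsets), is_partition = TRUE)
}

# ---- defining triplet systems ----------------------------------------------

# Cycle labelling of a simple network: leaves x_1..x_n and the root position i
# along the cycle v_1 = hybrid, v_2, ..., v_i = root, ..., v_{n+1}.  x_1 is the
# hybrid leaf; x_2..x_{i-1} sit on the "up" side read bottom to top; x_i..x_n
# on the other side read top to bottom.  The orientation puts the side with
# more leaves first (so i - 2 >= n - i + 1); ties pick the lexicographically
# smaller bottom-to-top leaf sequence.
simple_labeling <- function(N) {
  if (!classify_network(N)$is_simple) stop("network is not simple")
  g <- galls(N)[[1L]]
  leaf_of <- function(u) unname(N$leaves[[off_cycle_child(N, u, g$cycle)]])
  la <- vapply(g$side1, leaf_of, character(1))  # top -> bottom
  lb <- vapply(g$side2, leaf_of, character(1))
  swap <- if (length(la) != length(lb)) {
    length(la) < length(lb)
  } else {
    paste(rev(lb), collapse = "\r") < paste(rev(la), collapse = "\r")
  }
  if (swap) { tmp <- la; la <- lb; lb <- tmp }
  x <- c(unname(N$leaves[[out_children(N, g$hybrid)]]), rev(la), lb)
  list(x = x, i = length(la) + 2L, n = length(x))
}

#' A small triplet system that defines a simple network
#'
#' Recursive construction of a triplet system of size at most 2n - 1 that
#' uniquely determines a simple network among all binary level-1 networks on
#' the same taxa: the base case n = 4 returns the full induced system (7
#' triplets); each step removes the cycle leaf next to the hybrid-adjacent end
#' of the shorter side, recurses, and adds two triplets that pin down the
#' removed leaf's position.
#'
#' @param N a simple `l1net` network on at least 4 taxa.
#' @return an `l1_triplets` system, a subset of `triplet_system(N)` of size at
#'   most `2 * length(taxa(N)) - 1`.
#' @export
defining_triplets_simple <- function(N) {
  if (!classify_network(N)$is_simple) stop("network is not simple")
  X <- taxa(N)
  n <- length(X)
  if (n < 4L) stop("the construction needs at least 4 taxa")
  if (n == 4L) return(triplet_system(N))
  lab <- simple_labeling(N)
  x <- lab$x
  x1 <- x[[1L]]; xn <- x[[lab$n]]; xn1 <- x[[lab$n - 1L]]
  pair <- if (lab$i == lab$n + 1L) {
    c(triplet(xn1, xn, x1), triplet(x1, xn1, xn))
  } else if (lab$i == lab$n) {
    c(triplet(xn, x1, xn1), triplet(x1, xn1, xn))
  } else {
    c(triplet(xn1, xn, x1), triplet(xn, x1, xn1))
  }
  sub <- defining_triplets_simple(restrict_network(N, setdiff(X, xn)))
  as_triplet_system(c(unclass(sub), pair), X)
}

#' Is a network uniquely determined by a triplet system?
#'
#' N is defined by R within the supplied universe when every universe member
#' whose induced triplet system contains R is equivalent to N.  The universe
#' should be exhaustive for the taxon set (see [enumerate_level1()]) for the
#' answer to be meaningful for the full class of level-1 networks.
#'
#' @param N an `l1net` network.
#' @param R a triplet system with `R` a subset of `triplet_system(N)`.
#' @param universe an `l1_universe` on `taxa(N)`.
#' @return list with `defined` (logical), `witnesses` (extended Newick strings
#'   of non-equivalent members also displaying R) and `n_checked`.
#' @export
is_l1_defined_by_triplets <- function(N, R, universe) {
  RN <- triplet_system(N)
  if (!all(R %in% RN)) stop("R is not a subset of the network's triplet system")
  systems <- universe_systems(universe, "triplets")
  me <- canonical_form(N)
  hit <- vapply(systems, function(s) all(R %in% s), logical(1))
  wit <- which(hit & universe$enc != me)
  list(defined = length(wit) == 0L,
       witnesses = vapply(universe$networks[wit], write_enewick, character(1)),
       n_checked = length(systems))
}

#' Smallest defining triplet subset (breadth-first search)
#'
#' Searches subsets of `triplet_system(N)` in order of increasing size for one
#' that defines N within the universe.  Exponential; guarded to at most 5
#' taxa.
#'
#' @inheritParams is_l1_defined_by_triplets
#' @param size_cap largest subset size to try (default: the full system size).
#' @return list with `found`, `size` (NA when not found within the cap) and
#'   `subset` (character vector of triplets).
#' @export
min_defining_triplets <- function(N, universe, size_cap = NULL) {
  X <- taxa(N)
  if (length(X) > 5L) stop("subset search is exponential; guarded to n <= 5")
  R <- unclass(triplet_system(N))
  if (is.null(size_cap)) size_cap <- length(R)
  systems <- universe_systems(universe, "triplets")
  me <- canonical_form(N)
  others <- universe$enc != me
  other_systems <- systems[others]
  for (k in 0:size_cap) {
    subs <- if (k == 0L) list(character()) else {
      asplit(combn(R, k), 2L)
    }
    for (S in subs) {
      ok <- !any(vapply(other_systems, function(s) all(S %in% s), logical(1)))
      if (ok) return(list(found = TRUE, size = k, subset = as.character(S)))
    }
  }
  list(found = FALSE, size = NA_integer_, subset = character())
}

#' Triplet system of a collapsed network, by projection
#'
#' Projects the triplets of N onto the blocks of its Cut partition: a triplet
#' survives when its three taxa lie in three distinct blocks, and is rewritten
#' on the block representatives.  Equals the induced triplet system of
#' `collapse_network(N)$network`.
#'
#' @param N an `l1net` network whose Cut partition has at least 3 blocks.
#' @return an `l1_triplets` system on the block representatives.
#' @export
collapsed_triplet_system <- function(N) {
  part <- cut_partition(N)
  if (length(part) < 3L) {
    stop("the Cut partition has fewer than 3 blocks; the collapsed network is a 2-leaf tree and induces no triplets")
  }
  reps <- vapply(part, min, character(1))
  block_of <- setNames(rep(reps, lengths(part)), unlist(part))
  out <- character()
  for (t in unclass(triplet_system(N))) {
    p <- parse_triplet(t)
    r <- block_of[p]
    if (length(unique(r)) == 3L) out <- c(out, triplet(r[[1L]], r[[2L]], r[[3L]]))
  }
  as_triplet_system(out, reps)
}
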