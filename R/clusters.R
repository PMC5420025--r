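# Clusters are stored as canonical strings "a,b,c" (taxa sorted, comma
# joined); a cluster system is a sorted unique character vector of class
# "l1_clusters" with a `taxa` attribute.

cluster_str <- function(members) paste(sort(members), collapse = ",")

parse_cluster <- function(s) strsplit(s, ",", fixed = TRUE)[[1L]]

as_cluster_system <- function(x, taxa) {
  structure(sort(unique(x)), taxa = sort(taxa), class = "l1_clusters")
}

#' @export
print.l1_clusters <- function(x, ...) {
  cat(sprintf("<cluster system> %d clusters on %d taxa\n",
              length(x), length(attr(x, "taxa"))))
  if (length(x)) {
    cat(" ", paste0("{", unclass(x), "}", collapse = " "), "\n")
  }
  invisible(x)
}

#' Hardwired cluster system of a network
#'
#' The clusters below each vertex: `{C(v) : v in V(N)}`.  Always contains the
#' full taxon set and every singleton; a binary tree on n leaves has exactly
#' 2n - 1 hardwired clusters.
#'
#' @param N an `l1net` network.
#' @return an `l1_clusters` system.
#' @export
hardwired_clusters <- function(N) {
  as_cluster_system(
    vapply(vertices(N), function(v) cluster_str(cluster_below(N, v)),
           character(1)),
    taxa(N)
  )
}

#' Softwired cluster system of a network
#'
#' The union of the hardwired cluster systems of all displayed trees.
#' Excluding the full taxon set, its size is exactly `3n - 4 - c_N` where
#' `c_N` is the number of non-trivial cut arcs.
#'
#' @param N an `l1net` network.
#' @param drop_full drop the full taxon set (the system written S(N)^- ).
#' @return an `l1_clusters` system.
#' @export
softwired_clusters <- function(N, drop_full = FALSE) {
  out <- unlist(lapply(displayed_trees(N), function(T) unclass(hardwired_clusters(T))))
  if (drop_full) out <- setdiff(out, cluster_str(taxa(N)))
  as_cluster_system(out, taxa(N))
}

#' Compatibility of clusters
#'
#' Two clusters are compatible when their intersection is empty or one of the
#' two; a system is compatible when all pairs are.
#'
#' @param A,B clusters, as taxon vectors or canonical strings.
#' @return logical.
#' @export
clusters_compatible <- function(A, B) {
  if (length(A) == 1L && grepl(",", A, fixed = TRUE)) A <- parse_cluster(A)
  if (length(B) == 1L && grepl(",", B, fixed = TRUE)) B <- parse_cluster(B)
  i <- intersect(A, B)
  length(i) == 0L || setequal(i, A) || setequal(i, B)
}

#' @rdname clusters_compatible
#' @param S a cluster system.
#' @export
is_compatible_system <- function(S) {
  sets <- lapply(unclass(S), parse_cluster)
  if (length(sets) < 2L) return(TRUE)
  for (i in seq_len(length(sets) - 1L)) {
    for (j in (i + 1L):length(sets)) {
      if (!clusters_compatible(sets[[i]], sets[[j]])) return(FALSE)
    }
  }
  TRUE
}

#' Does a network display a cluster system?
#'
#' In the softwired sense: every cluster of S is a softwired cluster of N.
#'
#' @param N an `l1net` network.
#' @param S an `l1_clusters` system (or character vector of cluster strings).
#' @return logical.
#' @export
displays_clusters <- function(N, S) {
  all(unclass(S) %in% unclass(softwired_clusters(N)))
}

#' Restriction of a cluster system to a taxon subset
#'
#' Drops the removed taxa from every cluster, discards emptied clusters and
#' deduplicates.
#'
#' @param S an `l1_clusters` system.
#' @param keep taxa to retain.
#' @return an `l1_clusters` system on `keep`.
#' @export
restrict_cluster_system <- function(S, keep) {
  out <- vapply(unclass(S), function(s) {
    cluster_str(intersect(parse_cluster(s), keep))
  }, character(1))
  as_cluster_system(out[out != ""], keep)
}

#' A small cluster system that defines a simple network
#'
#' Emits at most n softwired clusters that uniquely determine a simple
#' network among all binary level-1 networks on the same taxa.  With the cycle
#' labelled x_1 (hybrid leaf), x_2, ..., x_n and the root at cycle position i
#' (orientation chosen so the first side carries at least as many leaves as
#' the second), the construction emits, depending on whether the root is
#' adjacent to the hybrid (i = n + 1), one step away (i = n), or further:
#' nested chains of cycle clusters plus two or three small clusters anchoring
#' the hybrid leaf.
#'
#' @param N a simple `l1net` network on at least 4 taxa.
#' @return an `l1_clusters` system, a subset of `softwired_clusters(N)` of
#'   size at most `length(taxa(N))`.
#' @export
defining_clusters_simple <- function(N) {
  if (!classify_network(N)$is_simple) stop("network is not simple")
  n <- length(N$leaves)
  if (n < 4L) stop("the construction needs at least 4 taxa")
  lab <- simple_labeling(N)
  x <- lab$x
  i <- lab$i
  out <- if (i == n + 1L) {
    c(vapply(2:(n - 1L), function(j) cluster_str(x[1:j]), character(1)),
      cluster_str(x[2:n]))
  } else if (i == n) {
    c(vapply(3:(n - 1L), function(j) cluster_str(x[2:j]), character(1)),
      cluster_str(x[c(1L, 2L)]), cluster_str(x[c(1L, n)]),
      cluster_str(x[1:3]))
  } else {
    c(if (i >= 4L) vapply(3:(i - 1L), function(j) cluster_str(x[2:j]), character(1)),
      vapply(i:(n - 1L), function(j) cluster_str(x[j:n]), character(1)),
      cluster_str(x[c(1L, 2L)]), cluster_str(x[c(1L, n)]),
      cluster_str(x[c(1L, n, n - 1L)]))
  }
  as_cluster_system(out, taxa(N))
}

#' Is a network uniquely determined by a cluster system?
#'
#' N is defined by S within the universe when every universe member that
#' displays S (in the softwired sense) is equivalent to N.
#'
#' @param N an `l1net` network.
#' @param S a cluster system with `S` a subset of `softwired_clusters(N)`.
#' @param universe an `l1_universe` on `taxa(N)`.
#' @return list with `defined`, `witnesses` (extended Newick of non-equivalent
#'   members displaying S) and `n_checked`.
#' @export
is_l1_defined_by_clusters <- function(N, S, universe) {
  SN <- softwired_clusters(N)
  if (!all(S %in% SN)) stop("S is not a subset of the network's softwired clusters")
  systems <- universe_systems(universe, "clusters")
  me <- canonical_form(N)
  hit <- vapply(systems, function(s) all(S %in% s), logical(1))
  wit <- which(hit & universe$enc != me)
  list(defined = length(wit) == 0L,
       witnesses = vapply(universe$networks[wit], write_enewick, character(1)),
       n_checked = length(systems))
}

#' Search a universe for networks with a given softwired system
#'
#' Utility for locating every level-1 network (in an exhaustive universe)
#' whose softwired cluster system exactly equals `S`.
#'
#' @param S an `l1_clusters` system.
#' @param universe an `l1_universe`.
#' @return list of matching `l1net` networks (possibly empty).
#' @export
find_networks_with_softwired <- function(S, universe) {
  want <- sort(unique(unclass(S)))
  systems <- universe_systems(universe, "clusters")
  hit <- vapply(systems, function(s) identical(sort(unclass(s)), want), logical(1))
  universe$networks[hit]
}
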