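#' l1net: combinatorics of binary level-1 phylogenetic networks
#'
#' A binary level-1 network is a rooted directed acyclic graph whose sinks are
#' labelled by taxa, whose interior vertices are split vertices (in-degree 1,
#' out-degree 2) or hybrid vertices (in-degree 2, out-degree 1), and in which
#' every biconnected component of the underlying undirected graph contains at
#' most one hybrid vertex.  The package provides the structural queries on such
#' networks (galls, cut arcs, restriction, collapse, displayed trees), the
#' rooted-triplet and softwired-cluster systems they induce, and exhaustive
#' small-n enumeration used to verify uniqueness results computationally.
#'
#' @keywords internal
"_PACKAGE"

#' @importFrom utils combn head tail
#' @importFrom stats setNames
NULL

# Characters reserved by the canonical encoding; taxa and vertex ids must
# avoid them so that encodings of distinct networks cannot collide.
.reserved_chars <- "[<>()\\[\\]|,;]"

#' Construct and validate a binary level-1 network
#'
#' Builds a network from an arc list and a leaf labelling and checks every
#' structural invariant: single root of out-degree 2, split/hybrid/leaf degree
#' constraints, acyclicity, at most one hybrid vertex per biconnected
#' component (level-1), and no underlying cycle on fewer than 4 vertices.
#'
#' @param arcs a two-column character matrix (or coercible data frame / list of
#'   length-2 vectors) of arcs as (tail, head) pairs.
#' @param leaf_labels named character vector mapping sink vertex identifiers to
#'   taxon names.  If omitted, sinks are labelled by their own identifier.
#' @param validate if `FALSE`, skip invariant checking (used internally by
#'   generators whose output is valid by construction).
#' @return an object of class `l1net` with fields `arcs`, `root` and `leaves`.
#' @seealso [validate_network()] for the list of violations without an error,
#'   [network_counts()], [classify_network()].
#' @examples
#' # the unique shape of a proper level-1 network on 3 leaves with both gall
#' # sides non-empty: a 4-cycle with hybrid leaf x3
#' N <- build_network(
#'   rbind(
#'     c("r", "a"), c("r", "b"), c("a", "h"), c("b", "h"),
#'     c("a", "x1"), c("b", "x2"), c("h", "x3")
#'   ),
#'   c(x1 = "x1", x2 = "x2", x3 = "x3")
#' )
#' network_counts(N)
#' @export
build_network <- function(arcs, leaf_labels = NULL, validate = TRUE) {
  arcs <- as_arc_matrix(arcs)
  if (is.null(leaf_labels)) {
    sinks <- setdiff(c(arcs), arcs[, 1L])
    leaf_labels <- setNames(sinks, sinks)
  }
  leaf_labels <- unlist(leaf_labels)
  if (is.null(names(leaf_labels)) || any(names(leaf_labels) == "")) {
    stop("`leaf_labels` must be a named vector (vertex id -> taxon)")
  }
  net <- structure(
    list(arcs = arcs, root = root_of(arcs, names(leaf_labels)),
         leaves = leaf_labels),
    class = "l1net"
  )
  if (validate) {
    problems <- validate_network(arcs, leaf_labels)
    if (length(problems)) {
      stop("not a valid binary level-1 network:\n",
           paste0("  - ", problems, collapse = "\n"))
    }
  }
  net
}

# Degenerate one-leaf network (no root in the strict sense); produced by
# restriction to a single taxon and used as a building block by generators.
leaf_network <- function(taxon, vertex = taxon) {
  structure(
    list(arcs = matrix(character(), ncol = 2L), root = vertex,
         leaves = setNames(taxon, vertex)),
    class = "l1net"
  )
}

as_arc_matrix <- function(arcs) {
  if (is.data.frame(arcs)) arcs <- as.matrix(arcs)
  if (is.list(arcs)) arcs <- do.call(rbind, arcs)
  if (!is.matrix(arcs)) stop("`arcs` must be a two-column matrix")
  if (ncol(arcs) != 2L) stop("`arcs` must have exactly two columns")
  storage.mode(arcs) <- "character"
  dimnames(arcs) <- NULL
  arcs
}

root_of <- function(arcs, leaf_vertices) {
  verts <- unique(c(arcs, leaf_vertices))
  cand <- setdiff(verts, arcs[, 2L])
  if (length(cand) == 1L) cand else NA_character_
}

#' List every violated network invariant
#'
#' @inheritParams build_network
#' @return character vector of human-readable violations; empty when the input
#'   is a valid binary level-1 network.
#' @export
validate_network <- function(arcs, leaf_labels) {
  arcs <- as_arc_matrix(arcs)
  leaf_labels <- unlist(leaf_labels)
  problems <- character()
  note <- function(msg) problems <<- c(problems, msg)

  if (nrow(arcs) == 0L) {
    if (length(leaf_labels) != 1L) note("no arcs and not a single labelled leaf")
    return(problems)
  }
  if (anyNA(arcs) || any(arcs == "")) note("arcs contain missing vertex ids")
  if (any(arcs[, 1L] == arcs[, 2L])) note("loop arcs are not allowed")
  if (anyDuplicated(paste(arcs[, 1L], arcs[, 2L]))) {
    note("parallel arcs are not allowed")
  }
  verts <- unique(c(arcs))
  if (any(grepl(.reserved_chars, c(verts, leaf_labels)))) {
    note("vertex ids and taxa must not contain the characters <>()[]|,;")
  }

  outdeg <- table(factor(arcs[, 1L], levels = verts))
  indeg <- table(factor(arcs[, 2L], levels = verts))
  sinks <- verts[outdeg == 0L]
  sources <- verts[indeg == 0L]

  lv <- names(leaf_labels)
  if (!setequal(lv, sinks)) {
    note(sprintf("leaf labels must cover exactly the sinks (sinks: %s; labelled: %s)",
                 paste(sort(sinks), collapse = ","),
                 paste(sort(lv), collapse = ",")))
  }
  if (anyDuplicated(leaf_labels)) note("taxon names must be distinct")

  if (length(sources) != 1L) {
    note(sprintf("expected exactly one root (in-degree 0), found %d: %s",
                 length(sources), paste(sort(sources), collapse = ",")))
  } else {
    if (outdeg[[sources]] != 2L) {
      note(sprintf("root %s must have out-degree 2, has %d",
                   sources, outdeg[[sources]]))
    }
  }

  for (v in verts) {
    din <- indeg[[v]]
    dout <- outdeg[[v]]
    if (din == 0L) next                       # root, checked above
    ok <- (din == 1L && dout == 0L) ||        # leaf
      (din == 1L && dout == 2L) ||            # split vertex
      (din == 2L && dout == 1L)               # hybrid vertex
    if (!ok) {
      note(sprintf("vertex %s has in-degree %d / out-degree %d (not a leaf, split or hybrid vertex)",
                   v, din, dout))
    }
    if (din == 1L && dout == 0L && !(v %in% lv)) {
      note(sprintf("sink %s carries no taxon label", v))
    }
  }

  g <- arcs_igraph(arcs)
  if (!igraph::is_dag(g)) note("the arc set contains a directed cycle")
  if (igraph::components(igraph::as_undirected(g))$no != 1L) {
    note("the underlying graph is disconnected")
  }

  hybrids <- verts[indeg == 2L]
  for (comp in nontrivial_bicomponents(arcs)) {
    nh <- sum(hybrids %in% comp)
    if (nh > 1L) {
      note(sprintf("biconnected component {%s} contains %d hybrid vertices (level-1 allows one)",
                   paste(sort(comp), collapse = ","), nh))
    }
    if (length(comp) < 4L) {
      note(sprintf("underlying cycle {%s} has fewer than 4 vertices",
                   paste(sort(comp), collapse = ",")))
    }
    within <- sum(arcs[, 1L] %in% comp & arcs[, 2L] %in% comp)
    if (within != length(comp)) {
      note(sprintf("biconnected component {%s} is not a simple cycle",
                   paste(sort(comp), collapse = ",")))
    }
  }
  problems
}

arcs_igraph <- function(arcs, vertices = NULL) {
  if (is.null(vertices)) vertices <- unique(c(arcs))
  igraph::graph_from_data_frame(
    data.frame(from = arcs[, 1L], to = arcs[, 2L]),
    directed = TRUE,
    vertices = data.frame(name = vertices)
  )
}

# Vertex-name sets of the non-trivial (>1 edge) biconnected components of the
# underlying undirected graph.
nontrivial_bicomponents <- function(arcs) {
  if (nrow(arcs) == 0L) return(list())
  # fast path: a rooted DAG without repeated arc heads has no undirected cycle
  if (!anyDuplicated(arcs[, 2L])) return(list())
  u <- igraph::as_undirected(arcs_igraph(arcs), mode = "each")
  bc <- igraph::biconnected_components(u)
  comps <- lapply(bc$components, function(vs) igraph::V(u)$name[as.integer(vs)])
  sizes <- vapply(bc$component_edges, length, integer(1))
  comps[sizes > 1L]
}

#' @export
print.l1net <- function(x, ...) {
  if (is_degenerate(x)) {
    cat("<l1net> degenerate network: single leaf", unname(x$leaves), "\n")
    return(invisible(x))
  }
  cnt <- network_counts(x)
  cat(sprintf(
    "<l1net> binary level-1 network on %d taxa: %d vertices, %d arcs, %d gall(s), %d non-trivial cut arc(s)\n",
    cnt$n, cnt$n_vertices, cnt$n_arcs, cnt$n_galls, cnt$c_n))
  cat("  taxa:", paste(taxa(x), collapse = ", "), "\n")
  cat(" ", write_enewick(x), "\n")
  invisible(x)
}

#' Taxa (leaf labels) of a network
#' @param N an `l1net` network.
#' @return sorted character vector of taxon names.
#' @export
taxa <- function(N) sort(unname(N$leaves))

vertices <- function(N) unique(c(c(N$arcs), names(N$leaves), N$root))

is_degenerate <- function(N) nrow(N$arcs) == 0L

hybrid_vertices <- function(N) {
  if (is_degenerate(N)) return(character())
  ind <- table(N$arcs[, 2L])
  names(ind)[ind == 2L]
}

out_children <- function(N, v) N$arcs[N$arcs[, 1L] == v, 2L]
in_parents <- function(N, v) N$arcs[N$arcs[, 2L] == v, 1L]

# adjacency list tail -> heads, as an environment for O(1) lookup
adjacency <- function(N) {
  adj <- new.env(parent = emptyenv(), size = length(vertices(N)))
  for (v in vertices(N)) assign(v, character(), envir = adj)
  for (i in seq_len(nrow(N$arcs))) {
    t <- N$arcs[i, 1L]
    assign(t, c(get(t, envir = adj), N$arcs[i, 2L]), envir = adj)
  }
  adj
}

# descendants (vertices strictly below v), by DFS
descendants <- function(N, v) {
  stack <- out_children(N, v)
  seen <- character()
  while (length(stack)) {
    u <- stack[[1L]]
    stack <- stack[-1L]
    if (u %in% seen) next
    seen <- c(seen, u)
    stack <- c(stack, out_children(N, u))
  }
  seen
}

#' Cluster of leaves below a vertex
#'
#' The hardwired cluster of `v`: the taxa labelling the leaves below `v`
#' (or the taxon of `v` itself when `v` is a leaf).
#'
#' @param N an `l1net` network.
#' @param v a vertex identifier.
#' @return sorted character vector of taxa.
#' @export
cluster_below <- function(N, v) {
  if (!v %in% vertices(N)) stop(sprintf("vertex %s is not in the network", v))
  if (v %in% names(N$leaves)) return(unname(N$leaves[[v]]))
  below <- descendants(N, v)
  sort(unname(N$leaves[names(N$leaves) %in% below]))
}

#' Basic size statistics of a network
#'
#' @param N an `l1net` network.
#' @return list with `n` (number of taxa), `n_vertices`, `n_arcs`, `n_galls`
#'   and `c_n` (number of non-trivial cut arcs).
#' @export
network_counts <- function(N) {
  list(
    n = length(N$leaves),
    n_vertices = length(vertices(N)),
    n_arcs = nrow(N$arcs),
    n_galls = length(galls(N)),
    c_n = if (is_degenerate(N)) 0L else cut_arcs(N)$c_n
  )
}
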