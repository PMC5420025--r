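#' Galls of a level-1 network
#'
#' A gall is a non-trivial biconnected component of the underlying graph with
#' the original arc directions restored: an undirected cycle formed by two
#' directed paths from a gall root down to a hybrid vertex.
#'
#' @param N an `l1net` network.
#' @return list of `l1_gall` objects, each with fields `root` (the top vertex
#'   of the cycle), `side1`/`side2` (the cycle vertices of the two root-to-
#'   hybrid paths, top to bottom, excluding root and hybrid), `hybrid`,
#'   `cycle` (all cycle vertices) and `outgoing` (arc matrix of arcs leaving
#'   the cycle).
#' @export
galls <- function(N) {
  if (is_degenerate(N)) return(list())
  hybs <- hybrid_vertices(N)
  lapply(nontrivial_bicomponents(N$arcs), function(comp) {
    within <- N$arcs[N$arcs[, 1L] %in% comp & N$arcs[, 2L] %in% comp, ,
                     drop = FALSE]
    hybrid <- intersect(hybs, comp)
    outdeg_in <- table(factor(within[, 1L], levels = comp))
    groot <- comp[outdeg_in == 2L]
    stopifnot(length(hybrid) == 1L, length(groot) == 1L)
    walk <- function(start) {
      path <- character()
      v <- start
      while (v != hybrid) {
        path <- c(path, v)
        v <- within[within[, 1L] == v, 2L]
      }
      path
    }
    tops <- within[within[, 1L] == groot, 2L]
    side1 <- if (tops[[1L]] == hybrid) character() else walk(tops[[1L]])
    side2 <- if (tops[[2L]] == hybrid) character() else walk(tops[[2L]])
    outgoing <- N$arcs[N$arcs[, 1L] %in% comp & !(N$arcs[, 2L] %in% comp), ,
                       drop = FALSE]
    structure(
      list(root = groot, side1 = side1, side2 = side2, hybrid = hybrid,
           cycle = c(groot, side1, hybrid, rev(side2)), outgoing = outgoing),
      class = "l1_gall"
    )
  })
}

#' @export
print.l1_gall <- function(x, ...) {
  cat(sprintf("<gall> root %s, hybrid %s, cycle of %d vertices, %d outgoing arcs\n",
              x$root, x$hybrid, length(x$cycle), nrow(x$outgoing)))
  invisible(x)
}

#' Classify the cut arcs of a network
#'
#' An arc is a cut arc if its deletion disconnects the underlying graph;
#' trivial if its head is a leaf.  A cut arc is highest if no other cut arc
#' lies on a directed path above it.
#'
#' @param N an `l1net` network.
#' @return an `l1_cut_arcs` object: arc matrices `trivial`, `nontrivial`,
#'   `highest`, and the count `c_n` of non-trivial cut arcs.
#' @export
cut_arcs <- function(N) {
  if (is_degenerate(N)) {
    empty <- matrix(character(), ncol = 2L)
    return(structure(list(trivial = empty, nontrivial = empty,
                          highest = empty, c_n = 0L),
                     class = "l1_cut_arcs"))
  }
  g <- arcs_igraph(N$arcs)
  u <- igraph::as_undirected(g, mode = "each")
  br <- igraph::bridges(u)
  ends <- igraph::ends(u, br, names = TRUE)
  # undirected bridge endpoints back to directed arcs
  key <- paste(N$arcs[, 1L], N$arcs[, 2L])
  is_cut <- key %in% c(paste(ends[, 1L], ends[, 2L]),
                       paste(ends[, 2L], ends[, 1L]))
  cut <- N$arcs[is_cut, , drop = FALSE]
  triv <- cut[, 2L] %in% names(N$leaves)

  reach <- is.finite(igraph::distances(g, mode = "out"))
  vn <- rownames(reach)
  highest <- vapply(seq_len(nrow(cut)), function(i) {
    u_i <- cut[i, 1L]
    others <- cut[-i, , drop = FALSE]
    if (nrow(others) == 0L) return(TRUE)
    !any(reach[match(others[, 2L], vn), match(u_i, vn)])
  }, logical(1))

  structure(
    list(trivial = cut[triv, , drop = FALSE],
         nontrivial = cut[!triv, , drop = FALSE],
         highest = cut[highest, , drop = FALSE],
         c_n = sum(!triv)),
    class = "l1_cut_arcs"
  )
}

#' @export
print.l1_cut_arcs <- function(x, ...) {
  cat(sprintf("<cut arcs> %d trivial, %d non-trivial (%d highest)\n",
              nrow(x$trivial), x$c_n, nrow(x$highest)))
  invisible(x)
}

#' The Cut partition of the taxa
#'
#' Partition of the taxon set given by the clusters below the heads of the
#' highest cut arcs.  For the triplet system induced by a level-1 network this
#' coincides with the set of maximal non-trivial SN-sets
#' (see [maximal_sn_sets()]).
#'
#' @param N an `l1net` network with at least 2 taxa.
#' @return an `l1_partition`: a list of sorted taxon vectors, ordered by their
#'   first element.
#' @export
cut_partition <- function(N) {
  if (length(N$leaves) < 2L) stop("cut_partition() needs at least 2 taxa")
  hi <- cut_arcs(N)$highest
  blocks <- lapply(seq_len(nrow(hi)), function(i) cluster_below(N, hi[i, 2L]))
  stopifnot(setequal(unlist(blocks), taxa(N)),
            sum(lengths(blocks)) == length(N$leaves))
  as_partition(blocks)
}

as_partition <- function(blocks) {
  blocks <- lapply(blocks, sort)
  blocks <- blocks[order(vapply(blocks, `[`, character(1), 1L))]
  structure(blocks, class = "l1_partition")
}

#' @export
print.l1_partition <- function(x, ...) {
  cat("<partition>",
      paste(vapply(x, function(b) paste0("{", paste(b, collapse = ","), "}"),
                   character(1)), collapse = " "), "\n")
  invisible(x)
}

#' @export
format.l1_partition <- function(x, ...) {
  paste(vapply(x, function(b) paste0("{", paste(b, collapse = ","), "}"),
               character(1)), collapse = " ")
}

#' Structural property flags of a network
#'
#' @param N an `l1net` network.
#' @return list of logical flags:
#'   * `is_tree`: no hybrid vertex (level-0);
#'   * `is_proper`: at least one gall;
#'   * `is_simple`: exactly one gall and every leaf adjacent to its cycle;
#'   * `is_saturated`: no vertex incident with more than one cut arc (read
#'     literally, so trees are never saturated: their root is incident with
#'     two);
#'   * `is_4_outwards`: no underlying cycle on 4 or fewer vertices.
#' @export
classify_network <- function(N) {
  if (is_degenerate(N)) {
    return(list(is_tree = TRUE, is_proper = FALSE, is_simple = FALSE,
                is_saturated = TRUE, is_4_outwards = TRUE))
  }
  gs <- galls(N)
  leaves <- names(N$leaves)
  simple <- FALSE
  if (length(gs) == 1L) {
    cyc <- gs[[1L]]$cycle
    parents <- N$arcs[match(leaves, N$arcs[, 2L]), 1L]
    simple <- all(parents %in% cyc)
  }
  ca <- cut_arcs(N)
  cut <- rbind(ca$trivial, ca$nontrivial)
  incident <- table(c(cut[, 1L], cut[, 2L]))
  list(
    is_tree = length(gs) == 0L,
    is_proper = length(gs) >= 1L,
    is_simple = simple,
    is_saturated = all(incident <= 1L),
    is_4_outwards = all(vapply(gs, function(g) length(g$cycle), integer(1)) >= 5L)
  )
}
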