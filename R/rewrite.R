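# Graph clean-up engine shared by restriction and displayed-tree extraction.
#
# Operates on a multigraph state (arcs may temporarily be parallel) and
# repeatedly applies the five clean-up rules until none applies:
#   r1  suppress vertices with in-degree 1 and out-degree 1
#   r2  delete non-leaf sinks
#   r3  collapse parallel arcs
#   r4  rewire a gall left with exactly two outgoing cut arcs
#   r5  delete vertices with in-degree 0 and out-degree 1
# The rules are confluent up to equivalence; `order = "random"` exercises
# arbitrary application orders (used by the property tests).

cleanup_state <- function(arcs, leaves) list(arcs = arcs, leaves = leaves)

state_vertices <- function(st) unique(c(c(st$arcs), names(st$leaves)))

cleanup_moves <- function(st, rule) {
  arcs <- st$arcs
  verts <- state_vertices(st)
  outdeg <- table(factor(arcs[, 1L], levels = verts))
  indeg <- table(factor(arcs[, 2L], levels = verts))
  switch(rule,
    r3 = {
      dup <- which(duplicated(paste(arcs[, 1L], arcs[, 2L])))
      lapply(dup, function(i) list(rule = "r3", row = i))
    },
    r2 = {
      sinks <- verts[outdeg == 0L & !(verts %in% names(st$leaves))]
      lapply(sinks, function(v) list(rule = "r2", vertex = v))
    },
    r1 = {
      vs <- verts[indeg == 1L & outdeg == 1L]
      lapply(vs, function(v) list(rule = "r1", vertex = v))
    },
    r5 = {
      vs <- verts[indeg == 0L & outdeg == 1L]
      lapply(vs, function(v) list(rule = "r5", vertex = v))
    },
    r4 = {
      if (nrow(arcs) == 0L) return(list())
      out <- list()
      for (comp in nontrivial_bicomponents(arcs)) {
        within <- arcs[, 1L] %in% comp & arcs[, 2L] %in% comp
        wa <- arcs[within, , drop = FALSE]
        if (anyDuplicated(paste(wa[, 1L], wa[, 2L]))) next  # r3 first
        if (nrow(wa) != length(comp) || length(comp) < 3L) next
        outgoing <- which(arcs[, 1L] %in% comp & !(arcs[, 2L] %in% comp))
        if (length(outgoing) != 2L) next
        win <- table(factor(wa[, 1L], levels = comp))
        r <- comp[win == 2L]
        if (length(r) != 1L) next
        out[[length(out) + 1L]] <-
          list(rule = "r4", comp = comp, within = which(within),
               outgoing = outgoing, r = r)
      }
      out
    }
  )
}

apply_move <- function(st, mv) {
  arcs <- st$arcs
  switch(mv$rule,
    r3 = st$arcs <- arcs[-mv$row, , drop = FALSE],
    r2 = {
      st$arcs <- arcs[arcs[, 2L] != mv$vertex, , drop = FALSE]
    },
    r1 = {
      p <- arcs[arcs[, 2L] == mv$vertex, 1L]
      c_ <- arcs[arcs[, 1L] == mv$vertex, 2L]
      keep <- arcs[, 1L] != mv$vertex & arcs[, 2L] != mv$vertex
      st$arcs <- rbind(arcs[keep, , drop = FALSE], c(p, c_))
    },
    r5 = {
      st$arcs <- arcs[arcs[, 1L] != mv$vertex, , drop = FALSE]
    },
    r4 = {
      heads <- arcs[mv$outgoing, 2L]
      drop <- union(mv$within, mv$outgoing)
      st$arcs <- rbind(arcs[-drop, , drop = FALSE],
                       cbind(mv$r, heads))
    }
  )
  st
}

run_cleanup <- function(st, order = c("fixed", "random"), use_r4 = TRUE) {
  order <- match.arg(order)
  priority <- c("r3", "r2", "r1", "r5", if (use_r4) "r4")
  repeat {
    if (order == "fixed") {
      mv <- NULL
      for (rule in priority) {
        ms <- cleanup_moves(st, rule)
        if (length(ms)) { mv <- ms[[1L]]; break }
      }
    } else {
      ms <- unlist(lapply(priority, function(r) cleanup_moves(st, r)),
                   recursive = FALSE)
      mv <- if (length(ms)) ms[[sample.int(length(ms), 1L)]] else NULL
    }
    if (is.null(mv)) return(st)
    st <- apply_move(st, mv)
  }
}

finalize_network <- function(st, validate = TRUE) {
  if (nrow(st$arcs) == 0L) {
    stopifnot(length(st$leaves) == 1L)
    return(leaf_network(unname(st$leaves), names(st$leaves)))
  }
  build_network(st$arcs, st$leaves, validate = validate)
}

#' Restrict a network to a subset of its taxa
#'
#' Deletes the leaves outside `keep` and applies the clean-up operations
#' (suppression of degree-two vertices, deletion of unlabelled sinks, collapse
#' of parallel arcs, rewiring of galls left with exactly two outgoing cut
#' arcs, deletion of out-degree-one sources) until a valid network on `keep`
#' remains.  On trees this is the usual restriction.  The rules may be applied
#' in any order; the result is unique up to equivalence.
#'
#' @param N an `l1net` network.
#' @param keep non-empty subset of `taxa(N)` to retain.
#' @param order clean-up scheduling; `"random"` picks applicable rule
#'   instances at random and is only useful for checking confluence.
#' @return an `l1net` network on `keep` (degenerate single leaf when
#'   `length(keep) == 1`).
#' @export
restrict_network <- function(N, keep, order = "fixed") {
  keep <- unique(keep)
  if (length(keep) == 0L) stop("`keep` must be a non-empty set of taxa")
  if (!all(keep %in% taxa(N))) {
    stop("`keep` contains taxa not in the network: ",
         paste(setdiff(keep, taxa(N)), collapse = ", "))
  }
  if (setequal(keep, taxa(N)) && order == "fixed") return(N)
  drop_vertices <- names(N$leaves)[!(N$leaves %in% keep)]
  arcs <- N$arcs[!(N$arcs[, 1L] %in% drop_vertices) &
                   !(N$arcs[, 2L] %in% drop_vertices), , drop = FALSE]
  leaves <- N$leaves[N$leaves %in% keep]
  st <- run_cleanup(cleanup_state(arcs, leaves), order = order)
  finalize_network(st)
}

#' Phylogenetic trees displayed by a network
#'
#' For each way of choosing one in-arc per hybrid vertex (one per gall,
#' `2^g(N)` switchings in total), delete the other in-arc and suppress the
#' resulting degree-two vertices.  The switchings are deduplicated up to
#' equivalence, so the result is the set of distinct trees on the full taxon
#' set that the network displays.
#'
#' @param N an `l1net` network.
#' @return list of `l1net` trees (level-0 networks) on `taxa(N)`.
#' @export
displayed_trees <- function(N) {
  if (is_degenerate(N)) return(list(N))
  hybs <- hybrid_vertices(N)
  if (length(hybs) == 0L) return(list(N))
  per_hybrid <- lapply(hybs, function(h) which(N$arcs[, 2L] == h))
  combos <- expand.grid(lapply(per_hybrid, seq_along))
  trees <- list()
  seen <- character()
  for (i in seq_len(nrow(combos))) {
    drop <- vapply(seq_along(hybs),
                   function(j) per_hybrid[[j]][combos[i, j]], integer(1))
    st <- cleanup_state(N$arcs[-drop, , drop = FALSE], N$leaves)
    # deleting one in-arc per hybrid leaves no undirected cycle, so the gall
    # rewiring rule can never apply and validation is redundant here
    tr <- finalize_network(run_cleanup(st, use_r4 = FALSE), validate = FALSE)
    key <- canonical_form(tr)
    if (!key %in% seen) {
      seen <- c(seen, key)
      trees[[length(trees) + 1L]] <- tr
    }
  }
  trees
}

#' Collapse a network onto its Cut partition
#'
#' Replaces, for each highest cut arc, the sub-network hanging below it by a
#' single representative leaf (the lexicographically least taxon of its
#' block).  The result is a simple network or a tree on two leaves; together
#' with the pruned sub-networks it determines the original network.
#'
#' @param N an `l1net` network with at least 2 taxa.
#' @return list with components `network` (the collapsed network on the
#'   representatives), `subnetworks` (named list of the pruned `l1net`
#'   sub-networks, isolated leaves for singleton blocks), and `partition`
#'   (the Cut partition).
#' @export
collapse_network <- function(N) {
  if (length(N$leaves) < 2L) stop("collapse_network() needs at least 2 taxa")
  hi <- cut_arcs(N)$highest
  heads <- hi[, 2L]
  blocks <- lapply(heads, function(v) cluster_below(N, v))
  reps <- vapply(blocks, min, character(1))

  subnetworks <- setNames(lapply(seq_along(heads), function(i) {
    v <- heads[[i]]
    if (v %in% names(N$leaves)) return(leaf_network(unname(N$leaves[[v]]), v))
    verts <- c(v, descendants(N, v))
    arcs <- N$arcs[N$arcs[, 1L] %in% verts, , drop = FALSE]
    build_network(arcs, N$leaves[names(N$leaves) %in% verts])
  }), reps)

  below <- unlist(lapply(heads, function(v) descendants(N, v)))
  keep <- setdiff(vertices(N), below)
  arcs <- N$arcs[N$arcs[, 1L] %in% keep & N$arcs[, 2L] %in% keep, , drop = FALSE]
  collapsed <- build_network(arcs, setNames(reps, heads))

  list(network = collapsed, subnetworks = subnetworks,
       partition = as_partition(blocks))
}
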