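# Networks are generated through their recursive blob decomposition: a network
# on X is a single leaf, a root split over an unordered bipartition into two
# sub-networks, or a root gall given by an ordered left block list, an ordered
# right block list and a hybrid block (at least 3 blocks in total, so the
# underlying cycle has at least 4 vertices), every block again a network.
# Shapes are deduplicated by the same canonical encoding as canonical_form(),
# which quotients out the left/right reflection of each gall.

shape_leaf <- function(taxon) list(type = "leaf", taxon = taxon)
shape_split <- function(a, b) list(type = "split", kids = list(a, b))
shape_gall <- function(left, right, hyb) {
  list(type = "gall", left = left, right = right, hyb = hyb)
}

shape_canon <- function(s) {
  switch(s$type,
    leaf = leaf_code(s$taxon),
    split = {
      k <- sort(vapply(s$kids, shape_canon, character(1)))
      paste0("(", paste(k, collapse = ","), ")")
    },
    gall = {
      l <- vapply(s$left, shape_canon, character(1))
      r <- vapply(s$right, shape_canon, character(1))
      h <- shape_canon(s$hyb)
      min(
        paste0("[", paste(l, collapse = ","), "|", paste(r, collapse = ","), "|", h, "]"),
        paste0("[", paste(r, collapse = ","), "|", paste(l, collapse = ","), "|", h, "]")
      )
    }
  )
}

shape_taxa <- function(s) {
  switch(s$type,
    leaf = s$taxon,
    split = unlist(lapply(s$kids, shape_taxa)),
    gall = c(unlist(lapply(c(s$left, s$right), shape_taxa)), shape_taxa(s$hyb))
  )
}

shape_to_network <- function(s, validate = FALSE) {
  counter <- new.env(parent = emptyenv())
  counter$i <- 0L
  arcs <- list()
  leaves <- character()
  fresh <- function() {
    counter$i <- counter$i + 1L
    paste0("v", counter$i)
  }
  build <- function(s) {
    if (s$type == "leaf") {
      id <- fresh()
      leaves[[id]] <<- s$taxon
      return(id)
    }
    if (s$type == "split") {
      v <- fresh()
      arcs[[length(arcs) + 1L]] <<- c(v, build(s$kids[[1L]]))
      arcs[[length(arcs) + 1L]] <<- c(v, build(s$kids[[2L]]))
      return(v)
    }
    r <- fresh()
    h <- fresh()
    chain <- function(side) {
      prev <- r
      for (blk in side) {
        u <- fresh()
        arcs[[length(arcs) + 1L]] <<- c(prev, u)
        arcs[[length(arcs) + 1L]] <<- c(u, build(blk))
        prev <- u
      }
      arcs[[length(arcs) + 1L]] <<- c(prev, h)
    }
    chain(s$left)
    chain(s$right)
    arcs[[length(arcs) + 1L]] <<- c(h, build(s$hyb))
    r
  }
  top <- build(s)
  if (length(arcs) == 0L) return(leaf_network(s$taxon, top))
  build_network(do.call(rbind, arcs), leaves, validate = validate)
}

# structural flags, computed on the shape (cheap; cross-checked against
# classify_network() in the tests)
shape_flags <- function(s) {
  galls_info <- function(s) {
    switch(s$type,
      leaf = list(),
      split = c(galls_info(s$kids[[1L]]), galls_info(s$kids[[2L]])),
      gall = c(list(length(s$left) + length(s$right)),
               unlist(lapply(c(s$left, s$right, list(s$hyb)), galls_info),
                      recursive = FALSE))
    )
  }
  has_split <- function(s) {
    switch(s$type,
      leaf = FALSE,
      split = TRUE,
      gall = any(vapply(c(s$left, s$right, list(s$hyb)), has_split, logical(1)))
    )
  }
  side_counts <- unlist(galls_info(s))
  g <- length(side_counts)
  all_leaf_blocks <- s$type == "gall" &&
    all(vapply(c(s$left, s$right, list(s$hyb)), function(b) b$type == "leaf",
               logical(1)))
  list(
    is_tree = g == 0L,
    is_proper = g >= 1L,
    is_simple = g == 1L && all_leaf_blocks,
    is_saturated = !has_split(s),
    is_4_outwards = g == 0L || all(side_counts >= 3L)
  )
}

set_partitions <- function(x) {
  if (length(x) == 1L) return(list(list(x)))
  rest <- set_partitions(x[-1L])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(x[[1L]], q[[i]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(x[[1L]]), p)
  }
  out
}

permutations <- function(n) {
  if (n == 0L) return(list(integer()))
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in permutations(n - 1L)) {
    for (k in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}

cartesian <- function(lists) {
  # all ways to pick one element from each list
  out <- list(list())
  for (l in lists) {
    out <- unlist(lapply(out, function(acc) {
      lapply(l, function(e) c(acc, list(e)))
    }), recursive = FALSE)
  }
  out
}

all_shapes <- function(tx, memo) {
  key <- paste(sort(tx), collapse = "\r")
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  n <- length(tx)
  res <- list()
  seen <- character()
  add <- function(s) {
    k <- shape_canon(s)
    if (!k %in% seen) {
      seen <<- c(seen, k)
      res[[length(res) + 1L]] <<- s
    }
  }
  if (n == 1L) {
    add(shape_leaf(tx))
  } else {
    rest <- setdiff(tx, tx[[1L]])
    for (k in 0:(n - 2L)) {
      subsets <- if (k == 0L) list(character()) else asplit(combn(rest, k), 2L)
      for (S in subsets) {
        A <- c(tx[[1L]], as.character(S))
        B <- setdiff(tx, A)
        for (sa in all_shapes(A, memo)) {
          for (sb in all_shapes(B, memo)) add(shape_split(sa, sb))
        }
      }
    }
    if (n >= 3L) {
      for (P in set_partitions(tx)) {
        m <- length(P)
        if (m < 3L) next
        block_shapes <- lapply(P, all_shapes, memo = memo)
        for (hi in seq_len(m)) {
          rest_idx <- setdiff(seq_len(m), hi)
          for (perm in permutations(m - 1L)) {
            ord <- rest_idx[perm]
            for (cut in 0:(m - 1L)) {
              li <- ord[seq2(1L, cut)]
              ri <- ord[seq2(cut + 1L, m - 1L)]
              for (combo in cartesian(block_shapes[c(li, ri, hi)])) {
                nl <- length(li)
                add(shape_gall(combo[seq2(1L, nl)],
                               combo[seq2(nl + 1L, m - 1L)],
                               combo[[m]]))
              }
            }
          }
        }
      }
    }
  }
  memo[[key]] <- res
  res
}

make_universe <- function(shapes, taxa, filter) {
  flags <- do.call(rbind, lapply(shapes, function(s) as.data.frame(shape_flags(s))))
  keep <- switch(filter,
    all = rep(TRUE, length(shapes)),
    proper = flags$is_proper,
    tree = flags$is_tree,
    simple = flags$is_simple,
    four_outwards = flags$is_4_outwards,
    saturated = flags$is_saturated
  )
  shapes <- shapes[keep]
  flags <- flags[keep, , drop = FALSE]
  rownames(flags) <- NULL
  structure(
    list(taxa = sort(taxa),
         networks = lapply(shapes, shape_to_network),
         enc = vapply(shapes, shape_canon, character(1)),
         flags = flags,
         filter = filter,
         cache = new.env(parent = emptyenv())),
    class = "l1_universe"
  )
}

#' Exhaustively enumerate binary level-1 networks on a taxon set
#'
#' Generates, up to equivalence, every binary level-1 network on the given
#' taxa by recursive blob decomposition, optionally filtered by a structural
#' property.  Exhaustive enumeration grows super-exponentially and is guarded
#' to 6 taxa.
#'
#' @param taxa character vector of 2 to 6 taxon names (or a single integer n,
#'   shorthand for taxa `x1..xn`).
#' @param filter one of `"all"`, `"proper"`, `"tree"`, `"simple"`,
#'   `"four_outwards"`, `"saturated"`.
#' @param allow_large override the 6-taxon guard.
#' @return an `l1_universe`: pairwise non-equivalent networks plus their
#'   structural flags.
#' @export
enumerate_level1 <- function(taxa,
                             filter = c("all", "proper", "tree", "simple",
                                        "four_outwards", "saturated"),
                             allow_large = FALSE) {
  filter <- match.arg(filter)
  if (length(taxa) == 1L && !is.character(taxa)) {
    taxa <- paste0("x", seq_len(taxa))
  }
  if (length(taxa) < 2L) stop("enumeration needs at least 2 taxa")
  if (length(taxa) > 6L && !allow_large) {
    stop("exhaustive enumeration is guarded to 6 taxa; set allow_large = TRUE to override")
  }
  memo <- new.env(parent = emptyenv())
  make_universe(all_shapes(sort(taxa), memo), taxa, filter)
}

#' Enumerate the simple networks on a taxon set
#'
#' Direct construction: choose the hybrid leaf, then split the remaining
#' leaves into two ordered side sequences along the cycle (sides may be empty
#' as long as the cycle keeps at least 4 vertices); reflections are
#' deduplicated.
#'
#' @param taxa character vector of at least 3 taxon names (or an integer n).
#' @return an `l1_universe` of simple networks.
#' @export
enumerate_simple <- function(taxa) {
  if (length(taxa) == 1L && !is.character(taxa)) {
    taxa <- paste0("x", seq_len(taxa))
  }
  if (length(taxa) < 3L) stop("a simple network needs at least 3 taxa")
  taxa <- sort(taxa)
  shapes <- list()
  seen <- character()
  for (h in taxa) {
    others <- setdiff(taxa, h)
    k <- length(others)
    for (perm in permutations(k)) {
      ord <- others[perm]
      for (cut in 0:k) {
        s <- shape_gall(lapply(ord[seq2(1L, cut)], shape_leaf),
                        lapply(ord[seq2(cut + 1L, k)], shape_leaf),
                        shape_leaf(h))
        key <- shape_canon(s)
        if (!key %in% seen) {
          seen <- c(seen, key)
          shapes[[length(shapes) + 1L]] <- s
        }
      }
    }
  }
  make_universe(shapes, taxa, "all")
}

#' @export
print.l1_universe <- function(x, ...) {
  cat(sprintf("<l1 universe> %d pairwise non-equivalent networks on {%s} (filter: %s)\n",
              length(x$networks), paste(x$taxa, collapse = ","), x$filter))
  invisible(x)
}

#' Filter an existing universe by structural flags
#'
#' @param universe an `l1_universe`.
#' @param ... logical expressions over the flag columns `is_tree`,
#'   `is_proper`, `is_simple`, `is_saturated`, `is_4_outwards`.
#' @return an `l1_universe` restricted to the matching members.
#' @export
universe_subset <- function(universe, ...) {
  keep <- rep(TRUE, nrow(universe$flags))
  exprs <- substitute(list(...))
  for (i in seq_along(exprs)[-1L]) {
    keep <- keep & eval(exprs[[i]], universe$flags, parent.frame())
  }
  structure(
    list(taxa = universe$taxa,
         networks = universe$networks[keep],
         enc = universe$enc[keep],
         flags = universe$flags[keep, , drop = FALSE],
         filter = "subset",
         cache = new.env(parent = emptyenv())),
    class = "l1_universe"
  )
}

# Induced systems of every universe member, computed once per universe and
# cached; triplets and softwired clusters share one displayed-tree pass.
universe_systems <- function(universe, kind = c("triplets", "clusters")) {
  kind <- match.arg(kind)
  cache <- universe$cache
  if (is.null(cache$triplets)) {
    trips <- vector("list", length(universe$networks))
    clus <- vector("list", length(universe$networks))
    for (i in seq_along(universe$networks)) {
      trees <- displayed_trees(universe$networks[[i]])
      trips[[i]] <- sort(unique(unlist(lapply(trees, function(T) unclass(tree_triplets(T))))))
      clus[[i]] <- sort(unique(unlist(lapply(trees, function(T) unclass(hardwired_clusters(T))))))
    }
    cache$triplets <- trips
    cache$clusters <- clus
  }
  if (kind == "triplets") cache$triplets else cache$clusters
}

#' Write or read a universe as extended Newick lines
#'
#' @param universe an `l1_universe`.
#' @param path file path (one eNewick string per line).
#' @export
universe_write <- function(universe, path) {
  writeLines(vapply(universe$networks, write_enewick, character(1)), path)
  invisible(path)
}

#' @rdname universe_write
#' @export
universe_read <- function(path) {
  networks <- lapply(readLines(path), parse_enewick)
  flags <- do.call(rbind, lapply(networks, function(N) {
    f <- classify_network(N)
    data.frame(is_tree = f$is_tree, is_proper = f$is_proper,
               is_simple = f$is_simple, is_saturated = f$is_saturated,
               is_4_outwards = f$is_4_outwards)
  }))
  structure(
    list(taxa = taxa(networks[[1L]]),
         networks = networks,
         enc = vapply(networks, canonical_form, character(1)),
         flags = flags,
         filter = "file",
         cache = new.env(parent = emptyenv())),
    class = "l1_universe"
  )
}

#' Generate a random binary level-1 network
#'
#' Recursive top-down generation: with probability `gall_rate` the current
#' taxon block becomes a gall (block sizes drawn uniformly over admissible
#' compositions), otherwise a split over a random bipartition.  Fully
#' reproducible through `seed`.
#'
#' @param n number of taxa (at least 2); ignored when `taxa` is given.
#' @param seed optional integer seed (the caller's RNG state is preserved).
#' @param gall_rate probability of placing a gall at an internal decision
#'   point with at least 3 taxa below it.
#' @param taxa taxon names.
#' @return an `l1net` network.
#' @export
random_level1 <- function(n, seed = NULL, gall_rate = 0.4,
                          taxa = sprintf("t%02d", seq_len(n))) {
  if (length(taxa) < 2L) stop("random_level1() needs at least 2 taxa")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  gen <- function(tx) {
    m <- length(tx)
    if (m == 1L) return(shape_leaf(tx))
    if (m >= 3L && stats::runif(1L) < gall_rate) {
      nb <- if (m == 3L) 3L else sample(3:m, 1L)
      cuts <- sort(sample(m - 1L, nb - 1L))
      shuffled <- sample(tx)
      sizes <- diff(c(0L, cuts, m))
      blocks <- split(shuffled, rep(seq_len(nb), sizes))
      hi <- sample(nb, 1L)
      rest <- sample(setdiff(seq_len(nb), hi))
      cut <- sample(0:(nb - 1L), 1L)
      return(shape_gall(lapply(blocks[rest[seq2(1L, cut)]], gen),
                        lapply(blocks[rest[seq2(cut + 1L, nb - 1L)]], gen),
                        gen(blocks[[hi]])))
    }
    k <- sample(m - 1L, 1L)
    A <- sample(tx, k)
    shape_split(gen(A), gen(setdiff(tx, A)))
  }
  shape_to_network(gen(sort(taxa)), validate = TRUE)
}
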