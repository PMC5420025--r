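# Shared fixtures and independent oracles.  Exhaustive universes are expensive
# to build, so they are generated once per test run and memoised here.

.universe_cache <- new.env(parent = emptyenv())

get_universe <- function(n, filter = "all") {
  key <- paste(n, filter)
  hit <- .universe_cache[[key]]
  if (!is.null(hit)) return(hit)
  U <- enumerate_level1(n, filter = filter)
  .universe_cache[[key]] <- U
  U
}

# Independent equivalence oracle: igraph VF2 with leaf labels as colours and a
# single colour for interior vertices.
iso_oracle <- function(N, M) {
  tax <- sort(taxa(N))
  if (!setequal(tax, taxa(M))) return(FALSE)
  as_coloured <- function(net) {
    g <- l1net:::arcs_igraph(net$arcs)
    nm <- igraph::V(g)$name
    col <- rep(0L, length(nm))
    li <- match(nm, names(net$leaves))
    col[!is.na(li)] <- match(unname(net$leaves[li[!is.na(li)]]), tax)
    list(g = g, col = col)
  }
  a <- as_coloured(N)
  b <- as_coloured(M)
  igraph::isomorphic(a$g, b$g, method = "vf2",
                     vertex.color1 = a$col, vertex.color2 = b$col)
}

# Independent cut-arc oracle: delete each arc in turn and test connectivity of
# the underlying graph.
cut_arc_oracle <- function(N) {
  is_cut <- vapply(seq_len(nrow(N$arcs)), function(i) {
    rest <- N$arcs[-i, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
      data.frame(from = rest[, 1L], to = rest[, 2L]),
      directed = FALSE,
      vertices = data.frame(name = unique(c(c(N$arcs)))))
    igraph::components(g)$no == 1L
  }, logical(1))
  N$arcs[!is_cut, , drop = FALSE]
}

arc_key <- function(m) sort(paste(m[, 1L], m[, 2L]))

# the 16 triplets induced by the simple 5-leaf network with gall sides
# (x1, x2) and (x5, x4) and hybrid leaf x3
printed_triplets_16 <- c(
  "x1,x2|x3", "x1,x2|x4", "x1,x2|x5", "x3,x4|x1", "x1,x3|x4", "x3,x5|x1",
  "x1,x3|x5", "x4,x5|x1", "x3,x4|x2", "x2,x3|x4", "x3,x5|x2", "x2,x3|x5",
  "x4,x5|x2", "x4,x5|x3", "x3,x4|x5", "x2,x3|x1"
)

# 11 softwired clusters displayed by the simple 5-leaf network with gall
# sides (x1) and (x2, x3, x4) and hybrid leaf x5
printed_clusters_11 <- c(
  "x1,x2,x3,x4,x5", "x2,x3,x4,x5", "x3,x4,x5", "x4,x5", "x2,x3,x4", "x3,x4",
  "x1", "x2", "x3", "x4", "x5"
)
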