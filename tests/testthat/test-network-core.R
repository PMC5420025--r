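test_that("valid networks build and invalid ones are rejected with diagnostics", {
  # the 4-cycle simple network on 3 leaves has 7 vertices and 7 arcs
  N <- build_network(
    rbind(c("r", "a"), c("r", "b"), c("a", "h"), c("b", "h"),
          c("a", "x1"), c("b", "x2"), c("h", "x3")),
    c(x1 = "x1", x2 = "x2", x3 = "x3"))
  cnt <- network_counts(N)
  expect_equal(cnt$n_vertices, 7L)
  expect_equal(cnt$n_arcs, 7L)
  expect_equal(cnt$n_galls, 1L)

  # smallest tree: a cherry
  cherry <- build_network(rbind(c("r", "x1"), c("r", "x2")))
  expect_true(classify_network(cherry)$is_tree)

  # underlying 3-cycle is forbidden
  expect_error(
    build_network(rbind(c("r", "a"), c("r", "h"), c("a", "h"),
                        c("a", "x1"), c("h", "x2"))),
    "fewer than 4 vertices")

  # two roots
  expect_error(
    build_network(rbind(c("r", "x1"), c("r", "x2"), c("s", "x3"), c("s", "x4"))),
    "exactly one root")

  # two hybrids in one biconnected component (level-2 blob)
  expect_error(
    build_network(rbind(
      c("r", "a"), c("r", "b"), c("a", "h1"), c("b", "h1"),
      c("a", "c"), c("b", "d"), c("c", "h2"), c("d", "h2"),
      c("c", "x1"), c("d", "x2"), c("h1", "x3"), c("h2", "x4"))),
    "hybrid")

  # diagnostics list every violation at once
  msgs <- validate_network(rbind(c("r", "a"), c("r", "a"), c("a", "a")),
                           c(a = "a"))
  expect_true(any(grepl("parallel", msgs)))
  expect_true(any(grepl("loop", msgs)))
})

test_that("cut arcs match the brute-force deletion oracle and worked examples", {
  # every arc of a tree is a cut arc; n - 2 of them are non-trivial
  tr <- random_level1(6, seed = 3, gall_rate = 0)
  ca <- cut_arcs(tr)
  expect_equal(nrow(ca$trivial) + nrow(ca$nontrivial), 2L * (6L - 1L))
  expect_equal(ca$c_n, 4L)
  expect_equal(arc_key(rbind(ca$trivial, ca$nontrivial)),
               arc_key(cut_arc_oracle(tr)))

  # oracle agreement on proper networks too
  for (s in 1:5) {
    N <- random_level1(6, seed = s, gall_rate = 0.6)
    ca <- cut_arcs(N)
    expect_equal(arc_key(rbind(ca$trivial, ca$nontrivial)),
                 arc_key(cut_arc_oracle(N)))
  }

  # 3-leaf simple network: 3 trivial cut arcs, no non-trivial ones
  ca3 <- cut_arcs(simple3_network())
  expect_equal(nrow(ca3$trivial), 3L)
  expect_equal(ca3$c_n, 0L)

  # a triplet has exactly one non-trivial cut arc
  trip <- parse_enewick("((a,b),c);")
  expect_equal(cut_arcs(trip)$c_n, 1L)
})

test_that("the Cut partition consists of the clusters below highest cut arcs", {
  pair <- contrast_pair(c("y1", "y2"))
  expect_equal(format(cut_partition(pair$N1)), "{a,b,c} {d,y1,y2}")

  cat3 <- parse_enewick("(x1,(x2,x3));")
  expect_equal(format(cut_partition(cat3)), "{x1} {x2,x3}")

  # all cut arcs of a simple network are trivial: all-singleton partition
  for (N in enumerate_simple(4)$networks) {
    expect_true(all(lengths(cut_partition(N)) == 1L))
  }
})

test_that("classification flags behave as defined", {
  f22 <- classify_network(simple5_sides22())
  expect_true(f22$is_simple && f22$is_saturated && f22$is_4_outwards)

  f3 <- classify_network(simple3_network())
  expect_true(f3$is_simple && f3$is_saturated)
  expect_false(f3$is_4_outwards)  # its cycle has exactly 4 vertices

  # a tree root is incident with two cut arcs, so trees are never saturated
  ftr <- classify_network(random_level1(5, seed = 1, gall_rate = 0))
  expect_true(ftr$is_tree)
  expect_false(ftr$is_saturated)
  expect_true(ftr$is_4_outwards)

  # shape-derived universe flags agree with graph-based classification
  U <- get_universe(4)
  for (i in seq_along(U$networks)) {
    expect_equal(unlist(classify_network(U$networks[[i]])),
                 unlist(U$flags[i, ]), ignore_attr = TRUE)
  }
})

test_that("cluster_below returns the leaves under a vertex", {
  N <- simple3_network()
  expect_equal(cluster_below(N, N$root), c("x1", "x2", "x3"))
  leafv <- names(N$leaves)[N$leaves == "x1"]
  expect_equal(cluster_below(N, leafv), "x1")
  hyb <- l1net:::hybrid_vertices(N)
  expect_equal(cluster_below(N, hyb), "x3")
  expect_error(cluster_below(N, "nope"), "not in the network")
})

test_that("vertex and arc counts of trees follow the closed forms", {
  for (n in c(4L, 7L)) {
    tr <- random_level1(n, seed = n, gall_rate = 0)
    cnt <- network_counts(tr)
    expect_equal(cnt$n_vertices, 2L * n - 1L)
    expect_equal(cnt$n_arcs, 2L * (n - 1L))
  }
})
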