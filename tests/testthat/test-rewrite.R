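test_that("restriction reproduces the worked examples", {
  N3 <- simple3_network()
  # keeping the whole taxon set is the identity
  expect_identical(restrict_network(N3, taxa(N3)), N3)
  # dropping one side leaf triggers the gall-rewiring rule and leaves a cherry
  r <- restrict_network(N3, c("x1", "x3"))
  expect_true(classify_network(r)$is_tree)
  expect_equal(taxa(r), c("x1", "x3"))
  # one taxon: degenerate single-leaf network
  one <- restrict_network(N3, "x3")
  expect_equal(nrow(one$arcs), 0L)
  expect_equal(taxa(one), "x3")
  # errors
  expect_error(restrict_network(N3, character()), "non-empty")
  expect_error(restrict_network(N3, c("x1", "zz")), "not in the network")
})

test_that("tree restriction agrees with ape::keep.tip", {
  skip_if_not_installed("ape")
  for (s in 1:8) {
    N <- random_level1(7, seed = s, gall_rate = 0)
    set.seed(s)
    keep <- sample(taxa(N), 4)
    mine <- restrict_network(N, keep)
    ref <- ape::keep.tip(ape::read.tree(text = write_enewick(N)), keep)
    expect_true(are_equivalent(mine, parse_enewick(ape::write.tree(ref))))
  }
})

test_that("the clean-up rules are confluent", {
  set.seed(13)
  for (k in 1:60) {
    N <- random_level1(sample(4:8, 1), gall_rate = 0.5)
    tx <- taxa(N)
    keep <- sample(tx, sample(2:(length(tx) - 1L), 1))
    ref <- canonical_form(restrict_network(N, keep))
    for (r in 1:2) {
      expect_identical(canonical_form(restrict_network(N, keep, order = "random")),
                       ref)
    }
  }
})

test_that("restriction of induced systems matches systems of restrictions", {
  # triplets of a restriction are exactly the surviving triplets
  set.seed(5)
  for (k in 1:10) {
    N <- random_level1(6, gall_rate = 0.5)
    keep <- sample(taxa(N), 4)
    expect_setequal(
      unclass(triplet_system(restrict_network(N, keep))),
      intersect(unclass(triplet_system(N)), all_triplets(keep)))
  }
})

test_that("displayed trees match the worked examples", {
  trs <- displayed_trees(simple3_network())
  expect_length(trs, 2L)
  expect_setequal(vapply(trs, function(t) unclass(tree_triplets(t)), character(1)),
                  c("x2,x3|x1", "x1,x3|x2"))

  tr <- random_level1(6, seed = 2, gall_rate = 0)
  expect_length(displayed_trees(tr), 1L)
  expect_true(are_equivalent(displayed_trees(tr)[[1L]], tr))

  # the two switchings of the 2+2-sided simple 5-leaf network
  trs5 <- displayed_trees(simple5_sides22())
  expect_length(trs5, 2L)
  want <- c(canonical_form(parse_enewick("((x1,(x2,x3)),(x5,x4));")),
            canonical_form(parse_enewick("((x1,x2),(x5,(x4,x3)));")))
  expect_setequal(vapply(trs5, canonical_form, character(1)), want)
  # and their triplet union is the printed 16-element system
  expect_setequal(unlist(lapply(trs5, function(t) unclass(tree_triplets(t)))),
                  printed_triplets_16)
})

test_that("collapse yields a simple network or a two-leaf tree", {
  # a simple network is a fixed point
  N <- simple5_sides13()
  expect_true(are_equivalent(collapse_network(N)$network, N))

  # bipartite Cut partition collapses to a cherry
  pair <- contrast_pair(c("y1", "y2"))
  col <- collapse_network(pair$N1)
  expect_equal(length(col$network$leaves), 2L)
  expect_equal(format(col$partition), "{a,b,c} {d,y1,y2}")
  expect_equal(sort(names(col$subnetworks)), c("a", "d"))
  expect_equal(taxa(col$subnetworks[["a"]]), c("a", "b", "c"))

  # over the exhaustive 4-taxon universe: simple or 2-leaf tree, and the
  # projected triplet system equals that of the collapsed network
  U <- get_universe(4)
  for (N in U$networks) {
    col <- collapse_network(N)
    cl <- classify_network(col$network)
    expect_true(cl$is_simple || length(col$network$leaves) == 2L)
    if (length(col$partition) >= 3L) {
      expect_setequal(unclass(collapsed_triplet_system(N)),
                      unclass(triplet_system(col$network)))
    }
  }
})
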