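test_that("tree triplet extraction is one triplet per 3-subset", {
  cat3 <- parse_enewick("(x1,(x2,x3));")
  expect_equal(as.character(tree_triplets(cat3)), "x2,x3|x1")

  bal <- parse_enewick("((a,b),(c,d));")
  expect_setequal(unclass(tree_triplets(bal)),
                  c("a,b|c", "a,b|d", "c,d|a", "c,d|b"))

  for (n in c(5L, 7L)) {
    tr <- random_level1(n, seed = n, gall_rate = 0)
    expect_equal(length(tree_triplets(tr)), choose(n, 3L))
  }
  expect_error(tree_triplets(simple3_network()), "tree")
})

test_that("path-based consistency matches the worked examples", {
  N <- simple5_sides22()
  expect_true(is_consistent(N, triplet("x1", "x2", "x3")))
  expect_false(is_consistent(N, triplet("x1", "x3", "x2")))

  trip <- parse_enewick("((a,b),c);")
  expect_true(is_consistent(trip, triplet("a", "b", "c")))
  expect_false(is_consistent(trip, triplet("a", "c", "b")))
  expect_error(is_consistent(trip, triplet("a", "b", "z")), "taxa")
})

test_that("both triplet extraction algorithms agree", {
  U3 <- get_universe(3)
  for (N in U3$networks) {
    expect_identical(unclass(triplet_system(N, "paths")),
                     unclass(triplet_system(N, "trees")))
  }
  for (s in 1:5) {
    N <- random_level1(8, seed = s, gall_rate = 0.5)
    expect_identical(unclass(triplet_system(N, "paths")),
                     unclass(triplet_system(N, "trees")))
  }
})

test_that("every 3-subset of a level-1 network carries at least one triplet", {
  for (s in 1:5) {
    N <- random_level1(7, seed = 10 + s, gall_rate = 0.5)
    R <- triplet_system(N)
    expect_gte(length(R), choose(7, 3))
    per_trio <- table(vapply(unclass(R), function(t) {
      paste(sort(parse_triplet(t)), collapse = ",")
    }, character(1)))
    expect_equal(length(per_trio), choose(7, 3))
  }
})

test_that("SN-sets: clusters below cut arcs are SN-sets; maximal ones equal Cut", {
  pair <- contrast_pair(c("y1", "y2"))
  R <- triplet_system(pair$N1)
  M <- maximal_sn_sets(R)
  expect_true(attr(M, "is_partition"))
  expect_equal(format(M), format(cut_partition(pair$N1)))

  # exhaustive cross-check of the two computations at n = 4
  U <- get_universe(4)
  for (N in U$networks) {
    expect_equal(format(maximal_sn_sets(triplet_system(N))),
                 format(cut_partition(N)))
  }

  # singletons and the full set are always SN-sets
  sets <- sn_sets(R)
  expect_true(all(c("a", "b", "c", "d") %in%
                    vapply(sets, paste, character(1), collapse = ",")))

  # empty system: every proper subset is an SN-set, the maximal non-trivial
  # ones are the (n-1)-subsets and they do not partition the taxa
  E <- l1net:::as_triplet_system(character(), c("p", "q", "r", "s"))
  expect_warning(ME <- maximal_sn_sets(E), "not induced")
  expect_false(attr(ME, "is_partition"))
  expect_equal(lengths(ME), rep(3L, 4L))
})

test_that("the defining triplet construction stays small and inside R(N)", {
  # base case: a simple 4-leaf network is defined by its full 7-triplet system
  S4 <- enumerate_simple(4)
  N4 <- S4$networks[[1L]]
  expect_identical(unclass(defining_triplets_simple(N4)),
                   unclass(triplet_system(N4)))
  expect_equal(length(triplet_system(N4)), 7L)

  for (N in list(simple5_sides22(), simple5_sides13())) {
    D <- defining_triplets_simple(N)
    expect_lte(length(D), 2L * 5L - 1L)
    expect_true(all(D %in% triplet_system(N)))
  }
  # size bound on all simple 6-leaf fixtures drawn at random
  S6 <- enumerate_simple(6)
  set.seed(2)
  for (i in sample(seq_along(S6$networks), 10)) {
    D <- defining_triplets_simple(S6$networks[[i]])
    expect_lte(length(D), 11L)
    expect_true(all(D %in% triplet_system(S6$networks[[i]])))
  }
  expect_error(defining_triplets_simple(parse_enewick("((a,b),c);")),
               "not simple")
})

test_that("definedness and minimal subsets behave on small universes", {
  U4 <- get_universe(4)
  N <- enumerate_simple(4)$networks[[1L]]
  res <- is_l1_defined_by_triplets(N, triplet_system(N), U4)
  expect_true(res$defined)

  # a tree is never defined within the full level-1 universe: some gall-
  # augmented network displays all its triplets
  T4 <- get_universe(4, "tree")$networks[[1L]]
  res_t <- is_l1_defined_by_triplets(T4, triplet_system(T4), U4)
  expect_false(res_t$defined)
  expect_gt(length(res_t$witnesses), 0L)

  # but it is defined within the tree universe by n - 2 triplets
  m <- min_defining_triplets(T4, get_universe(4, "tree"))
  expect_equal(m$size, 2L)

  # degenerate universe: the empty system suffices
  solo <- universe_subset(U4, is_simple)
  solo$networks <- solo$networks[1L]
  solo$enc <- solo$enc[1L]
  solo$flags <- solo$flags[1L, , drop = FALSE]
  solo$cache <- new.env()
  m0 <- min_defining_triplets(solo$networks[[1L]], solo)
  expect_equal(m0$size, 0L)

  expect_error(is_l1_defined_by_triplets(N, l1net:::as_triplet_system("x9,x8|x7", taxa(N)), U4),
               "not a subset")
})

test_that("triplet-count contrast pair reproduces the closed forms", {
  for (k in 2:3) {
    pair <- contrast_pair(paste0("y", seq_len(k)))
    n <- 4L + k
    c1 <- network_counts(pair$N1)
    c2 <- network_counts(pair$N2)
    expect_equal(c1$n_galls, 1L)
    expect_equal(c2$n_galls, 1L)
    expect_equal(c1$c_n, c2$c_n)
    expect_equal(c1$c_n, (k - 2L) + 3L)  # c_T + 3 for a caterpillar inner tree
    expect_equal(length(triplet_system(pair$N1)), choose(n, 3L) + 1L)
    expect_equal(length(triplet_system(pair$N2)), choose(n, 3L) + 1L + k)
  }
  # the counts do not depend on the inner tree's shape
  pb <- contrast_pair(paste0("y", 1:4), tree_shape = "balanced")
  expect_equal(length(triplet_system(pb$N2)) - length(triplet_system(pb$N1)), 4L)
})
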