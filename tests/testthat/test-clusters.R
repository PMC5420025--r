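test_that("hardwired clusters follow the closed forms", {
  tr <- random_level1(6, seed = 8, gall_rate = 0)
  expect_equal(length(hardwired_clusters(tr)), 2L * 6L - 1L)

  expect_setequal(unclass(hardwired_clusters(simple3_network())),
                  c("x1,x2,x3", "x1,x3", "x2,x3", "x1", "x2", "x3"))

  cherry <- parse_enewick("(x1,x2);")
  expect_setequal(unclass(hardwired_clusters(cherry)), c("x1,x2", "x1", "x2"))
})

test_that("softwired cluster sizes match the counting formula", {
  expect_equal(length(softwired_clusters(simple3_network(), drop_full = TRUE)), 5L)
  expect_equal(length(softwired_clusters(parse_enewick("((a,b),c);"),
                                         drop_full = TRUE)), 4L)

  # exhaustive at n = 4 (n = 5 runs in the acceptance suite) and random draws
  for (N in get_universe(4)$networks) {
    expect_equal(length(softwired_clusters(N, drop_full = TRUE)),
                 3L * 4L - 4L - network_counts(N)$c_n)
  }
  for (s in 1:10) {
    n <- sample(6:10, 1L)
    N <- random_level1(n, seed = 100 + s, gall_rate = 0.5)
    sw <- softwired_clusters(N, drop_full = TRUE)
    expect_equal(length(sw), 3L * n - 4L - network_counts(N)$c_n)
    expect_lte(length(sw) + 1L, 3L * n - 3L)  # |S(N)| grows linearly
  }

  # without hybrids the softwired system is the hardwired one
  tr <- random_level1(6, seed = 4, gall_rate = 0)
  expect_identical(unclass(softwired_clusters(tr)), unclass(hardwired_clusters(tr)))
})

test_that("cluster compatibility is the three-way intersection condition", {
  expect_true(clusters_compatible(c("1", "2"), c("3", "4")))
  expect_true(clusters_compatible(c("1", "2"), c("1", "2", "3")))
  expect_false(clusters_compatible(c("1", "2"), c("2", "3")))
  tr <- random_level1(6, seed = 5, gall_rate = 0)
  expect_true(is_compatible_system(hardwired_clusters(tr)))
  expect_false(is_compatible_system(softwired_clusters(simple3_network())))
})

test_that("cluster display and system restriction work", {
  N <- simple5_sides13()
  expect_true(displays_clusters(N, printed_clusters_11))
  expect_true(displays_clusters(N, hardwired_clusters(displayed_trees(N)[[1L]])))
  tr <- parse_enewick("((a,b),(c,d));")
  expect_false(displays_clusters(tr, "b,c"))

  S <- l1net:::as_cluster_system(c("a,b,c", "b,c", "a"), c("a", "b", "c"))
  expect_setequal(unclass(restrict_cluster_system(S, c("a", "c"))),
                  c("a,c", "c", "a"))
})

test_that("defining cluster systems follow the three case formulas", {
  # root adjacent to the hybrid (one empty side): n - 1 nested clusters
  case1 <- l1net:::shape_to_network(l1net:::shape_gall(
    lapply(c("x5", "x4", "x3", "x2"), l1net:::shape_leaf), list(),
    l1net:::shape_leaf("x1")))
  D1 <- defining_clusters_simple(case1)
  expect_setequal(unclass(D1),
                  c("x1,x2", "x1,x2,x3", "x1,x2,x3,x4", "x2,x3,x4,x5"))
  expect_true(all(D1 %in% softwired_clusters(case1)))

  # root one step from the hybrid: n clusters
  case2 <- l1net:::shape_to_network(l1net:::shape_gall(
    lapply(c("x4", "x3", "x2"), l1net:::shape_leaf),
    list(l1net:::shape_leaf("x5")),
    l1net:::shape_leaf("x1")))
  D2 <- defining_clusters_simple(case2)
  expect_equal(length(D2), 5L)
  expect_true(all(D2 %in% softwired_clusters(case2)))

  # root in the interior of the cycle: n clusters
  D3 <- defining_clusters_simple(simple5_sides22())
  expect_equal(length(D3), 5L)
  expect_true(all(D3 %in% softwired_clusters(simple5_sides22())))

  expect_error(defining_clusters_simple(parse_enewick("((a,b),c);")),
               "not simple")
})

test_that("cluster definedness distinguishes trees from saturated networks", {
  U4 <- get_universe(4)
  N <- enumerate_simple(4)$networks[[1L]]
  expect_true(is_l1_defined_by_clusters(N, softwired_clusters(N), U4)$defined)
  expect_true(is_l1_defined_by_clusters(N, defining_clusters_simple(N), U4)$defined)

  T4 <- get_universe(4, "tree")$networks[[1L]]
  res <- is_l1_defined_by_clusters(T4, hardwired_clusters(T4), U4)
  expect_false(res$defined)
})

test_that("softwired-system search finds exact matches", {
  U3 <- get_universe(3)
  hits <- find_networks_with_softwired(softwired_clusters(simple3_network()), U3)
  expect_gte(length(hits), 1L)
  expect_true(canonical_form(simple3_network()) %in%
                vapply(hits, canonical_form, character(1)))
})

test_that("a level-1 network realizing the 11-cluster example system exists", {
  S <- l1net:::as_cluster_system(printed_clusters_11, paste0("x", 1:5))
  hits <- find_networks_with_softwired(S, get_universe(5))
  expect_gte(length(hits), 1L)
  for (h in hits) {
    fl <- classify_network(h)
    expect_true(fl$is_4_outwards)
    expect_false(fl$is_saturated)
    expect_equal(network_counts(h)$c_n, 1L)   # |S^-| = 10 = 3n - 4 - c_N
    # its system is contained in that of the 1+3-sided simple network, giving
    # a cluster containment counterexample pair
    expect_true(displays_clusters(simple5_sides13(), softwired_clusters(h)))
    expect_false(canonical_form(h) == canonical_form(simple5_sides13()))
  }
})
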