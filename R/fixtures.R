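# Small worked-example networks used throughout the documentation and tests.

#' Worked-example networks
#'
#' * `simple3_network()`: the simple network on `{x1, x2, x3}` whose gall is a
#'   4-cycle with one leaf per side and hybrid leaf `x3`.
#' * `simple5_sides22()`: the simple network on `{x1..x5}` whose gall sides
#'   carry `x1, x2` and `x5, x4` (top to bottom) with hybrid leaf `x3`; its
#'   induced triplet system has exactly 16 elements.
#' * `simple5_sides13()`: the simple network on `{x1..x5}` with sides `x1` and
#'   `x2, x3, x4` (top to bottom) and hybrid leaf `x5`.
#'
#' @return an `l1net` network.
#' @export
simple3_network <- function() {
  shape_to_network(shape_gall(list(shape_leaf("x1")), list(shape_leaf("x2")),
                              shape_leaf("x3")), validate = TRUE)
}

#' @rdname simple3_network
#' @export
simple5_sides22 <- function() {
  shape_to_network(
    shape_gall(list(shape_leaf("x1"), shape_leaf("x2")),
               list(shape_leaf("x5"), shape_leaf("x4")),
               shape_leaf("x3")),
    validate = TRUE
  )
}

#' @rdname simple3_network
#' @export
simple5_sides13 <- function() {
  shape_to_network(
    shape_gall(list(shape_leaf("x1")),
               list(shape_leaf("x2"), shape_leaf("x3"), shape_leaf("x4")),
               shape_leaf("x5")),
    validate = TRUE
  )
}

caterpillar_shape <- function(tx) {
  if (length(tx) == 1L) return(shape_leaf(tx))
  shape_split(shape_leaf(tx[[1L]]), caterpillar_shape(tx[-1L]))
}

balanced_shape <- function(tx) {
  if (length(tx) == 1L) return(shape_leaf(tx))
  k <- ceiling(length(tx) / 2)
  shape_split(balanced_shape(tx[seq_len(k)]), balanced_shape(tx[-seq_len(k)]))
}

#' A pair of networks with equal gall and cut-arc counts but different
#' triplet-system sizes
#'
#' Both networks live on `{a, b, c, d}` together with `inner`, contain one
#' gall and have `c_T + 3` non-trivial cut arcs (`c_T` those of the inner
#' tree), yet the first induces `choose(n,3) + 1` triplets and the second
#' `choose(n,3) + 1 + length(inner)`: the size of an induced triplet system is
#' not a function of the gall and cut-arc counts.
#'
#' The first network roots a gall on `{a, b, c}` (hybrid leaf `b`) beside the
#' tree `(d, T(inner))`; the second roots the leaf `d` beside a gall with
#' side leaves `a` and `c` whose hybrid vertex carries `(b, T(inner))`.
#'
#' @param inner at least two taxon names, disjoint from `a, b, c, d`.
#' @param tree_shape shape of the inner tree `T` (the triplet counts do not
#'   depend on it).
#' @return list of two `l1net` networks `N1`, `N2`.
#' @export
contrast_pair <- function(inner = c("y1", "y2"),
                          tree_shape = c("caterpillar", "balanced")) {
  tree_shape <- match.arg(tree_shape)
  if (length(inner) < 2L) stop("`inner` needs at least two taxa")
  if (any(inner %in% c("a", "b", "c", "d"))) {
    stop("`inner` must be disjoint from {a, b, c, d}")
  }
  tsh <- switch(tree_shape, caterpillar = caterpillar_shape(inner),
                balanced = balanced_shape(inner))
  n1 <- shape_split(
    shape_gall(list(shape_leaf("a")), list(shape_leaf("c")), shape_leaf("b")),
    shape_split(shape_leaf("d"), tsh)
  )
  n2 <- shape_split(
    shape_leaf("d"),
    shape_gall(list(shape_leaf("a")), list(shape_leaf("c")),
               shape_split(shape_leaf("b"), tsh))
  )
  list(N1 = shape_to_network(n1, validate = TRUE),
       N2 = shape_to_network(n2, validate = TRUE))
}
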