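#' Canonical form of a network
#'
#' A text encoding such that two networks on the same taxon set are equivalent
#' (related by a graph isomorphism fixing the leaf labels) if and only if
#' their encodings are equal.  Tree vertices sort their child encodings
#' lexicographically; a gall is encoded as the lexicographic minimum over its
#' two side orientations, reflection being the only symmetry a gall of a
#' binary level-1 network admits.
#'
#' @param N an `l1net` network.
#' @return a character scalar.
#' @export
canonical_form <- function(N) {
  if (is_degenerate(N)) return(leaf_code(unname(N$leaves)))
  canonical_encoder(N)$enc(N$root)
}

# Shared recursive encoder; also used by write_enewick() to order children and
# orient galls deterministically.
canonical_encoder <- function(N) {
  gall_of_root <- list()
  for (g in galls(N)) gall_of_root[[g$root]] <- g
  memo <- new.env(parent = emptyenv())
  enc <- function(v) {
    hit <- memo[[v]]
    if (!is.null(hit)) return(hit)
    tax <- N$leaves[names(N$leaves) == v]
    res <- if (length(tax)) {
      leaf_code(unname(tax))
    } else if (!is.null(gall_of_root[[v]])) {
      encode_gall(N, gall_of_root[[v]], enc)
    } else {
      kids <- sort(vapply(out_children(N, v), enc, character(1)))
      paste0("(", paste(kids, collapse = ","), ")")
    }
    memo[[v]] <- res
    res
  }
  list(enc = enc, gall_of_root = gall_of_root)
}

leaf_code <- function(taxon) paste0("<", taxon, ">")

# off-cycle child of a cycle vertex
off_cycle_child <- function(N, v, cycle) {
  setdiff(out_children(N, v), cycle)
}

encode_gall <- function(N, g, enc) {
  side_enc <- function(side) {
    vapply(side, function(u) enc(off_cycle_child(N, u, g$cycle)), character(1))
  }
  s1 <- side_enc(g$side1)
  s2 <- side_enc(g$side2)
  h <- enc(out_children(N, g$hybrid))
  cand <- c(
    paste0("[", paste(s1, collapse = ","), "|", paste(s2, collapse = ","), "|", h, "]"),
    paste0("[", paste(s2, collapse = ","), "|", paste(s1, collapse = ","), "|", h, "]")
  )
  min(cand)
}

#' Equivalence of two networks
#'
#' Two networks on the same taxon set are equivalent when some graph
#' isomorphism between them is the identity on the taxa.
#'
#' @param N,M `l1net` networks on the same taxa.
#' @return logical.
#' @export
are_equivalent <- function(N, M) {
  if (!setequal(taxa(N), taxa(M))) {
    stop("networks have different leaf sets and are not comparable")
  }
  canonical_form(N) == canonical_form(M)
}
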