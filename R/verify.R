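# Verification drivers: run the counting formulas and the uniqueness results
# over an (exhaustive or random) universe and report every failure.  On taxon
# sets with at most 5 taxa the triplet and cluster systems fit into 32-bit
# masks, which makes the all-pairs containment scans cheap.

system_masks <- function(systems, dictionary) {
  if (length(dictionary) > 31L) return(NULL)
  bits <- as.integer(2^(seq_along(dictionary) - 1L))
  vapply(systems, function(s) {
    idx <- match(s, dictionary)
    stopifnot(!anyNA(idx))
    Reduce(bitwOr, bits[idx], 0L)
  }, integer(1))
}

all_cluster_strings <- function(taxa) {
  n <- length(taxa)
  out <- character()
  for (k in seq_len(n)) {
    out <- c(out, apply(combn(sort(taxa), k), 2L, paste, collapse = ","))
  }
  out
}

# indices of universe members whose system contains the system of index i
# (or the explicit set `sys`)
containing_members <- function(masks, systems, i = NULL, sys = NULL) {
  if (!is.null(masks)) {
    m <- if (is.null(sys)) masks[[i]] else sys
    return(which(bitwAnd(m, masks) == m))
  }
  s <- if (is.null(sys)) systems[[i]] else sys
  which(vapply(systems, function(o) all(s %in% o), logical(1)))
}

new_report <- function(id, n_checked, failures, details = list()) {
  structure(list(id = id, n_checked = n_checked, failures = failures,
                 details = details),
            class = "l1_report")
}

#' @export
print.l1_report <- function(x, ...) {
  cat(sprintf("<verification: %s> %d instance(s) checked, %d failure(s)\n",
              x$id, x$n_checked, length(x$failures)))
  for (f in head(x$failures, 10L)) cat("  FAIL:", f, "\n")
  if (length(x$details)) {
    for (nm in names(x$details)) {
      cat(sprintf("  %s: %s\n", nm, paste(x$details[[nm]], collapse = " ")))
    }
  }
  invisible(x)
}

#' Verify the vertex/arc/gall/cluster counting formulas over a universe
#'
#' For every member, checks (as applicable): the vertex and arc bounds
#' `2n+1 <= |V| <= 3n-2` and `2n+1 <= |A| <= 3.5(n-1)` for proper networks,
#' `|V| = |A| = 2n+1` for simple networks, the gall bound
#' `g(N) <= n - c_N - 2` with equality for trees and for networks all of whose
#' galls have exactly three outgoing arcs, and the softwired-cluster size
#' formula `|S(N)^-| = 3n - 4 - c_N`.
#'
#' @param universe an `l1_universe` (or plain list of `l1net` networks).
#' @return an `l1_report`; `failures` is empty when every formula holds.
#' @export
verify_counting <- function(universe) {
  networks <- if (inherits(universe, "l1_universe")) universe$networks else universe
  failures <- character()
  checked <- 0L
  for (N in networks) {
    checked <- checked + 1L
    cnt <- network_counts(N)
    n <- cnt$n
    gs <- galls(N)
    id <- function() write_enewick(N)
    if (cnt$n_galls >= 1L) {
      if (!(2 * n + 1 <= cnt$n_vertices && cnt$n_vertices <= 3 * n - 2)) {
        failures <- c(failures, paste("vertex bounds:", id()))
      }
      if (!(2 * n + 1 <= cnt$n_arcs && cnt$n_arcs <= 3.5 * (n - 1))) {
        failures <- c(failures, paste("arc bounds:", id()))
      }
    }
    if (classify_network(N)$is_simple &&
        !(cnt$n_vertices == 2 * n + 1 && cnt$n_arcs == 2 * n + 1)) {
      failures <- c(failures, paste("simple |V|=|A|=2n+1:", id()))
    }
    if (cnt$n_galls > n - cnt$c_n - 2) {
      failures <- c(failures, paste("gall bound:", id()))
    }
    three_out <- length(gs) > 0L &&
      all(vapply(gs, function(g) nrow(g$outgoing), integer(1)) == 3L)
    if ((cnt$n_galls == 0L || three_out) &&
        cnt$n_galls != n - cnt$c_n - 2) {
      failures <- c(failures, paste("gall bound tightness:", id()))
    }
    sw <- softwired_clusters(N, drop_full = TRUE)
    if (length(sw) != 3 * n - 4 - cnt$c_n) {
      failures <- c(failures, paste("softwired size formula:", id()))
    }
  }
  new_report("counting", checked, failures)
}

#' Verify the uniqueness (definedness) results over an exhaustive universe
#'
#' Over all members of an exhaustive universe this checks that
#' * every saturated, 4-outwards member is uniquely determined by its full
#'   induced triplet system and by its full softwired cluster system;
#' * for every saturated member N and every member N' whose triplet system
#'   contains that of N, the Cut partitions agree;
#' * across every containment pair, all pairs of clusters below non-trivial
#'   cut arcs are compatible.
#' It also records whether some non-saturated 4-outwards member fails
#' triplet-definedness and some member fails cluster-definedness (both are
#' expected from 5 taxa on).
#'
#' @param universe an exhaustive `l1_universe` (filter `"all"`).
#' @return an `l1_report`; `details` carries the existence records.
#' @export
verify_definedness <- function(universe) {
  stopifnot(inherits(universe, "l1_universe"))
  enc <- universe$enc
  flags <- universe$flags
  nets <- universe$networks
  R <- universe_systems(universe, "triplets")
  S <- universe_systems(universe, "clusters")
  mR <- system_masks(R, all_triplets(universe$taxa))
  mS <- system_masks(S, all_cluster_strings(universe$taxa))
  failures <- character()

  sat4 <- which(flags$is_saturated & flags$is_4_outwards)
  trip_defined <- function(i) {
    sup <- containing_members(mR, R, i)
    all(enc[sup] == enc[[i]])
  }
  clus_defined <- function(i) {
    sup <- containing_members(mS, S, i)
    all(enc[sup] == enc[[i]])
  }
  for (i in sat4) {
    if (!trip_defined(i)) {
      failures <- c(failures,
                    paste("saturated 4-outwards member not triplet-defined:",
                          write_enewick(nets[[i]])))
    }
    if (!clus_defined(i)) {
      failures <- c(failures,
                    paste("saturated 4-outwards member not cluster-defined:",
                          write_enewick(nets[[i]])))
    }
  }

  # Cut preservation under triplet containment for saturated networks
  parts <- vapply(nets, function(N) format(cut_partition(N)), character(1))
  for (i in which(flags$is_saturated)) {
    for (j in containing_members(mR, R, i)) {
      if (parts[[j]] != parts[[i]]) {
        failures <- c(failures,
                      paste("Cut partition not preserved:",
                            write_enewick(nets[[i]]), "->",
                            write_enewick(nets[[j]])))
      }
    }
  }

  # compatibility of cut-arc clusters across every triplet containment pair
  head_clusters <- lapply(nets, function(N) {
    heads <- cut_arcs(N)$nontrivial[, 2L]
    lapply(heads, function(v) cluster_below(N, v))
  })
  n_pairs <- 0L
  for (i in seq_along(nets)) {
    ci <- head_clusters[[i]]
    if (length(ci) == 0L) next
    for (j in containing_members(mR, R, i)) {
      cj <- head_clusters[[j]]
      if (length(cj) == 0L) next
      n_pairs <- n_pairs + 1L
      for (A in ci) for (B in cj) {
        if (!clusters_compatible(A, B)) {
          failures <- c(failures,
                        paste("incompatible cut-arc clusters:",
                              write_enewick(nets[[i]]), "vs",
                              write_enewick(nets[[j]])))
        }
      }
    }
  }

  not4sat <- which(flags$is_4_outwards & !flags$is_saturated & flags$is_proper)
  exists_trip_undef <- any(!vapply(not4sat, trip_defined, logical(1)))
  exists_clus_undef <- any(!vapply(seq_along(nets), clus_defined, logical(1)))

  new_report("definedness",
             length(sat4) + sum(flags$is_saturated) + n_pairs,
             failures,
             details = list(
               n_saturated_4_outwards = length(sat4),
               exists_nonsaturated_triplet_undefined = exists_trip_undef,
               exists_cluster_undefined = exists_clus_undef
             ))
}

#' Search for containment counterexamples to uniqueness
#'
#' Finds every ordered pair (N', N) of non-equivalent universe members, both
#' 4-outwards (optionally also saturated), such that the triplet (or
#' softwired cluster) system of N' is contained in that of N.  Non-empty
#' results demonstrate that 4-outwards alone does not guarantee that a network
#' is uniquely determined by the system it induces.
#'
#' @param universe an exhaustive `l1_universe`.
#' @param mode `"triplet"` or `"cluster"` containment.
#' @param require_saturated also restrict both members to saturated networks
#'   (then the result is expected to be empty).
#' @return data frame with columns `contained` and `container` (extended
#'   Newick) plus the member indices.
#' @export
search_containment_counterexamples <- function(universe,
                                               mode = c("triplet", "cluster"),
                                               require_saturated = FALSE) {
  mode <- match.arg(mode)
  flags <- universe$flags
  keep <- flags$is_4_outwards
  if (require_saturated) keep <- keep & flags$is_saturated
  idx <- which(keep)
  systems <- universe_systems(universe,
                              if (mode == "triplet") "triplets" else "clusters")
  dict <- if (mode == "triplet") all_triplets(universe$taxa)
          else all_cluster_strings(universe$taxa)
  masks <- system_masks(systems, dict)
  enc <- universe$enc
  out_i <- integer(); out_j <- integer()
  sub_masks <- if (!is.null(masks)) masks[idx] else NULL
  for (a in seq_along(idx)) {
    i <- idx[[a]]
    sup <- if (!is.null(masks)) {
      idx[bitwAnd(masks[[i]], sub_masks) == masks[[i]]]
    } else {
      idx[vapply(systems[idx], function(o) all(systems[[i]] %in% o), logical(1))]
    }
    sup <- sup[enc[sup] != enc[[i]]]
    out_i <- c(out_i, rep(i, length(sup)))
    out_j <- c(out_j, sup)
  }
  data.frame(
    contained_index = out_i,
    container_index = out_j,
    contained = vapply(universe$networks[out_i], write_enewick, character(1)),
    container = vapply(universe$networks[out_j], write_enewick, character(1)),
    stringsAsFactors = FALSE
  )
}
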