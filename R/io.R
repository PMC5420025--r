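#' Read and write triplet/cluster systems as TSV
#'
#' Triplet files carry one triplet per line in the form `a b | c`; cluster
#' files one cluster per line as comma-separated taxa `a,b,c`.  Reading
#' deduplicates (systems are sets); writing is deterministic (lexicographic
#' order), so write-then-read round-trips losslessly.
#'
#' @param path file path.
#' @param kind `"triplets"` or `"clusters"`.
#' @return [read_system()]: an `l1_triplets` or `l1_clusters` object.
#' @export
read_system <- function(path, kind = c("triplets", "clusters")) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  lines <- trimws(lines)
  keep <- lines != ""
  lines <- lines[keep]
  lineno <- which(keep)
  if (kind == "triplets") {
    trips <- vapply(seq_along(lines), function(i) {
      parts <- strsplit(lines[[i]], "|", fixed = TRUE)[[1L]]
      lhs <- strsplit(trimws(parts[[1L]]), "[ ,]+")[[1L]]
      rhs <- if (length(parts) == 2L) strsplit(trimws(parts[[2L]]), "[ ,]+")[[1L]] else character()
      if (length(parts) != 2L || length(lhs) != 2L || length(rhs) != 1L) {
        stop(sprintf("%s:%d: malformed triplet line: %s",
                     path, lineno[[i]], lines[[i]]))
      }
      triplet(lhs[[1L]], lhs[[2L]], rhs)
    }, character(1))
    tx <- unique(unlist(lapply(trips, parse_triplet)))
    as_triplet_system(trips, tx)
  } else {
    cl <- vapply(seq_along(lines), function(i) {
      members <- strsplit(lines[[i]], ",", fixed = TRUE)[[1L]]
      members <- trimws(members)
      if (any(members == "")) {
        stop(sprintf("%s:%d: malformed cluster line: %s",
                     path, lineno[[i]], lines[[i]]))
      }
      cluster_str(members)
    }, character(1))
    as_cluster_system(cl, unique(unlist(lapply(cl, parse_cluster))))
  }
}

#' @rdname read_system
#' @param x an `l1_triplets` or `l1_clusters` system.
#' @export
write_system <- function(x, path) {
  lines <- if (inherits(x, "l1_triplets")) {
    vapply(sort(unclass(x)), function(t) {
      p <- parse_triplet(t)
      paste(p[[1L]], p[[2L]], "|", p[[3L]])
    }, character(1))
  } else if (inherits(x, "l1_clusters")) {
    sort(unclass(x))
  } else {
    stop("`x` must be an l1_triplets or l1_clusters system")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read and write a network as a JSON edge list
#'
#' The dialect is `{"arcs": [[tail, head], ...], "leaves": {vertex: taxon}}`.
#'
#' @param path file path.
#' @return [read_network_json()]: an `l1net` network.
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$arcs) || is.null(obj$leaves)) {
    stop("JSON network needs `arcs` and `leaves` fields")
  }
  leaves <- unlist(obj$leaves)
  if (length(obj$arcs) == 0L) {
    stopifnot(length(leaves) == 1L)
    return(leaf_network(unname(leaves), names(leaves)))
  }
  build_network(as_arc_matrix(obj$arcs), leaves)
}

#' @rdname read_network_json
#' @param N an `l1net` network.
#' @export
write_network_json <- function(N, path) {
  arcs <- N$arcs
  jsonlite::write_json(
    list(arcs = if (nrow(arcs)) unname(apply(arcs, 1L, as.list, simplify = FALSE)) else list(),
         leaves = as.list(N$leaves)),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
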