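#' Serialize a network as extended Newick
#'
#' Hybrid vertices are written once with their subtree as `(subtree)#Hk` and
#' referenced as a bare `#Hk` from their other parent.  The serialization is
#' canonical: children are ordered by their canonical encodings and each gall
#' is oriented as in [canonical_form()], so equivalent networks serialize to
#' the same string.
#'
#' @param N an `l1net` network.
#' @return an extended Newick string terminated by ";".
#' @export
write_enewick <- function(N) {
  if (is_degenerate(N)) return(paste0(unname(N$leaves), ";"))
  coder <- canonical_encoder(N)
  tag_count <- 0L
  wr <- function(v) {
    tax <- N$leaves[names(N$leaves) == v]
    if (length(tax)) return(unname(tax))
    g <- coder$gall_of_root[[v]]
    if (!is.null(g)) return(wr_gall(g))
    kids <- out_children(N, v)
    kids <- kids[order(vapply(kids, coder$enc, character(1)))]
    paste0("(", wr(kids[[1L]]), ",", wr(kids[[2L]]), ")")
  }
  wr_gall <- function(g) {
    side_enc <- function(side) {
      vapply(side, function(u) coder$enc(off_cycle_child(N, u, g$cycle)),
             character(1))
    }
    s1 <- side_enc(g$side1)
    s2 <- side_enc(g$side2)
    h <- coder$enc(out_children(N, g$hybrid))
    cand1 <- paste0("[", paste(s1, collapse = ","), "|",
                    paste(s2, collapse = ","), "|", h, "]")
    cand2 <- paste0("[", paste(s2, collapse = ","), "|",
                    paste(s1, collapse = ","), "|", h, "]")
    first <- if (cand2 < cand1) g$side2 else g$side1
    second <- if (cand2 < cand1) g$side1 else g$side2
    tag_count <<- tag_count + 1L
    tag <- paste0("#H", tag_count)
    full <- paste0("(", wr(out_children(N, g$hybrid)), ")", tag)
    chain <- function(side, terminal) {
      cur <- terminal
      for (u in rev(side)) {
        cur <- paste0("(", wr(off_cycle_child(N, u, g$cycle)), ",", cur, ")")
      }
      cur
    }
    paste0("(", chain(first, full), ",", chain(second, tag), ")")
  }
  paste0(wr(N$root), ";")
}

#' Parse an extended Newick string into a network
#'
#' Accepts plain Newick (trees) and the hybrid-tag dialect in which a hybrid
#' vertex occurs once as `(subtree)#Hk` and once as a bare `#Hk`.  Internal
#' vertex names are ignored.  The parsed graph must pass the level-1 network
#' validation of [build_network()].
#'
#' @param text an extended Newick string (a terminating ";" is optional).
#' @return an `l1net` network.
#' @export
parse_enewick <- function(text) {
  s <- gsub("[[:space:]]", "", text)
  s <- sub(";$", "", s)
  if (nchar(s) == 0L) stop("empty eNewick string")
  chars <- strsplit(s, "")[[1L]]
  pos <- 1L
  peek <- function() if (pos <= length(chars)) chars[[pos]] else ""
  advance <- function() pos <<- pos + 1L
  fail <- function(msg) stop(sprintf("eNewick syntax error at position %d: %s", pos, msg))

  nodes <- list()      # per node: name, tag
  arcs <- matrix(character(), ncol = 2L)
  new_node <- function(name, tag) {
    id <- paste0("p", length(nodes) + 1L)
    nodes[[id]] <<- list(name = name, tag = tag)
    id
  }
  read_token <- function() {
    start <- pos
    while (pos <= length(chars) && !chars[[pos]] %in% c("(", ")", ",", "#", ";")) {
      advance()
    }
    paste(chars[seq2(start, pos - 1L)], collapse = "")
  }
  read_tag <- function() {
    if (peek() != "#") return(NA_character_)
    advance()
    tag <- read_token()
    if (tag == "") fail("empty hybrid tag after '#'")
    tag
  }
  parse_subtree <- function() {
    if (peek() == "(") {
      advance()
      kids <- parse_subtree()
      while (peek() == ",") {
        advance()
        kids <- c(kids, parse_subtree())
      }
      if (peek() != ")") fail("expected ')' or ','")
      advance()
      name <- read_token()          # internal label, ignored
      tag <- read_tag()
      id <- new_node("", tag)
      for (k in kids) arcs <<- rbind(arcs, c(id, k))
      id
    } else {
      name <- read_token()
      tag <- read_tag()
      if (name == "" && is.na(tag)) fail("expected a taxon, '(' or '#H' tag")
      if (name != "" && !is.na(tag)) {
        fail("a tagged leaf must be written as (taxon)#Hk")
      }
      new_node(name, tag)
    }
  }
  root <- parse_subtree()
  if (pos <= length(chars)) fail("trailing characters after the outermost group")

  # merge hybrid-tag occurrences into single vertices
  tags <- vapply(nodes, function(n) n$tag, character(1))
  for (tag in unique(tags[!is.na(tags)])) {
    ids <- names(nodes)[!is.na(tags) & tags == tag]
    if (length(ids) < 2L) {
      stop(sprintf("hybrid tag #%s occurs only once", tag))
    }
    keep <- ids[[1L]]
    arcs[arcs %in% ids] <- keep
  }
  sinks <- setdiff(c(root, c(arcs)), arcs[, 1L])
  if (nrow(arcs) == 0L) {
    nm <- nodes[[root]]$name
    if (nm == "") stop("single vertex carries no taxon name")
    return(leaf_network(nm, root))
  }
  leaf_labels <- vapply(sinks, function(v) nodes[[v]]$name, character(1))
  if (any(leaf_labels == "")) {
    stop("hybrid tag(s) never defined with a subtree: sink without taxon name")
  }
  build_network(arcs, setNames(leaf_labels, sinks))
}

seq2 <- function(from, to) if (from > to) integer() else seq.int(from, to)
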