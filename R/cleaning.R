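# Graph cleaning: colour propagation to unmapped reads, removal of reads
# whose propagated colours conflict, deletion of colour-inconsistent edges,
# and minimal topology-only simplification (transitive reduction and tip
# removal).

#' Propagate colours to uncoloured reads through the overlap graph
#'
#' For each uncoloured read, a breadth-first search walks edges in both
#' directions through uncoloured reads only, up to `depth_limit` edges; the
#' read receives the union of the colour sets of all mapping-coloured reads
#' first reached.  The pass is simultaneous: only the original
#' mapping-derived colouring seeds the search, so reads that were
#' uncoloured before the call never seed each other, running the operation
#' twice changes nothing, and both orientations of a read receive the same
#' set.  Reads that gained colours this way are recorded in the graph's
#' `propagated` field (conflict removal acts on those only).
#'
#' @param graph A `coloured_overlap_graph`.
#' @param depth_limit Maximum BFS depth in edges (default 10).
#' @return The graph with propagated colours.
#' @export
propagate_colours <- function(graph, depth_limit = 10) {
  stopifnot(inherits(graph, "coloured_overlap_graph"), depth_limit >= 1)
  nc <- lengths(graph$colours)
  # pass-through set: reads without mapping-derived colours
  passthrough <- union(names(nc)[nc == 0L], graph$propagated)
  targets <- passthrough
  if (length(targets) == 0L) return(graph)

  e <- graph$edges
  nbr <- list()
  if (nrow(e) > 0L) {
    pairs <- unique(data.frame(a = c(e$from_id, e$to_id), b = c(e$to_id, e$from_id),
                               stringsAsFactors = FALSE))
    nbr <- split(pairs$b, pairs$a)
  }
  is_pass <- stats::setNames(graph$reads$read_id %in% passthrough, graph$reads$read_id)

  new_sets <- list()
  for (u in targets) {
    frontier <- u
    visited <- u
    absorbed <- character(0)
    depth <- 0L
    while (length(frontier) > 0L && depth < depth_limit) {
      nxt <- unique(unlist(nbr[frontier], use.names = FALSE))
      nxt <- setdiff(nxt, visited)
      visited <- c(visited, nxt)
      absorbed <- c(absorbed, nxt[!is_pass[nxt]])
      frontier <- nxt[is_pass[nxt]]
      depth <- depth + 1L
    }
    if (length(absorbed) > 0L) {
      new_sets[[u]] <- sort(unique(unlist(graph$colours[absorbed], use.names = FALSE)))
    }
  }
  if (length(new_sets) > 0L) {
    graph$colours[names(new_sets)] <- new_sets
  }
  # reads that were targets but received nothing revert to uncoloured
  got_nothing <- setdiff(targets, names(new_sets))
  graph$colours[got_nothing] <- rep(list(numeric(0)), length(got_nothing))
  graph$propagated <- sort(names(new_sets))
  graph
}

# A colour set conflicts when it spans several chromosomes, or when two or
# more consecutive bin ordinals are absent between its minimum and maximum
# on one chromosome (a single missing ordinal is within the adjacency slack
# of noisy maps).
colour_set_conflicts <- function(cols) {
  if (length(cols) < 2L) return(FALSE)
  if (length(unique(colour_chrom(cols))) > 1L) return(TRUE)
  o <- sort(unique(colour_ordinal(cols)))
  any(diff(o) >= 3)
}

#' Remove reads whose propagated colours conflict
#'
#' A propagated colour set that skips two or more bins between its extremes
#' (or spans several chromosomes) means the search jumped over part of the
#' genome; such a colouring cannot clean the graph usefully, so the read is
#' removed entirely, with both orientations and all incident edges.  Only
#' reads coloured by [propagate_colours()] are examined; mapping-derived
#' colourings are left alone.
#'
#' @param graph A `coloured_overlap_graph` after propagation.
#' @return The graph without conflicting reads; the number removed is in
#'   the `conflicts_removed` attribute.
#' @export
drop_conflicting_vertices <- function(graph) {
  stopifnot(inherits(graph, "coloured_overlap_graph"))
  bad <- graph$propagated[vapply(graph$colours[graph$propagated],
                                 colour_set_conflicts, logical(1))]
  graph <- drop_reads(graph, bad)
  attr(graph, "conflicts_removed") <- length(bad)
  graph
}

#' Remove inconsistently coloured edges
#'
#' An edge is inconsistently coloured when both endpoint reads carry
#' colours but no colour of one is within distance `d` of a colour of the
#' other (colours on different chromosomes are never within any distance).
#' All such edges are deleted together with their mirrors.  Edges touching
#' an uncoloured endpoint are kept: the inconsistency definition
#' quantifies over existing colours, and deleting every edge of an
#' unmapped read would defeat propagation.
#'
#' @param graph A `coloured_overlap_graph`.
#' @param d Colour distance (default 1).
#' @return List with elements `graph` (the cleaned graph) and `report`
#'   (data.frame: per-chromosome and total counts of removed links).
#' @export
remove_inconsistent_edges <- function(graph, d = 1) {
  stopifnot(inherits(graph, "coloured_overlap_graph"), d >= 0)
  e <- graph$edges
  if (nrow(e) == 0L) {
    return(list(graph = graph,
                report = data.frame(chromosome = character(0), links_removed = integer(0))))
  }
  cons <- edge_consistency(graph, d)
  removed <- e[!cons, , drop = FALSE]
  graph$edges <- e[cons, , drop = FALSE]

  report <- data.frame(chromosome = character(0), links_removed = integer(0),
                       stringsAsFactors = FALSE)
  if (nrow(removed) > 0L) {
    pair_first <- removed$from_id < removed$to_id |
      (removed$from_id == removed$to_id & removed$from_strand == "+")
    links <- removed[!duplicated(paste(pmin(removed$from_id, removed$to_id),
                                       pmax(removed$from_id, removed$to_id))), , drop = FALSE]
    lab <- vapply(seq_len(nrow(links)), function(i) {
      ch <- unique(colour_chrom(c(graph$colours[[links$from_id[i]]],
                                  graph$colours[[links$to_id[i]]])))
      paste(sort(ch), collapse = "|")
    }, "")
    tab <- table(lab)
    report <- data.frame(chromosome = names(tab), links_removed = as.integer(tab),
                         stringsAsFactors = FALSE)
    pair_first <- NULL
  }
  report <- rbind(report,
                  data.frame(chromosome = "total",
                             links_removed = nrow(removed) %/% 2L,
                             stringsAsFactors = FALSE))
  list(graph = graph, report = report)
}

# Plain (not colour-aware) degree of every vertex.
degree_table <- function(edges, vertices) {
  out <- stats::setNames(rep(0L, length(vertices)), vertices)
  inn <- out
  if (nrow(edges) > 0L) {
    tf <- table(vertex_key(edges$from_id, edges$from_strand))
    tt <- table(vertex_key(edges$to_id, edges$to_strand))
    out[names(tf)] <- as.integer(tf)
    inn[names(tt)] <- as.integer(tt)
  }
  list(outdeg = out, indeg = inn)
}

#' Topology-only graph simplification
#'
#' Standard overlap-graph plumbing: first transitive edges are reduced --
#' an edge (u, w) is removed when edges (u, v) and (v, w) exist and the
#' overlap implied by the two-hop path matches the direct overlap within
#' `fuzz` bp -- then short dead-end side branches (tips of at most
#' `max_tip` reads that merge into another path) are removed.  Mirror
#' symmetry is preserved throughout.  Transitive reduction needs read
#' lengths; reads with unknown length are left untouched.
#'
#' @param graph A `coloured_overlap_graph`.
#' @param fuzz Overlap-length slack in bp for transitive reduction
#'   (default 1000).
#' @param max_tip Maximum number of reads in a removable tip (default 4).
#' @return The simplified graph; counts are stored in the
#'   `simplify_stats` attribute (`transitive_links_removed`,
#'   `tip_reads_removed`).
#' @export
simplify_graph <- function(graph, fuzz = 1000, max_tip = 4) {
  stopifnot(inherits(graph, "coloured_overlap_graph"))
  e <- data.table::as.data.table(graph$edges)
  n_trans <- 0L
  if (nrow(e) > 0L) {
    len <- stats::setNames(graph$reads$length, graph$reads$read_id)
    e[, from := vertex_key(from_id, from_strand)]
    e[, to := vertex_key(to_id, to_strand)]
    e[, eid := .I]
    hop1 <- e[, list(u = from, v = to, o1 = overlap_len)]
    hop2 <- e[, list(v = from, w = to, o2 = overlap_len, lenv = len[from_id])]
    two <- merge(hop1, hop2, by = "v", allow.cartesian = TRUE)
    two <- two[u != w & !is.na(lenv)]
    if (nrow(two) > 0L) {
      two[, implied := o1 + o2 - lenv]
      direct <- e[, list(u = from, w = to, od = overlap_len, eid = eid)]
      hit <- merge(direct, two, by = c("u", "w"), allow.cartesian = TRUE)
      hit <- hit[abs(od - implied) <= fuzz]
      drop_ids <- unique(hit$eid)
      if (length(drop_ids) > 0L) {
        dropped <- e[drop_ids]
        # close the removal set under mirroring
        mkey <- paste(dropped$to_id, flip_strand(dropped$to_strand),
                      dropped$from_id, flip_strand(dropped$from_strand))
        ekey <- paste(e$from_id, e$from_strand, e$to_id, e$to_strand)
        drop_ids <- union(drop_ids, which(ekey %in% mkey))
        n_trans <- length(drop_ids) %/% 2L
        e <- e[-drop_ids]
      }
    }
    graph$edges <- as.data.frame(e[, list(from_id, from_strand, to_id, to_strand,
                                          overlap_len)])
  }

  # tip removal: short unambiguous paths from a source that merge into a
  # vertex with other incoming edges
  verts <- c(vertex_key(graph$reads$read_id, "+"), vertex_key(graph$reads$read_id, "-"))
  deg <- degree_table(graph$edges, verts)
  succ <- split(vertex_key(graph$edges$to_id, graph$edges$to_strand),
                vertex_key(graph$edges$from_id, graph$edges$from_strand))
  tip_reads <- character(0)
  sources <- verts[deg$indeg[verts] == 0L & deg$outdeg[verts] > 0L]
  for (s in sources) {
    path <- character(0)
    v <- s
    repeat {
      if (deg$outdeg[v] != 1L) break
      path <- c(path, v)
      if (length(path) > max_tip) { path <- character(0); break }
      w <- succ[[v]]
      if (deg$indeg[w] >= 2L) {
        tip_reads <- c(tip_reads, substr(path, 1L, nchar(path) - 1L))
        path <- character(0)
        break
      }
      if (deg$outdeg[w] != 1L) { path <- character(0); break }
      v <- w
    }
  }
  tip_reads <- unique(tip_reads)
  graph <- drop_reads(graph, tip_reads)
  attr(graph, "simplify_stats") <- list(transitive_links_removed = n_trans,
                                        tip_reads_removed = length(tip_reads))
  graph
}

#' Run the full cleaning pipeline
#'
#' Propagates colours (depth-limited BFS), removes propagated reads with
#' conflicting colours, deletes colour-inconsistent edges at distance `d`,
#' and optionally applies topology-only simplification (transitive
#' reduction, then tip removal).
#'
#' @param graph A coloured `coloured_overlap_graph`.
#' @param d Colour distance for inconsistency (default 1).
#' @param depth_limit Propagation depth limit (default 10).
#' @param simplify Run [simplify_graph()] afterwards? (default TRUE)
#' @param fuzz,max_tip Passed to [simplify_graph()].
#' @return List with elements `graph` and `report`.  The report is a
#'   one-row data.frame with counts of reads propagated, reads removed for
#'   colour conflicts, inconsistent links removed, transitive links
#'   removed, and tip reads removed, plus `per_chromosome`, the breakdown
#'   from [remove_inconsistent_edges()], as an attribute.
#' @export
clean_graph <- function(graph, d = 1, depth_limit = 10, simplify = TRUE,
                        fuzz = 1000, max_tip = 4) {
  g <- propagate_colours(graph, depth_limit)
  n_prop <- length(g$propagated)
  g <- drop_conflicting_vertices(g)
  n_conf <- attr(g, "conflicts_removed")
  res <- remove_inconsistent_edges(g, d)
  g <- res$graph
  n_incons <- res$report$links_removed[res$report$chromosome == "total"]
  n_trans <- 0L
  n_tips <- 0L
  if (simplify) {
    g <- simplify_graph(g, fuzz = fuzz, max_tip = max_tip)
    st <- attr(g, "simplify_stats")
    n_trans <- st$transitive_links_removed
    n_tips <- st$tip_reads_removed
  }
  report <- data.frame(reads_propagated = n_prop,
                       conflict_reads_removed = n_conf,
                       inconsistent_links_removed = n_incons,
                       transitive_links_removed = n_trans,
                       tip_reads_removed = n_tips)
  attr(report, "per_chromosome") <- res$report
  list(graph = g, report = report)
}
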