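# The coloured overlap graph.
#
# Vertices are oriented reads ("read7" in + or - orientation); every retained
# read contributes both orientations, which share one colour set.  Edges are
# suffix-prefix overlaps; whenever (u, v) is present so is the mirror
# (v-bar, u-bar) with the same overlap length, so the graph is bidirected.
# Edges carry the overlap length in bp on the source suffix / target prefix.

flip_strand <- function(s) ifelse(s == "+", "-", "+")

vertex_key <- function(id, strand) paste0(id, strand)

# Mirror of a directed edge table.
mirror_edges <- function(edges) {
  data.frame(from_id = edges$to_id,
             from_strand = flip_strand(edges$to_strand),
             to_id = edges$from_id,
             to_strand = flip_strand(edges$from_strand),
             overlap_len = edges$overlap_len,
             stringsAsFactors = FALSE)
}

empty_edges <- function() {
  data.frame(from_id = character(0), from_strand = character(0),
             to_id = character(0), to_strand = character(0),
             overlap_len = numeric(0), stringsAsFactors = FALSE)
}

# Deduplicate parallel edges (keep the longest overlap) and close the edge
# set under mirroring.
close_edges <- function(edges) {
  e <- rbind(edges, mirror_edges(edges))
  dt <- data.table::as.data.table(e)
  data.table::setorder(dt, from_id, from_strand, to_id, to_strand, -overlap_len)
  key <- paste(dt$from_id, dt$from_strand, dt$to_id, dt$to_strand, sep = "\r")
  as.data.frame(dt[!duplicated(key)])
}

#' Construct a coloured overlap graph
#'
#' Low-level constructor.  `edges` is closed under mirroring and
#' deduplicated; colours for reads not mentioned in `colours` default to
#' the empty set.
#'
#' @param reads data.frame with columns `read_id` and `length` (bp; may be
#'   `NA` when unknown).
#' @param edges data.frame with columns `from_id`, `from_strand`, `to_id`,
#'   `to_strand`, `overlap_len`.
#' @param colours Named list mapping `read_id` to a numeric vector of
#'   packed colours.
#' @return A `coloured_overlap_graph`.
#' @export
new_overlap_graph <- function(reads, edges = empty_edges(), colours = list()) {
  reads <- data.frame(read_id = as.character(reads$read_id),
                      length = as.numeric(reads$length),
                      stringsAsFactors = FALSE)
  reads <- reads[!duplicated(reads$read_id), , drop = FALSE]
  reads <- reads[order(reads$read_id), , drop = FALSE]
  rownames(reads) <- NULL
  edges <- close_edges(edges)
  stopifnot(all(edges$from_id %in% reads$read_id),
            all(edges$to_id %in% reads$read_id),
            all(edges$overlap_len > 0 | nrow(edges) == 0L))
  full <- stats::setNames(rep(list(numeric(0)), nrow(reads)), reads$read_id)
  keep <- intersect(names(colours), reads$read_id)
  full[keep] <- lapply(colours[keep], sort)
  structure(list(reads = reads, edges = edges, colours = full,
                 propagated = character(0)),
            class = "coloured_overlap_graph")
}

#' @export
print.coloured_overlap_graph <- function(x, ...) {
  cat(sprintf(paste0("coloured_overlap_graph: %d reads (%d coloured), ",
                     "%d links (%d directed edges)\n"),
              nrow(x$reads), sum(lengths(x$colours) > 0),
              nrow(x$edges) %/% 2L, nrow(x$edges)))
  invisible(x)
}

#' Number of undirected links in an overlap graph
#'
#' Each suffix-prefix overlap is stored as a directed edge plus its
#' reverse-complement mirror; this counts each such pair once.
#'
#' @param graph A `coloured_overlap_graph`.
#' @return Integer link count.
#' @export
n_links <- function(graph) nrow(graph$edges) %/% 2L

# Drop reads (both orientations, incident edges, colours) from the graph.
drop_reads <- function(graph, read_ids) {
  if (length(read_ids) == 0L) return(graph)
  graph$reads <- graph$reads[!(graph$reads$read_id %in% read_ids), , drop = FALSE]
  e <- graph$edges
  graph$edges <- e[!(e$from_id %in% read_ids | e$to_id %in% read_ids), , drop = FALSE]
  graph$colours <- graph$colours[setdiff(names(graph$colours), read_ids)]
  graph$propagated <- setdiff(graph$propagated, read_ids)
  graph
}

#' Build the overlap graph from all-vs-all read overlaps
#'
#' Each read-vs-read PAF record is classified the standard way: records
#' whose aligned span is shorter than `min_overlap` are dropped; records
#' with long unaligned overhangs on both flanks are internal matches and
#' dropped; records where one read's flanks fit inside the other mark the
#' shorter read as contained (contained reads are removed from the graph
#' before any edge is added); the rest are suffix-prefix overlaps and
#' become a directed edge in the orientation-resolved direction plus its
#' mirror.  Self-overlap records are skipped.
#'
#' @param paf data.frame of all-vs-all overlaps as from [read_paf()].
#' @param min_overlap Minimum aligned span in bp (default 2000).
#' @param max_hang Maximum total unaligned overhang for a dovetail
#'   (default 1000); the overhang is also capped at `int_frac` times the
#'   aligned span.
#' @param int_frac Fraction of the aligned span allowed as overhang
#'   (default 0.8).
#' @return An uncoloured `coloured_overlap_graph`.
#' @export
build_graph_from_paf <- function(paf, min_overlap = 2000, max_hang = 1000,
                                 int_frac = 0.8) {
  paf <- paf[paf$qname != paf$tname, , drop = FALSE]
  lens <- c(stats::setNames(paf$qlen, paf$qname), stats::setNames(paf$tlen, paf$tname))
  lens <- lens[!duplicated(names(lens))]
  all_reads <- data.frame(read_id = names(lens), length = as.numeric(lens),
                          stringsAsFactors = FALSE)
  if (nrow(paf) == 0L) return(new_overlap_graph(all_reads))

  # orient the target with the query
  ts <- ifelse(paf$strand == "-", paf$tlen - paf$tend, paf$tstart)
  te <- ifelse(paf$strand == "-", paf$tlen - paf$tstart, paf$tend)
  maplen <- pmax(paf$qend - paf$qstart, te - ts)
  keep <- maplen >= min_overlap
  overhang <- pmin(paf$qstart, ts) + pmin(paf$qlen - paf$qend, paf$tlen - te)
  internal <- overhang > pmin(max_hang, maplen * int_frac)
  q_contained <- !internal & paf$qstart <= ts & (paf$qlen - paf$qend) <= (paf$tlen - te)
  t_contained <- !internal & !q_contained & paf$qstart >= ts &
    (paf$qlen - paf$qend) >= (paf$tlen - te)

  contained <- unique(c(paf$qname[keep & q_contained], paf$tname[keep & t_contained]))
  dove <- keep & !internal & !q_contained & !t_contained &
    !(paf$qname %in% contained) & !(paf$tname %in% contained)

  q_first <- paf$qstart > ts
  e1 <- paf[dove & q_first, , drop = FALSE]
  ts1 <- ts[dove & q_first]; te1 <- te[dove & q_first]
  edges1 <- data.frame(from_id = e1$qname, from_strand = rep("+", nrow(e1)),
                       to_id = e1$tname, to_strand = e1$strand,
                       overlap_len = te1 - ts1, stringsAsFactors = FALSE)
  e2 <- paf[dove & !q_first, , drop = FALSE]
  edges2 <- data.frame(from_id = e2$tname, from_strand = e2$strand,
                       to_id = e2$qname, to_strand = rep("+", nrow(e2)),
                       overlap_len = e2$qend - e2$qstart, stringsAsFactors = FALSE)
  reads <- all_reads[!(all_reads$read_id %in% contained), , drop = FALSE]
  new_overlap_graph(reads, rbind(edges1, edges2))
}

#' Attach a read colouring to the graph
#'
#' Both orientations of a read share the read's colour set.  Colouring
#' entries for reads absent from the graph (for example reads removed as
#' contained) are ignored; their count is stored in the
#' `ignored_colourings` attribute of the result.
#'
#' @param graph A `coloured_overlap_graph`.
#' @param colouring A `read_colouring` (named list of packed colours).
#' @return The coloured graph.
#' @export
attach_colours <- function(graph, colouring) {
  stopifnot(inherits(graph, "coloured_overlap_graph"))
  present <- intersect(names(colouring), graph$reads$read_id)
  graph$colours[present] <- lapply(colouring[present], sort)
  attr(graph, "ignored_colourings") <- length(colouring) - length(present)
  graph
}

# Consistency flag for every directed edge at colour distance d.
# An edge is consistent when either endpoint read is uncoloured, or some
# colour pair of the two endpoint reads is adjacent at distance d.
edge_consistency <- function(graph, d) {
  e <- graph$edges
  if (nrow(e) == 0L) return(logical(0))
  nc <- lengths(graph$colours)
  a <- pmin(e$from_id, e$to_id)
  b <- pmax(e$from_id, e$to_id)
  pairkey <- paste(a, b, sep = "\r")
  first <- !duplicated(pairkey)
  ua <- a[first]; ub <- b[first]
  ok <- rep(TRUE, sum(first))
  both <- nc[ua] > 0L & nc[ub] > 0L
  idx <- which(both)
  if (length(idx) > 0L) {
    A <- data.table::data.table(pid = rep(idx, nc[ua[idx]]),
                                col = unlist(graph$colours[ua[idx]], use.names = FALSE))
    B <- data.table::data.table(pid = rep(idx, nc[ub[idx]]),
                                col = unlist(graph$colours[ub[idx]], use.names = FALSE))
    data.table::setkey(B, pid, col)
    near <- B[A, on = c("pid", "col"), roll = "nearest",
              j = list(pid = pid, acol = i.col, bcol = x.col)]
    near <- near[, list(adj = any(colours_adjacent(acol, bcol, d))), by = "pid"]
    ok[near$pid] <- near$adj
  }
  res_pair <- stats::setNames(ok, pairkey[first])
  unname(res_pair[pairkey])
}

# Colour-consistent in/out degree of every vertex at effective distance d_eff
# (the caller applies the max(1, d) floor).  Neighbours across an edge with
# an uncoloured endpoint always count as consistent.
cc_degree_table <- function(graph, d_eff) {
  verts <- c(vertex_key(graph$reads$read_id, "+"), vertex_key(graph$reads$read_id, "-"))
  out <- stats::setNames(rep(0L, length(verts)), verts)
  inn <- out
  if (nrow(graph$edges) > 0L) {
    cons <- edge_consistency(graph, d_eff)
    e <- graph$edges[cons, , drop = FALSE]
    if (nrow(e) > 0L) {
      tf <- table(vertex_key(e$from_id, e$from_strand))
      tt <- table(vertex_key(e$to_id, e$to_strand))
      out[names(tf)] <- as.integer(tf)
      inn[names(tt)] <- as.integer(tt)
    }
  }
  data.frame(vertex = verts, ccin = unname(inn), ccout = unname(out),
             stringsAsFactors = FALSE)
}

#' Colour-consistent degrees of a vertex
#'
#' Counts the in- and out-neighbours of the oriented read that share at
#' least one colour within distance `max(1, d)` of one of its colours.
#' Edges with an uncoloured endpoint (either side) always count: unmapped
#' reads must not break paths before propagation has coloured them.
#'
#' @param graph A `coloured_overlap_graph`.
#' @param read_id Read identifier.
#' @param orientation `"+"` or `"-"`.
#' @param d Colour distance (default 1); the effective distance is
#'   `max(1, d)`.
#' @return Named numeric vector `c(indegree =, outdegree =)`.
#' @export
colour_consistent_degrees <- function(graph, read_id, orientation = "+", d = 1) {
  stopifnot(read_id %in% graph$reads$read_id, orientation %in% c("+", "-"))
  tab <- cc_degree_table(graph, max(1, d))
  row <- tab[tab$vertex == vertex_key(read_id, orientation), ]
  c(indegree = row$ccin, outdegree = row$ccout)
}

# ---- GFA 1.0 input/output -------------------------------------------------

#' Write / load the coloured overlap graph as GFA 1.0
#'
#' Segments are written as `S` lines (`*` sequence) carrying `LN:i:` and,
#' for coloured reads, a `cl:Z:` tag of comma-separated packed colours.
#' Each link is written once as an `L` line with a `<n>M` overlap CIGAR;
#' the mirror edge is implied and restored on loading.  Output is
#' canonicalised (sorted `S` then sorted `L` lines) so that writing is
#' byte-stable.
#'
#' @param graph A `coloured_overlap_graph`.
#' @param path GFA file path.
#' @return `write_gfa()`: `path` invisibly; `load_gfa()`: a
#'   `coloured_overlap_graph`.
#' @export
write_gfa <- function(graph, path) {
  stopifnot(inherits(graph, "coloured_overlap_graph"))
  r <- graph$reads[order(graph$reads$read_id), , drop = FALSE]
  ln <- ifelse(is.na(r$length), "", sprintf("\tLN:i:%d", as.integer(r$length)))
  cl <- vapply(graph$colours[r$read_id], format_colours, "")
  cl <- ifelse(nzchar(cl), paste0("\tcl:Z:", cl), "")
  s_lines <- sprintf("S\t%s\t*%s%s", r$read_id, ln, cl)

  e <- graph$edges
  l_lines <- character(0)
  if (nrow(e) > 0L) {
    fwd <- paste(e$from_id, e$from_strand, e$to_id, e$to_strand)
    m <- mirror_edges(e)
    rev <- paste(m$from_id, m$from_strand, m$to_id, m$to_strand)
    canon <- e[fwd <= rev, , drop = FALSE]
    l_lines <- sprintf("L\t%s\t%s\t%s\t%s\t%dM", canon$from_id, canon$from_strand,
                       canon$to_id, canon$to_strand, as.integer(canon$overlap_len))
    l_lines <- sort(l_lines)
  }
  writeLines(c("H\tVN:Z:1.0", s_lines, l_lines), path)
  invisible(path)
}

#' @rdname write_gfa
#' @export
load_gfa <- function(path) {
  if (!file.exists(path)) stop("GFA file not found: ", path)
  lines <- readLines(path)
  recs <- strsplit(lines, "\t", fixed = TRUE)
  type <- vapply(recs, function(r) if (length(r) > 0L) r[[1L]] else "", "")

  tag_val <- function(rec, prefix) {
    hit <- grep(prefix, rec, fixed = TRUE, value = TRUE)
    if (length(hit) == 0L) NA_character_ else sub(prefix, "", hit[1], fixed = TRUE)
  }

  s <- recs[type == "S"]
  if (length(s) == 0L) stop("GFA '", path, "' contains no S lines")
  ids <- vapply(s, `[[`, "", 2L)
  seqs <- vapply(s, function(r) if (length(r) >= 3L) r[[3L]] else "*", "")
  ln <- vapply(s, tag_val, "", prefix = "LN:i:")
  len <- ifelse(!is.na(ln), as.numeric(ln),
                ifelse(seqs != "*", nchar(seqs), NA_real_))
  cl <- vapply(s, tag_val, "", prefix = "cl:Z:")
  colours <- lapply(cl, function(x) if (is.na(x)) numeric(0) else parse_colours(x))
  names(colours) <- ids

  l <- recs[type == "L"]
  if (length(l) > 0L) {
    bad <- which(lengths(l) < 6L)
    if (length(bad) > 0L) stop("malformed GFA L line in '", path, "'")
    cig <- vapply(l, `[[`, "", 6L)
    if (!all(grepl("^[0-9]+M$", cig))) {
      stop("unsupported GFA overlap CIGAR (only <n>M is supported) in '", path, "'")
    }
    edges <- data.frame(from_id = vapply(l, `[[`, "", 2L),
                        from_strand = vapply(l, `[[`, "", 3L),
                        to_id = vapply(l, `[[`, "", 4L),
                        to_strand = vapply(l, `[[`, "", 5L),
                        overlap_len = as.numeric(sub("M$", "", cig)),
                        stringsAsFactors = FALSE)
  } else {
    edges <- empty_edges()
  }
  new_overlap_graph(data.frame(read_id = ids, length = len,
                               stringsAsFactors = FALSE),
                    edges, colours)
}

# Invariant assertion used by the test-suite: every edge has its mirror with
# equal overlap length, and both orientations of a read share colours.
assert_graph_symmetry <- function(graph) {
  e <- graph$edges
  if (nrow(e) == 0L) return(invisible(TRUE))
  key <- paste(e$from_id, e$from_strand, e$to_id, e$to_strand, e$overlap_len)
  m <- mirror_edges(e)
  mkey <- paste(m$from_id, m$from_strand, m$to_id, m$to_strand, m$overlap_len)
  if (!setequal(key, mkey)) stop("overlap graph mirror symmetry violated")
  invisible(TRUE)
}
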