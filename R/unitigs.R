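# Guided unitigs: maximal non-branching paths under colour-consistent
# degrees, reported once per mirror pair, oriented and split so that
# colours never decrease along the reported path.

# Linear edge: (u, v) such that u's colour-consistent outdegree and v's
# colour-consistent indegree are both exactly 1 (at distance max(1, d)) and
# the edge itself is colour-consistent.  Linear edges form vertex-disjoint
# paths and cycles; this returns their maximal chains as lists of vertex
# keys.  Cycles are broken deterministically at their smallest vertex.
cc_linear_paths <- function(graph, d = 1) {
  verts <- sort(c(vertex_key(graph$reads$read_id, "+"),
                  vertex_key(graph$reads$read_id, "-")))
  e <- graph$edges
  if (nrow(e) > 0L) {
    d_eff <- max(1, d)
    cons <- edge_consistency(graph, d_eff)
    tab <- cc_degree_table(graph, d_eff)
    ccout <- stats::setNames(tab$ccout, tab$vertex)
    ccin <- stats::setNames(tab$ccin, tab$vertex)
    ek_from <- vertex_key(e$from_id, e$from_strand)
    ek_to <- vertex_key(e$to_id, e$to_strand)
    linear <- cons & ccout[ek_from] == 1L & ccin[ek_to] == 1L
    succ <- stats::setNames(ek_to[linear], ek_from[linear])
    has_in <- unique(ek_to[linear])
  } else {
    succ <- stats::setNames(character(0), character(0))
    has_in <- character(0)
  }

  paths <- list()
  visited <- stats::setNames(rep(FALSE, length(verts)), verts)
  walk <- function(start) {
    p <- start
    visited[start] <<- TRUE
    v <- start
    repeat {
      nxt <- unname(succ[v])
      if (is.na(nxt) || visited[nxt]) break
      p <- c(p, nxt)
      visited[nxt] <<- TRUE
      v <- nxt
    }
    cyclic <- length(p) > 1L && !is.na(unname(succ[v])) && unname(succ[v]) == start
    list(p = p, cyclic = cyclic)
  }
  starts <- verts[!(verts %in% has_in)]
  for (s in starts) paths[[length(paths) + 1L]] <- walk(s)
  # anything left unvisited sits on a cycle of linear edges; break each at
  # its smallest vertex
  remaining <- verts[!visited[verts]]
  while (length(remaining) > 0L) {
    s <- min(remaining)
    paths[[length(paths) + 1L]] <- walk(s)
    remaining <- verts[!visited[verts]]
  }
  paths
}

mirror_path <- function(p) {
  ids <- substr(p, 1L, nchar(p) - 1L)
  strands <- substr(p, nchar(p), nchar(p))
  rev(vertex_key(ids, flip_strand(strands)))
}

path_key <- function(p) paste(p, collapse = "\r")

# Per-chromosome non-decreasing check across one edge: for every chromosome
# coloured on both sides, both the minimum and the maximum ordinal must not
# decrease.  Vacuous when either side is uncoloured.
edge_monotone <- function(cols_a, cols_b) {
  if (length(cols_a) == 0L || length(cols_b) == 0L) return(TRUE)
  ch <- intersect(unique(colour_chrom(cols_a)), unique(colour_chrom(cols_b)))
  for (k in ch) {
    a <- cols_a[colour_chrom(cols_a) == k]
    b <- cols_b[colour_chrom(cols_b) == k]
    if (min(b) < min(a) || max(b) < max(a)) return(FALSE)
  }
  TRUE
}

path_violations <- function(p, colours) {
  if (length(p) < 2L) return(integer(0))
  ids <- substr(p, 1L, nchar(p) - 1L)
  bad <- integer(0)
  for (i in seq_len(length(p) - 1L)) {
    if (!edge_monotone(colours[[ids[i]]], colours[[ids[i + 1L]]])) {
      bad <- c(bad, i)
    }
  }
  bad
}

split_at <- function(p, cut_after) {
  if (length(cut_after) == 0L) return(list(p))
  bounds <- c(0L, cut_after, length(p))
  lapply(seq_len(length(bounds) - 1L),
         function(i) p[(bounds[i] + 1L):bounds[i + 1L]])
}

#' Extract guided unitigs from a coloured overlap graph
#'
#' Finds all maximal paths in which every internal junction has
#' colour-consistent out- and in-degree exactly 1 (with an entirely
#' uncoloured graph this degenerates to plain maximal non-branching
#' paths).  Each path and its reverse-complement mirror describe the same
#' unitig; the lexicographically smaller of the two vertex sequences is
#' kept.  The kept path is then oriented so that colours tend upward (the
#' orientation with fewer per-edge monotonicity violations wins) and is
#' split at any edge where colours still decrease.
#'
#' @param graph A `coloured_overlap_graph` (cleaned, or raw for a
#'   baseline).
#' @param d Colour distance used for the consistent degrees; the effective
#'   distance is `max(1, d)`.
#' @return A `unitig_set`: list of unitigs, each a list with `id`,
#'   `vertices` (oriented vertex keys), `read_ids`, `strands`, `colours`
#'   (per-vertex packed colour sets), `colour_range` (packed min/max or
#'   `NULL` if uncoloured), `overlaps` (per-edge overlap lengths) and
#'   `length` (assembled bp, `NA` when read lengths are unknown).
#' @export
extract_unitigs <- function(graph, d = 1) {
  stopifnot(inherits(graph, "coloured_overlap_graph"))
  raw <- cc_linear_paths(graph, d)

  # one report per mirror pair: keep the lexicographically smaller vertex
  # sequence (cycles are compared after rotating the mirror to its own
  # smallest vertex, matching how cycles are broken during the walk)
  keep <- vapply(raw, function(w) {
    m <- mirror_path(w$p)
    if (w$cyclic) {
      i <- which.min(m)
      m <- m[c(i:length(m), seq_len(i - 1L))]
    }
    path_key(w$p) <= path_key(m)
  }, logical(1))
  raw <- raw[keep]

  pieces <- list()
  for (w in raw) {
    p <- w$p
    m <- mirror_path(p)
    vp <- path_violations(p, graph$colours)
    vm <- path_violations(m, graph$colours)
    chosen <- if (length(vm) < length(vp)) m else p
    cuts <- if (length(vm) < length(vp)) vm else vp
    pieces <- c(pieces, split_at(chosen, cuts))
  }
  o <- order(vapply(pieces, `[[`, "", 1L))
  pieces <- pieces[o]

  lens <- stats::setNames(graph$reads$length, graph$reads$read_id)
  ekey <- paste(vertex_key(graph$edges$from_id, graph$edges$from_strand),
                vertex_key(graph$edges$to_id, graph$edges$to_strand), sep = "\r")
  ol_of <- stats::setNames(graph$edges$overlap_len, ekey)

  utgs <- lapply(seq_along(pieces), function(i) {
    p <- pieces[[i]]
    ids <- substr(p, 1L, nchar(p) - 1L)
    strands <- substr(p, nchar(p), nchar(p))
    cols <- graph$colours[ids]
    ols <- if (length(p) > 1L) {
      unname(ol_of[paste(p[-length(p)], p[-1L], sep = "\r")])
    } else numeric(0)
    all_cols <- unlist(cols, use.names = FALSE)
    rng <- if (length(all_cols) > 0L) c(min(all_cols), max(all_cols)) else NULL
    total <- sum(lens[ids]) - sum(ols)
    list(id = sprintf("utg%06d", i), vertices = p, read_ids = ids,
         strands = strands, colours = cols, colour_range = rng,
         overlaps = ols, length = unname(total))
  })
  structure(utgs, class = "unitig_set")
}

#' @export
print.unitig_set <- function(x, ...) {
  tot <- sum(vapply(x, function(u) ifelse(is.na(u$length), 0, u$length), 0))
  cat(sprintf("unitig_set: %d unitigs, %d reads, %.0f bp assembled\n",
              length(x), sum(vapply(x, function(u) length(u$read_ids), 0L)), tot))
  invisible(x)
}

#' Spell the sequence of a unitig
#'
#' Overlap-layout spelling: the first read (orientation-resolved), then
#' each subsequent read with its overlap-length prefix removed, so the
#' total length is the sum of read lengths minus the sum of overlap
#' lengths.
#'
#' @param unitig One element of a `unitig_set` (or any list with
#'   `read_ids`, `strands`, `overlaps`).
#' @param reads Named character vector or `DNAStringSet` of read
#'   sequences.
#' @return A single sequence string.
#' @export
unitig_sequence <- function(unitig, reads) {
  if (!is.character(reads)) reads <- as.character(reads)
  seqs <- reads[unitig$read_ids]
  if (anyNA(seqs)) stop("missing read sequence(s): ",
                        paste(unitig$read_ids[is.na(seqs)], collapse = ", "))
  minus <- unitig$strands == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  out <- unname(seqs[1L])
  for (i in seq_along(unitig$overlaps)) {
    ol <- unitig$overlaps[i]
    if (ol >= nchar(seqs[i]) || ol >= nchar(seqs[i + 1L])) {
      stop("assembly error: overlap length ", ol,
           " not shorter than both incident reads")
    }
    out <- paste0(out, substr(seqs[i + 1L], ol + 1L, nchar(seqs[i + 1L])))
  }
  out
}

#' Write unitigs as FASTA and/or GFA
#'
#' FASTA headers carry `LN:i:` (assembled length) and `cl:Z:` (packed
#' colour range, `min,max`).  The GFA output holds one `S` line per
#' unitig with the same tags plus `pa:Z:` (the oriented read path) and
#' `ol:Z:` (per-edge overlap lengths), which [read_unitig_gfa()] restores
#' exactly.
#'
#' @param unitigs A `unitig_set`.
#' @param fasta_path Output FASTA path, or `NULL` to skip.
#' @param gfa_path Output GFA path, or `NULL` to skip.
#' @param reads Read sequences (required for FASTA; optional for GFA,
#'   where sequences are written when available and `*` otherwise).
#' @return Invisibly, the paths written.
#' @export
write_unitigs <- function(unitigs, fasta_path = NULL, gfa_path = NULL, reads = NULL) {
  seqs <- NULL
  if (!is.null(reads)) {
    seqs <- vapply(unitigs, unitig_sequence, "", reads = reads)
  }
  hdr_tags <- vapply(unitigs, function(u) {
    cl <- if (is.null(u$colour_range)) "" else
      sprintf(" cl:Z:%s", format_colours(u$colour_range))
    ln <- if (is.na(u$length)) "" else sprintf(" LN:i:%d", as.integer(u$length))
    paste0(ln, cl)
  }, "")
  ids <- vapply(unitigs, `[[`, "", "id")
  if (!is.null(fasta_path)) {
    if (is.null(seqs)) stop("read sequences are required to write unitig FASTA")
    lines <- if (length(ids) > 0L) paste0(">", ids, hdr_tags, "\n", seqs) else character(0)
    writeLines(lines, fasta_path, sep = "\n")
  }
  if (!is.null(gfa_path)) {
    s <- vapply(seq_along(unitigs), function(i) {
      u <- unitigs[[i]]
      tags <- character(0)
      if (!is.na(u$length)) tags <- c(tags, sprintf("LN:i:%d", as.integer(u$length)))
      if (!is.null(u$colour_range)) {
        tags <- c(tags, sprintf("cl:Z:%s", format_colours(u$colour_range)))
      }
      tags <- c(tags, sprintf("pa:Z:%s", paste(u$vertices, collapse = ",")),
                sprintf("ol:Z:%s", paste(as.integer(u$overlaps), collapse = ",")))
      paste(c("S", u$id, if (is.null(seqs)) "*" else seqs[i], tags), collapse = "\t")
    }, "")
    writeLines(c("H\tVN:Z:1.0", s), gfa_path)
  }
  invisible(c(fasta_path, gfa_path))
}

#' Read back a unitig GFA written by [write_unitigs()]
#'
#' @param path GFA path.
#' @return A list of unitigs with `id`, `vertices`, `read_ids`, `strands`
#'   and `overlaps` (sequence and colours are not restored).
#' @export
read_unitig_gfa <- function(path) {
  lines <- readLines(path)
  recs <- strsplit(lines, "\t", fixed = TRUE)
  recs <- recs[vapply(recs, function(r) length(r) > 0L && r[[1L]] == "S", logical(1))]
  lapply(recs, function(r) {
    pa <- sub("^pa:Z:", "", grep("^pa:Z:", r, value = TRUE)[1])
    olv <- sub("^ol:Z:", "", grep("^ol:Z:", r, value = TRUE)[1])
    verts <- strsplit(pa, ",", fixed = TRUE)[[1]]
    ols <- if (is.na(olv) || !nzchar(olv)) numeric(0) else
      as.numeric(strsplit(olv, ",", fixed = TRUE)[[1]])
    list(id = r[[2L]], vertices = verts,
         read_ids = substr(verts, 1L, nchar(verts) - 1L),
         strands = substr(verts, nchar(verts), nchar(verts)),
         overlaps = ols)
  })
}
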