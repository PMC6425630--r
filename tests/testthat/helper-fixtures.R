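# Fixtures and independent oracles used across the suite.  Oracles are
# deliberately naive (linear scans, double loops, exhaustive enumeration)
# and never call the code paths they check.

# -- quick constructors ------------------------------------------------------

mk_paf <- function(qname, qlen, qstart, qend, strand, tname, tlen, tstart, tend,
                   nmatch = NULL, alnlen = NULL, mapq = 255) {
  span <- pmax(qend - qstart, tend - tstart)
  data.frame(qname = qname, qlen = qlen, qstart = qstart, qend = qend,
             strand = strand, tname = tname, tlen = tlen, tstart = tstart,
             tend = tend,
             nmatch = if (is.null(nmatch)) span else nmatch,
             alnlen = if (is.null(alnlen)) span else alnlen,
             mapq = mapq, stringsAsFactors = FALSE)
}

# Linkage map with `n_bins` bins per chromosome, one marker per bin, on
# contigs named like the chromosomes.
mk_map <- function(n_bins = 10, chroms = "chrA", spacing = 1000) {
  bins <- do.call(rbind, lapply(seq_along(chroms), function(i) {
    data.frame(bin_id = sprintf("%s_b%d", chroms[i], seq_len(n_bins) - 1L),
               chromosome = chroms[i], chrom_index = i - 1L,
               ordinal = seq_len(n_bins) - 1L, stringsAsFactors = FALSE)
  }))
  markers <- data.frame(contig = bins$chromosome,
                        pos = bins$ordinal * spacing + spacing / 2,
                        bin_id = bins$bin_id, stringsAsFactors = FALSE)
  new_linkage_map(markers, bins)
}

# Hand-built graph from compact edge/colour specs.
# edges: data.frame(from, to, ol) with "r1+"-style vertex keys.
mk_graph <- function(edge_spec, colours = list(), read_len = 8000,
                     extra_reads = character(0)) {
  split_key <- function(k) {
    list(id = substr(k, 1, nchar(k) - 1), strand = substr(k, nchar(k), nchar(k)))
  }
  f <- split_key(edge_spec$from)
  t <- split_key(edge_spec$to)
  edges <- data.frame(from_id = f$id, from_strand = f$strand,
                      to_id = t$id, to_strand = t$strand,
                      overlap_len = edge_spec$ol, stringsAsFactors = FALSE)
  ids <- unique(c(f$id, t$id, names(colours), extra_reads))
  reads <- data.frame(read_id = ids, length = rep_len(read_len, length(ids)),
                      stringsAsFactors = FALSE)
  new_overlap_graph(reads, edges, colours)
}

# Random coloured graph (edges closed under mirroring by the constructor).
random_graph <- function(n_reads = 8, n_links = 10, colour_prob = 0.7,
                         n_chrom = 2, n_ord = 8, seed = 1) {
  set.seed(seed)
  ids <- sprintf("r%02d", seq_len(n_reads))
  reads <- data.frame(read_id = ids,
                      length = sample(5000:10000, n_reads, replace = TRUE),
                      stringsAsFactors = FALSE)
  from <- sample(ids, n_links, replace = TRUE)
  to <- sample(ids, n_links, replace = TRUE)
  keep <- from != to
  edges <- data.frame(from_id = from[keep],
                      from_strand = sample(c("+", "-"), sum(keep), replace = TRUE),
                      to_id = to[keep],
                      to_strand = sample(c("+", "-"), sum(keep), replace = TRUE),
                      overlap_len = sample(500:3000, sum(keep), replace = TRUE),
                      stringsAsFactors = FALSE)
  colours <- lapply(ids, function(i) {
    if (stats::runif(1) < colour_prob) {
      sort(sample(colour(sample.int(n_chrom, 1) - 1L, 0:(n_ord - 1L)),
                  sample.int(3L, 1)))
    } else numeric(0)
  })
  names(colours) <- ids
  new_overlap_graph(reads, edges, colours)
}

# Small error-free simulation wired through colouring, used by several tests.
small_sim <- function(seed, chrom_len = 50000, n_chrom = 1, coverage = 12,
                      mean_len = 4000, len_sd = 400, min_overlap = 500,
                      spurious_n = 0, min_sep_bins = 5, error_rate = 0) {
  sim <- simulate_genome_and_map(n_chrom, chrom_len, 0.008, 200, seed = seed)
  rd <- simulate_reads(sim$genome, coverage = coverage, mean_len = mean_len,
                       len_sd = len_sd, error_rate = error_rate,
                       seed = seed + 1000L)
  aln <- emit_true_alignments(rd$truth, nchar(sim$genome$sequences))
  colouring <- colour_from_mappings(aln, sim$map)
  ovl <- emit_overlaps(rd$truth, min_overlap = min_overlap,
                       spurious_n = spurious_n, min_sep_bins = min_sep_bins,
                       map = sim$map, seed = seed + 2000L)
  g <- attach_colours(build_graph_from_paf(ovl, min_overlap = min_overlap),
                      colouring)
  list(sim = sim, reads = rd$reads, truth = rd$truth, colouring = colouring,
       overlaps = ovl, graph = g)
}

# -- independent oracles -----------------------------------------------------

# Linear-scan point query over raw intervals.
brute_interval_query <- function(intervals, target_id, pos) {
  hit <- intervals$target_id == target_id &
    intervals$start <= pos & pos < intervals$end
  intervals$read_id[hit]
}

# Set-comprehension colour consistency: double loop over decoded colours.
brute_sets_consistent <- function(A, B, d) {
  if (length(A) == 0L || length(B) == 0L) return(TRUE)
  for (a in A) {
    for (b in B) {
      if (floor(a / 1e6) == floor(b / 1e6) && abs(a - b) <= d) return(TRUE)
    }
  }
  FALSE
}

# Colour-consistent degrees straight from the definition (with the
# max(1, d) floor the degree definition uses).
brute_cc_degrees <- function(graph, vkey, d) {
  d_eff <- max(1, d)
  e <- graph$edges
  ek_from <- paste0(e$from_id, e$from_strand)
  ek_to <- paste0(e$to_id, e$to_strand)
  id_of <- function(k) substr(k, 1, nchar(k) - 1)
  outdeg <- 0L
  indeg <- 0L
  for (i in seq_len(nrow(e))) {
    if (ek_from[i] == vkey &&
        brute_sets_consistent(graph$colours[[id_of(vkey)]],
                              graph$colours[[e$to_id[i]]], d_eff)) {
      outdeg <- outdeg + 1L
    }
    if (ek_to[i] == vkey &&
        brute_sets_consistent(graph$colours[[e$from_id[i]]],
                              graph$colours[[id_of(vkey)]], d_eff)) {
      indeg <- indeg + 1L
    }
  }
  c(indegree = indeg, outdegree = outdeg)
}

# Directed edges that the inconsistency definition marks for removal.
brute_inconsistent_edges <- function(graph, d) {
  e <- graph$edges
  bad <- vapply(seq_len(nrow(e)), function(i) {
    A <- graph$colours[[e$from_id[i]]]
    B <- graph$colours[[e$to_id[i]]]
    length(A) > 0L && length(B) > 0L && !brute_sets_consistent(A, B, d)
  }, logical(1))
  e[bad, , drop = FALSE]
}

# Exhaustive maximal-path enumeration for the guided unitig conditions:
# enumerate every simple path over the edge set, keep those whose internal
# junctions all have colour-consistent out/in-degree exactly 1 across a
# consistent edge, drop paths contained in longer valid paths, and
# canonicalise cycle rotations to start at the smallest vertex.
brute_max_paths <- function(graph, d) {
  d_eff <- max(1, d)
  e <- graph$edges
  verts <- sort(c(paste0(graph$reads$read_id, "+"), paste0(graph$reads$read_id, "-")))
  ek_from <- paste0(e$from_id, e$from_strand)
  ek_to <- paste0(e$to_id, e$to_strand)
  cons <- vapply(seq_len(nrow(e)), function(i) {
    brute_sets_consistent(graph$colours[[e$from_id[i]]],
                          graph$colours[[e$to_id[i]]], d_eff)
  }, logical(1))
  ccout <- vapply(verts, function(v) sum(ek_from == v & cons), 0L)
  ccin <- vapply(verts, function(v) sum(ek_to == v & cons), 0L)
  edge_ok <- function(u, v) {
    any(ek_from == u & ek_to == v & cons) && ccout[[u]] == 1L && ccin[[v]] == 1L
  }
  succs <- function(u) unique(ek_to[ek_from == u])

  paths <- list()
  extend <- function(p) {
    paths[[length(paths) + 1L]] <<- p
    for (v in succs(p[length(p)])) {
      if (!(v %in% p) && edge_ok(p[length(p)], v)) extend(c(p, v))
    }
  }
  for (v in verts) extend(v)

  key <- function(p) paste(p, collapse = "\r")
  keys <- vapply(paths, key, "")
  contained <- vapply(seq_along(paths), function(i) {
    any(vapply(seq_along(paths), function(j) {
      i != j && length(paths[[j]]) > length(paths[[i]]) &&
        grepl(keys[i], keys[j], fixed = TRUE)
    }, logical(1)))
  }, logical(1))
  # a full cycle traversal can also be "extended" by rotating: treat a path
  # that closes on itself as a cycle and keep only the min-vertex rotation
  maxp <- paths[!contained]
  out <- list()
  seen <- character(0)
  for (p in maxp) {
    last <- p[length(p)]
    cyclic <- length(p) > 1L && edge_ok(last, p[1])
    if (cyclic) {
      i <- which.min(p)
      p <- p[c(i:length(p), seq_len(i - 1))]
    }
    k <- key(p)
    if (!(k %in% seen)) {
      seen <- c(seen, k)
      out[[length(out) + 1L]] <- p
    }
  }
  # drop cycle rotations that duplicate the canonical one
  out
}

# Rainbow property of a unitig: per chromosome, each colour occupies one
# contiguous run of path positions and per-vertex min/max never decrease.
is_rainbow <- function(unitig) {
  cols <- unitig$colours
  n <- length(cols)
  occ <- list()
  for (i in seq_len(n)) {
    for (cl in cols[[i]]) {
      k <- as.character(cl)
      occ[[k]] <- c(occ[[k]], i)
    }
  }
  for (k in names(occ)) {
    p <- occ[[k]]
    if (!identical(p, p[1]:(p[1] + length(p) - 1L))) return(FALSE)
  }
  for (i in seq_len(n - 1)) {
    a <- cols[[i]]
    b <- cols[[i + 1]]
    if (length(a) == 0L || length(b) == 0L) next
    for (ch in intersect(unique(floor(a / 1e6)), unique(floor(b / 1e6)))) {
      ak <- a[floor(a / 1e6) == ch]
      bk <- b[floor(b / 1e6) == ch]
      if (min(bk) < min(ak) || max(bk) < max(ak)) return(FALSE)
    }
  }
  TRUE
}

n50 <- function(lens) {
  s <- sort(lens, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

path_keys <- function(paths) sort(vapply(paths, paste, "", collapse = "\r"))

# Run the installed command-line front end in a fresh R process.
run_cli <- function(...) {
  script <- system.file("cli", "maptig", package = "maptig")
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- system2(rscript, c(script, ...),
                 env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep)),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("cli failed: ", paste(out, collapse = "\n"))
  }
  invisible(out)
}
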