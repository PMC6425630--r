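# Read colouring: pick each read's longest mapping onto the draft assembly,
# stretch it (within a cap) to cover the whole read, index the stretched
# intervals by genome blocks, and hand every read the colours of the linkage
# map markers it covers.

#' Keep the longest mapping of a read
#'
#' Of all mapping records for one read, returns the single record with the
#' largest span on the read (`qend - qstart`).  Ties are broken by
#' `(tname, tstart)` in lexicographic order so selection is deterministic.
#' No mapping-quality filter is applied.
#'
#' @param records data.frame of PAF records, all with the same `qname`.
#' @return A one-row data.frame (zero rows for empty input).
#' @export
select_longest_mappings <- function(records) {
  if (nrow(records) == 0L) return(records)
  stopifnot(length(unique(records$qname)) == 1L)
  span <- records$qend - records$qstart
  cand <- records[span == max(span), , drop = FALSE]
  cand[order(cand$tname, cand$tstart), , drop = FALSE][1, , drop = FALSE]
}

# Vectorised longest-mapping selection over a whole PAF table.
select_longest_per_read <- function(paf) {
  dt <- data.table::as.data.table(paf)
  dt[, span := qend - qstart]
  data.table::setorder(dt, qname, -span, tname, tstart)
  out <- dt[!duplicated(dt$qname)]
  out[, span := NULL]
  as.data.frame(out)
}

#' Stretch a mapping to cover the whole read
#'
#' The unmapped read prefix and suffix are added to the target interval on
#' the strand-appropriate sides, each clipped to `cap` (insertions dominate
#' long-read error profiles, so unmapped read bases overestimate the
#' missing target span).  On the `-` strand the read prefix extends the
#' target end.  The result is clamped to `[0, target_len]` and never
#' shrinks the original interval.
#'
#' @param rec One-row data.frame of a PAF mapping record, or a multi-row
#'   data.frame (vectorised).
#' @param cap Maximum extension per side in bp (default 250).
#' @return data.frame with columns `target_id`, `start`, `end`, `read_id`
#'   (0-based half-open extended coordinates).
#' @export
extend_mapping <- function(rec, cap = 250) {
  stopifnot(cap >= 0)
  head_ext <- pmin(rec$qstart, cap)                 # unmapped read prefix
  tail_ext <- pmin(rec$qlen - rec$qend, cap)        # unmapped read suffix
  minus <- rec$strand == "-"
  left <- ifelse(minus, tail_ext, head_ext)
  right <- ifelse(minus, head_ext, tail_ext)
  data.frame(target_id = rec$tname,
             start = pmax(0, rec$tstart - left),
             end = pmin(rec$tlen, rec$tend + right),
             read_id = rec$qname,
             stringsAsFactors = FALSE)
}

#' Build a block index over extended read intervals
#'
#' Each target contig is split into fixed-size blocks and every interval is
#' registered in all blocks it overlaps.  A point query collects the
#' candidate intervals of the point's block and filters them to exact
#' overlap, so answers are independent of the block size.
#'
#' @param intervals data.frame with columns `target_id`, `start`, `end`,
#'   `read_id` as returned by [extend_mapping()].
#' @param block_size Block length in bp (default 10000).
#' @return A `block_index` object.
#' @export
build_block_index <- function(intervals, block_size = 10000) {
  stopifnot(block_size > 0)
  iv <- data.table::as.data.table(intervals[c("target_id", "start", "end", "read_id")])
  if (nrow(iv) > 0L) {
    stopifnot(all(iv$end > iv$start), all(iv$start >= 0))
    b0 <- iv$start %/% block_size
    b1 <- (iv$end - 1) %/% block_size
    nblk <- as.integer(b1 - b0 + 1)
    blocks <- data.table::data.table(
      target_id = rep(iv$target_id, nblk),
      block = unlist(lapply(seq_len(nrow(iv)), function(i) b0[i]:b1[i])),
      idx = rep(seq_len(nrow(iv)), nblk))
  } else {
    blocks <- data.table::data.table(target_id = character(0), block = numeric(0),
                                     idx = integer(0))
  }
  data.table::setkey(blocks, target_id, block)
  structure(list(block_size = block_size, intervals = iv, blocks = blocks),
            class = "block_index")
}

#' Point-query a block index
#'
#' @param index A `block_index`.
#' @param target_id Contig name (scalar).
#' @param pos 0-based position (scalar).
#' @return Character vector of `read_id`s whose extended interval contains
#'   `pos` (half-open: an interval `[s, e)` contains `pos` iff
#'   `s <= pos < e`).
#' @export
query_block_index <- function(index, target_id, pos) {
  stopifnot(inherits(index, "block_index"), length(target_id) == 1L, length(pos) == 1L)
  hits <- query_block_index_many(index,
                                 data.frame(target_id = target_id, pos = pos,
                                            stringsAsFactors = FALSE))
  hits$read_id
}

# Vectorised form: `queries` has columns target_id, pos; returns a data.table
# (query row index `qi`, read_id), one row per containing interval.
query_block_index_many <- function(index, queries) {
  q <- data.table::data.table(target_id = queries$target_id,
                              block = queries$pos %/% index$block_size,
                              pos = queries$pos,
                              qi = seq_len(nrow(queries)))
  j <- index$blocks[q, on = c("target_id", "block"), nomatch = NULL,
                    allow.cartesian = TRUE]
  if (nrow(j) == 0L) {
    return(data.table::data.table(qi = integer(0), read_id = character(0)))
  }
  iv <- index$intervals
  keep <- iv$start[j$idx] <= j$pos & j$pos < iv$end[j$idx]
  data.table::data.table(qi = j$qi[keep], read_id = iv$read_id[j$idx[keep]])
}

#' Colour reads from linkage-map markers
#'
#' For every marker in the map, each read whose extended interval contains
#' the marker position gains the packed colour of the marker's bin.  Reads
#' overlapping no marker keep an empty colour set.  Markers on contigs
#' absent from the index are skipped with a warning (their count is kept in
#' the `skipped_markers` attribute).
#'
#' @param index A `block_index` over extended read intervals.
#' @param map A `linkage_map`.
#' @return A `read_colouring`: named list mapping every indexed `read_id`
#'   to a sorted numeric vector of packed colours (possibly empty).
#' @export
colour_reads <- function(index, map) {
  stopifnot(inherits(index, "block_index"), inherits(map, "linkage_map"))
  m <- map$markers
  known <- m$contig %in% unique(index$intervals$target_id)
  n_skip <- sum(!known)
  if (n_skip > 0L) {
    warning(n_skip, " marker(s) on contigs absent from the mapping index were skipped")
  }
  m <- m[known, , drop = FALSE]
  reads <- unique(index$intervals$read_id)
  sets <- stats::setNames(rep(list(numeric(0)), length(reads)), reads)
  if (nrow(m) > 0L) {
    hits <- query_block_index_many(index, data.frame(target_id = m$contig,
                                                     pos = m$pos,
                                                     stringsAsFactors = FALSE))
    if (nrow(hits) > 0L) {
      pairs <- data.table::data.table(read_id = hits$read_id,
                                      col = m$colour[hits$qi])
      pairs <- unique(pairs)
      got <- split(pairs$col, pairs$read_id)
      got <- lapply(got, sort)
      sets[names(got)] <- got
    }
  }
  structure(sets, class = "read_colouring", skipped_markers = n_skip)
}

#' Colour reads from a mapping PAF in one step
#'
#' Convenience wrapper: keeps each read's longest mapping, stretches it
#' (capped at `cap` bp per side), indexes the stretched intervals in
#' `block_size` blocks, and colours the reads from the map's markers.
#'
#' @param paf data.frame of read-to-draft mappings as from [read_paf()].
#' @param map A `linkage_map`.
#' @param cap Extension cap per side in bp (default 250).
#' @param block_size Block index granularity in bp (default 10000; the
#'   colouring is independent of this value).
#' @return A `read_colouring`.
#' @export
colour_from_mappings <- function(paf, map, cap = 250, block_size = 10000) {
  best <- select_longest_per_read(paf)
  iv <- extend_mapping(best, cap = cap)
  idx <- build_block_index(iv, block_size = block_size)
  colour_reads(idx, map)
}

#' Write / load a read colouring as TSV
#'
#' Two columns: `read_id` and the comma-separated packed colours (empty
#' field for uncoloured reads).
#'
#' @param colouring A `read_colouring` (named list of packed colour vectors).
#' @param path File path.
#' @return `write_colouring()`: `path` invisibly; `load_colouring()`: a
#'   `read_colouring`.
#' @export
write_colouring <- function(colouring, path) {
  ids <- names(colouring)
  o <- order(ids)
  lines <- sprintf("%s\t%s", ids[o],
                   vapply(colouring[o], format_colours, ""))
  writeLines(c("#read_id\tcolours", lines), path)
  invisible(path)
}

#' @rdname write_colouring
#' @export
load_colouring <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) {
    return(structure(stats::setNames(list(), character(0)), class = "read_colouring"))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1L)
  cols <- lapply(parts, function(p) if (length(p) >= 2L) parse_colours(p[[2L]]) else numeric(0))
  structure(stats::setNames(cols, ids), class = "read_colouring")
}
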