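# Truth-based evaluation: classify read colourings against each read's
# acceptable colour range, and graph edges as genomic or spurious by
# whether the two reads' true intervals overlap in the genome.

#' Classify read colourings against their acceptable ranges
#'
#' A read is *inside* when it has colours and every one lies within its
#' acceptable range, *outside* when it has colours and none does,
#' *partial* otherwise, and *uncoloured* when its colour set is empty.
#' Percentages are relative to all reads in `truth`.
#'
#' @param colouring A `read_colouring`.
#' @param map A `linkage_map`.
#' @param truth Truth data.frame from [simulate_reads()].
#' @return data.frame with columns `category`, `reads`, `pct`.
#' @export
evaluate_colouring <- function(colouring, map, truth) {
  rng <- acceptable_colour_range(truth, map)
  sets <- colouring[rng$read_id]
  sets[vapply(sets, is.null, logical(1))] <- list(numeric(0))
  nin <- vapply(seq_len(nrow(rng)), function(i) {
    sum(sets[[i]] >= rng$low[i] & sets[[i]] <= rng$high[i])
  }, 0)
  ntot <- lengths(sets)
  category <- ifelse(ntot == 0L, "uncoloured",
                     ifelse(nin == ntot, "inside",
                            ifelse(nin == 0L, "outside", "partial")))
  counts <- table(factor(category, levels = c("inside", "partial", "outside",
                                              "uncoloured")))
  data.frame(category = names(counts), reads = as.integer(counts),
             pct = 100 * as.integer(counts) / nrow(truth),
             stringsAsFactors = FALSE)
}

# Genomic / spurious flag per undirected link of the graph: a link is
# genomic when the two reads' truth intervals share the chromosome and
# overlap by at least one bp.
classify_links <- function(graph, truth) {
  e <- graph$edges
  if (nrow(e) == 0L) {
    return(data.frame(a = character(0), b = character(0), genomic = logical(0),
                      stringsAsFactors = FALSE))
  }
  a <- pmin(e$from_id, e$to_id)
  b <- pmax(e$from_id, e$to_id)
  first <- !duplicated(paste(a, b, sep = "\r"))
  a <- a[first]; b <- b[first]
  ia <- match(a, truth$read_id)
  ib <- match(b, truth$read_id)
  if (anyNA(ia) || anyNA(ib)) {
    stop("evaluation error: graph contains read(s) without truth records")
  }
  genomic <- truth$chrom[ia] == truth$chrom[ib] &
    pmin(truth$end[ia], truth$end[ib]) > pmax(truth$start[ia], truth$start[ib])
  data.frame(a = a, b = b, genomic = genomic, stringsAsFactors = FALSE)
}

#' Classify graph edges as genomic or spurious against the truth
#'
#' A link (an edge and its mirror, counted once) is *genomic* when the two
#' reads' true intervals overlap in the genome by at least one bp, and
#' *spurious* otherwise.  Works on any graph stage (raw or cleaned).
#'
#' @param graph A `coloured_overlap_graph`.
#' @param truth Truth data.frame covering every read in the graph.
#' @return data.frame with columns `category` (`genomic`/`spurious`),
#'   `links`, `pct`.
#' @export
evaluate_edges <- function(graph, truth) {
  cls <- classify_links(graph, truth)
  n <- nrow(cls)
  ngen <- sum(cls$genomic)
  data.frame(category = c("genomic", "spurious"),
             links = c(ngen, n - ngen),
             pct = if (n > 0) 100 * c(ngen, n - ngen) / n else c(NA_real_, NA_real_),
             stringsAsFactors = FALSE)
}

#' Evaluate a colouring and a graph stage against the simulation truth
#'
#' @param colouring A `read_colouring`, or `NULL` to skip.
#' @param graph A `coloured_overlap_graph`, or `NULL` to skip.
#' @param map A `linkage_map` (needed for the colouring part).
#' @param truth Truth data.frame from [simulate_reads()].
#' @return List with elements `colouring` and `edges` (either may be
#'   `NULL`), as returned by [evaluate_colouring()] and
#'   [evaluate_edges()].
#' @export
evaluate_against_truth <- function(colouring = NULL, graph = NULL, map = NULL,
                                   truth) {
  out <- list(colouring = NULL, edges = NULL)
  if (!is.null(colouring)) {
    stopifnot(!is.null(map))
    out$colouring <- evaluate_colouring(colouring, map, truth)
  }
  if (!is.null(graph)) {
    out$edges <- evaluate_edges(graph, truth)
  }
  out
}
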