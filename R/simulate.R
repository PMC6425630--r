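# Synthetic study data with known truth: a repeat-free multi-chromosome
# genome, a dense linkage map at realistic marker/bin densities, long reads
# with recorded origins, their true alignments, and true suffix-prefix
# overlaps with optional injected spurious overlaps.  The genome doubles as
# its own draft assembly, which isolates the colouring and cleaning steps
# from draft quality.

#' Simulate a random genome and a dense linkage map on it
#'
#' Chromosome sequences are uniform random bases (no engineered repeats).
#' Markers are placed uniformly at random; a marker closer than
#' `bin_spacing` bp to the previous marker joins the previous marker's
#' bin, so consecutive bins are at least `bin_spacing` bp apart.  Defaults
#' reproduce the densities of real dense maps: 0.008 markers/bp and, with
#' 200 bp bin spacing, about 0.002 bins/bp.  Bin ordinals follow genomic
#' position, and the genome's chromosomes serve directly as the draft
#' contigs the markers live on.
#'
#' @param n_chrom Number of chromosomes (default 2).
#' @param chrom_len Length of each chromosome in bp (default 1e6; may be a
#'   vector of length `n_chrom`).
#' @param marker_density Markers per bp (default 0.008).
#' @param bin_spacing Minimum distance between consecutive bins in bp
#'   (default 200).
#' @param seed Optional RNG seed for reproducibility.
#' @return List with elements `genome` (a `sim_genome`: named chromosome
#'   sequences plus the seed) and `map` (a `linkage_map`).
#' @export
simulate_genome_and_map <- function(n_chrom = 2, chrom_len = 1e6,
                                    marker_density = 0.008, bin_spacing = 200,
                                    seed = NULL) {
  stopifnot(n_chrom >= 1, all(chrom_len >= 1), bin_spacing >= 1)
  chrom_len <- rep_len(chrom_len, n_chrom)
  if (any(marker_density * chrom_len < 1)) {
    stop("parameter error: marker_density * chrom_len must be at least 1")
  }
  if (!is.null(seed)) set.seed(seed)
  chroms <- sprintf("chr%d", seq_len(n_chrom))
  seqs <- vapply(chrom_len, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, "")
  names(seqs) <- chroms

  marker_list <- vector("list", n_chrom)
  bin_list <- vector("list", n_chrom)
  for (i in seq_len(n_chrom)) {
    n_mark <- max(1L, round(marker_density * chrom_len[i]))
    pos <- sort(sample.int(chrom_len[i], n_mark)) - 1
    new_bin <- c(TRUE, diff(pos) >= bin_spacing)
    ordinal <- cumsum(new_bin) - 1L
    bin_id <- sprintf("%s_b%06d", chroms[i], unique(ordinal))
    marker_list[[i]] <- data.frame(contig = chroms[i], pos = pos,
                                   bin_id = sprintf("%s_b%06d", chroms[i], ordinal),
                                   stringsAsFactors = FALSE)
    bin_list[[i]] <- data.frame(bin_id = bin_id, chromosome = chroms[i],
                                chrom_index = i - 1L, ordinal = unique(ordinal),
                                stringsAsFactors = FALSE)
  }
  map <- new_linkage_map(do.call(rbind, marker_list), do.call(rbind, bin_list))
  genome <- structure(list(sequences = seqs, seed = seed), class = "sim_genome")
  list(genome = genome, map = map)
}

#' @export
print.sim_genome <- function(x, ...) {
  cat(sprintf("sim_genome: %d chromosome(s), %.0f bp\n",
              length(x$sequences), sum(nchar(x$sequences))))
  invisible(x)
}

# Apply insertion-biased sequencing errors to one sequence.  Per base the
# error probability is `rate`; error types are drawn with the long-read mix
# insertion:deletion:substitution = 6:2:2.
apply_read_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  err <- which(stats::runif(n) < rate)
  if (length(err) == 0L) return(seq)
  x <- strsplit(seq, "", fixed = TRUE)[[1]]
  type <- sample(c("ins", "del", "sub"), length(err), replace = TRUE,
                 prob = c(0.6, 0.2, 0.2))
  bases <- c("A", "C", "G", "T")
  ins <- err[type == "ins"]
  if (length(ins) > 0L) {
    x[ins] <- paste0(x[ins], sample(bases, length(ins), replace = TRUE))
  }
  del <- err[type == "del"]
  if (length(del) > 0L) x[del] <- ""
  sub <- err[type == "sub"]
  if (length(sub) > 0L) {
    shift <- sample.int(3L, length(sub), replace = TRUE)
    x[sub] <- bases[(match(x[sub], bases) - 1L + shift) %% 4L + 1L]
  }
  paste(x, collapse = "")
}

#' Simulate long reads with known origins
#'
#' Read start positions are uniform over each chromosome, lengths are
#' normal with mean `mean_len` and sd `len_sd` truncated to
#' `[min_len, chrom_len]`, strands are random, and per-base errors follow
#' an insertion-biased mix (insertion:deletion:substitution = 6:2:2).
#' Every read carries exactly one truth record giving its chromosome,
#' 0-based half-open genomic interval and strand.
#'
#' @param genome A `sim_genome`.
#' @param coverage Target sequencing depth (default 40).
#' @param mean_len,len_sd Read length distribution in bp (defaults 15000
#'   and 1500).
#' @param error_rate Per-base error probability (default 0.1).
#' @param seed Optional RNG seed.
#' @param min_len Lower truncation of read lengths (default 500).
#' @return List with `reads` (named character vector of read sequences)
#'   and `truth` (data.frame: `read_id`, `chrom`, `start`, `end`,
#'   `strand`, `span` = genomic extent, `read_len` = sequence length after
#'   errors).
#' @export
simulate_reads <- function(genome, coverage = 40, mean_len = 15000,
                           len_sd = 1500, error_rate = 0.1, seed = NULL,
                           min_len = 500) {
  stopifnot(inherits(genome, "sim_genome"), coverage > 0)
  if (!is.null(seed)) set.seed(seed)
  chroms <- names(genome$sequences)
  clen <- nchar(genome$sequences)
  stopifnot(mean_len < max(clen))

  truth_list <- list()
  seq_list <- list()
  n_total <- 0L
  for (i in seq_along(chroms)) {
    n <- max(1L, round(coverage * clen[i] / mean_len))
    l <- pmin(clen[i], pmax(min_len, round(stats::rnorm(n, mean_len, len_sd))))
    start <- floor(stats::runif(n) * (clen[i] - l + 1))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    ids <- sprintf("read%06d", n_total + seq_len(n))
    n_total <- n_total + n
    raw <- substring(genome$sequences[i], start + 1, start + l)
    minus <- strand == "-"
    if (any(minus)) raw[minus] <- revcomp(raw[minus])
    if (error_rate > 0) {
      raw <- vapply(raw, apply_read_errors, "", rate = error_rate,
                    USE.NAMES = FALSE)
    }
    truth_list[[i]] <- data.frame(read_id = ids, chrom = chroms[i],
                                  start = start, end = start + l,
                                  strand = strand, span = l,
                                  read_len = nchar(raw),
                                  stringsAsFactors = FALSE)
    seq_list[[i]] <- stats::setNames(raw, ids)
  }
  truth <- do.call(rbind, truth_list)
  rownames(truth) <- NULL
  list(reads = do.call(c, seq_list), truth = truth)
}

#' Write / load simulation truth records as TSV
#'
#' @param truth Truth data.frame from [simulate_reads()].
#' @param path File path.
#' @return `write_truth()`: `path` invisibly; `load_truth()`: the
#'   data.frame.
#' @export
write_truth <- function(truth, path) {
  data.table::fwrite(truth, path, sep = "\t")
  invisible(path)
}

#' @rdname write_truth
#' @export
load_truth <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t",
                                  colClasses = list(character = c("read_id", "chrom", "strand"))))
}

#' Emit the true read-to-draft alignments as PAF
#'
#' One record per read, spanning the whole read and its true genomic
#' interval, with the simulated genome as the draft assembly.
#'
#' @param truth Truth data.frame from [simulate_reads()].
#' @param chrom_lengths Named numeric vector of chromosome lengths (e.g.
#'   `nchar(genome$sequences)`).
#' @return PAF data.frame as from [read_paf()].
#' @export
emit_true_alignments <- function(truth, chrom_lengths) {
  n <- nrow(truth)
  data.frame(qname = truth$read_id, qlen = truth$read_len,
             qstart = rep(0, n), qend = truth$read_len,
             strand = truth$strand, tname = truth$chrom,
             tlen = as.numeric(chrom_lengths[truth$chrom]),
             tstart = truth$start, tend = truth$end,
             nmatch = truth$span, alnlen = truth$span, mapq = rep(60, n),
             stringsAsFactors = FALSE)
}

# Map a genomic sub-interval [s, e) of a read's truth interval into the
# read's own (stored-orientation) coordinates, in genomic-span units.
interval_on_read <- function(tr_start, tr_end, strand, s, e) {
  if (strand == "+") c(s - tr_start, e - tr_start) else c(tr_end - e, tr_end - s)
}

#' Emit true suffix-prefix overlaps, optionally with injected spurious ones
#'
#' True overlaps: one PAF record per read pair whose truth intervals
#' overlap by at least `min_overlap` bp (coordinates are expressed in
#' genomic-span units, so the records are exact for error-free reads and
#' approximate otherwise, as real overlapper output is).  Spurious
#' overlaps: `spurious_n` additional dovetail records joining read pairs
#' whose acceptable colour ranges are at least `min_sep_bins` bins apart
#' or on different chromosomes.
#'
#' @param truth Truth data.frame from [simulate_reads()].
#' @param min_overlap Minimum true overlap emitted, in bp (default 2000).
#' @param spurious_n Number of spurious records to inject (default 0).
#' @param min_sep_bins Minimum bin separation of spurious pairs
#'   (default 5).
#' @param map `linkage_map`, required when `spurious_n > 0`.
#' @param seed Optional RNG seed for the spurious pair sampling.
#' @return PAF data.frame; the injected records are flagged in the
#'   attribute `spurious_pairs` (data.frame of read id pairs).
#' @export
emit_overlaps <- function(truth, min_overlap = 2000, spurious_n = 0,
                          min_sep_bins = 5, map = NULL, seed = NULL) {
  stopifnot(min_overlap >= 1)
  recs <- list()
  for (ch in unique(truth$chrom)) {
    tr <- truth[truth$chrom == ch, , drop = FALSE]
    tr <- tr[order(tr$start, tr$read_id), , drop = FALSE]
    n <- nrow(tr)
    if (n < 2L) next
    # read j (starting later) overlaps read i by >= min_overlap
    last_j <- findInterval(tr$end - min_overlap, tr$start)
    i_idx <- rep(seq_len(n), pmax(0L, last_j - seq_len(n)))
    j_idx <- unlist(lapply(seq_len(n), function(i) {
      if (last_j[i] > i) (i + 1L):last_j[i] else integer(0)
    }))
    if (length(i_idx) == 0L) next
    o_start <- tr$start[j_idx]
    o_end <- pmin(tr$end[i_idx], tr$end[j_idx])
    ok <- o_end - o_start >= min_overlap
    i_idx <- i_idx[ok]; j_idx <- j_idx[ok]
    o_start <- o_start[ok]; o_end <- o_end[ok]
    if (length(i_idx) == 0L) next
    qa <- t(vapply(seq_along(i_idx), function(k) {
      interval_on_read(tr$start[i_idx[k]], tr$end[i_idx[k]], tr$strand[i_idx[k]],
                       o_start[k], o_end[k])
    }, numeric(2)))
    qb <- t(vapply(seq_along(j_idx), function(k) {
      interval_on_read(tr$start[j_idx[k]], tr$end[j_idx[k]], tr$strand[j_idx[k]],
                       o_start[k], o_end[k])
    }, numeric(2)))
    recs[[ch]] <- data.frame(
      qname = tr$read_id[i_idx], qlen = tr$span[i_idx],
      qstart = qa[, 1], qend = qa[, 2],
      strand = ifelse(tr$strand[i_idx] == tr$strand[j_idx], "+", "-"),
      tname = tr$read_id[j_idx], tlen = tr$span[j_idx],
      tstart = qb[, 1], tend = qb[, 2],
      nmatch = o_end - o_start, alnlen = o_end - o_start, mapq = 255,
      stringsAsFactors = FALSE)
  }
  paf <- if (length(recs) > 0L) do.call(rbind, recs) else
    emit_true_alignments(truth[0, , drop = FALSE], numeric(0))
  rownames(paf) <- NULL

  spur_pairs <- data.frame(a = character(0), b = character(0),
                           stringsAsFactors = FALSE)
  if (spurious_n > 0) {
    if (is.null(map)) stop("a linkage map is required to inject spurious overlaps")
    if (!is.null(seed)) set.seed(seed)
    rng <- acceptable_colour_range(truth, map)
    rng <- rng[match(truth$read_id, rng$read_id), ]
    picked <- character(0)
    out <- list()
    tries <- 0L
    max_tries <- 1000L * spurious_n
    while (length(out) < spurious_n && tries < max_tries) {
      tries <- tries + 1L
      ij <- sample.int(nrow(truth), 2L)
      i <- ij[1]; j <- ij[2]
      same_chrom <- truth$chrom[i] == truth$chrom[j]
      sep_ok <- if (!same_chrom) TRUE else {
        gap <- max(rng$low[j] - rng$high[i], rng$low[i] - rng$high[j])
        gap >= min_sep_bins
      }
      if (!sep_ok) next
      key <- paste(sort(truth$read_id[c(i, j)]), collapse = "\r")
      if (key %in% picked) next
      o <- min(3000, floor(0.8 * min(truth$span[i], truth$span[j])))
      o <- max(o, min_overlap)
      if (o >= min(truth$span[i], truth$span[j])) next
      picked <- c(picked, key)
      out[[length(out) + 1L]] <- data.frame(
        qname = truth$read_id[i], qlen = truth$span[i],
        qstart = truth$span[i] - o, qend = truth$span[i], strand = "+",
        tname = truth$read_id[j], tlen = truth$span[j],
        tstart = 0, tend = o, nmatch = o, alnlen = o, mapq = 255,
        stringsAsFactors = FALSE)
    }
    if (length(out) < spurious_n) {
      stop("could not find ", spurious_n, " read pairs at least ", min_sep_bins,
           " bins apart to inject spurious overlaps")
    }
    spur <- do.call(rbind, out)
    spur_pairs <- data.frame(a = spur$qname, b = spur$tname,
                             stringsAsFactors = FALSE)
    paf <- rbind(paf, spur)
  }
  attr(paf, "spurious_pairs") <- spur_pairs
  paf
}

#' Acceptable colour range of each read given its true origin
#'
#' The lower limit is the colour of the last marker at or before the
#' read's true start; the upper limit is the colour of the first marker at
#' or after its true end.  Reads hanging over a chromosome end clamp to
#' the chromosome's first or last bin.
#'
#' @param truth Truth data.frame (any subset of rows).
#' @param map A `linkage_map` whose marker contigs are the truth
#'   chromosomes.
#' @return data.frame with columns `read_id`, `low`, `high` (packed
#'   colours, `low <= high`, same chromosome).
#' @export
acceptable_colour_range <- function(truth, map) {
  stopifnot(inherits(map, "linkage_map"))
  out_low <- numeric(nrow(truth))
  out_high <- numeric(nrow(truth))
  for (ch in unique(truth$chrom)) {
    sel <- truth$chrom == ch
    m <- map$markers[map$markers$contig == ch, , drop = FALSE]
    if (nrow(m) == 0L) stop("no markers on chromosome '", ch, "'")
    o <- order(m$pos)
    mpos <- m$pos[o]
    mcol <- m$colour[o]
    i_low <- findInterval(truth$start[sel], mpos)          # last marker pos <= start
    i_high <- findInterval(truth$end[sel] - 0.5, mpos) + 1 # first marker pos >= end
    out_low[sel] <- mcol[pmax(1L, i_low)]
    out_high[sel] <- mcol[pmin(length(mcol), i_high)]
  }
  data.frame(read_id = truth$read_id, low = pmin(out_low, out_high),
             high = pmax(out_low, out_high), stringsAsFactors = FALSE)
}
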