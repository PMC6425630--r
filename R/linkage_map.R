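# Linkage maps: markers localised on draft contigs, grouped into bins,
# bins ordered within chromosomes.  The bin order is the long-range
# positional signal everything downstream consumes, via packed colours.

#' Construct a linkage map from marker and bin tables
#'
#' Low-level constructor used by [load_linkage_map()] and the simulator.
#' No invariant checking is performed here; use [validate_map()].
#'
#' @param markers data.frame with columns `contig`, `pos` (0-based),
#'   `bin_id`.
#' @param bins data.frame with columns `bin_id`, `chromosome`,
#'   `chrom_index` (0-based), `ordinal` (0-based within chromosome).
#' @return A `linkage_map` object: list with elements `markers` (markers
#'   plus their packed `colour`), `bins` (bins plus `colour`) and
#'   `chromosomes` (character vector in index order).
#' @export
new_linkage_map <- function(markers, bins) {
  stopifnot(all(c("contig", "pos", "bin_id") %in% names(markers)),
            all(c("bin_id", "chromosome", "chrom_index", "ordinal") %in% names(bins)))
  bins <- as.data.frame(bins, stringsAsFactors = FALSE)
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  bins$colour <- colour(bins$chrom_index, bins$ordinal)
  idx <- match(markers$bin_id, bins$bin_id)
  markers$colour <- bins$colour[idx]
  chroms <- bins$chromosome[!duplicated(bins$chrom_index)]
  chroms <- chroms[order(unique(bins$chrom_index))]
  structure(list(markers = markers, bins = bins, chromosomes = chroms),
            class = "linkage_map")
}

#' Load a linkage map from a marker table
#'
#' The file is a tab-separated table with four columns: draft contig,
#' 1-based marker position, chromosome label, and bin identifier.  Lines
#' starting with `#` are comments.  Positions are converted to 0-based
#' internally.  Bin ordinals are assigned by first appearance within each
#' chromosome, and chromosome indices by first appearance in the file, so
#' the file itself is the order authority.
#'
#' @param path Path to the marker table.
#' @return A `linkage_map` object.
#' @seealso [write_linkage_map()], [validate_map()]
#' @export
load_linkage_map <- function(path) {
  if (!file.exists(path)) stop("linkage map file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty linkage map: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    bad <- lineno[which(nf < 4L)[1]]
    stop("malformed linkage map line ", bad, ": expected 4 tab-separated columns")
  }
  contig <- vapply(fields, `[[`, "", 1L)
  pos1 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  chromosome <- vapply(fields, `[[`, "", 3L)
  bin_id <- vapply(fields, `[[`, "", 4L)
  if (anyNA(pos1) || any(pos1 < 1)) {
    bad <- lineno[which(is.na(pos1) | pos1 < 1)[1]]
    stop("malformed linkage map line ", bad, ": position must be a 1-based integer")
  }
  if (anyDuplicated(paste(contig, pos1))) {
    stop("linkage map consistency error: duplicate (contig, pos) marker")
  }
  chrom_of_bin <- tapply(chromosome, bin_id, function(x) length(unique(x)))
  if (any(chrom_of_bin > 1L)) {
    stop("linkage map consistency error: bin '",
         names(chrom_of_bin)[which(chrom_of_bin > 1L)[1]],
         "' is assigned to more than one chromosome")
  }

  chroms <- unique(chromosome)
  first_bin <- !duplicated(bin_id)
  bins <- data.frame(bin_id = bin_id[first_bin],
                     chromosome = chromosome[first_bin],
                     stringsAsFactors = FALSE)
  bins$chrom_index <- match(bins$chromosome, chroms) - 1L
  ord <- integer(nrow(bins))
  for (ci in unique(bins$chrom_index)) {
    sel <- bins$chrom_index == ci
    ord[sel] <- seq_len(sum(sel)) - 1L
  }
  bins$ordinal <- ord
  markers <- data.frame(contig = contig, pos = pos1 - 1, bin_id = bin_id,
                        stringsAsFactors = FALSE)
  new_linkage_map(markers, bins)
}

#' Write a linkage map back to its 4-column tab-separated form
#'
#' Inverse of [load_linkage_map()]: positions are written 1-based, markers
#' in their stored order, so `load_linkage_map(write_linkage_map(m))`
#' reproduces `m`.
#'
#' @param map A `linkage_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_linkage_map <- function(map, path) {
  stopifnot(inherits(map, "linkage_map"))
  m <- map$markers
  chromosome <- map$bins$chromosome[match(m$bin_id, map$bins$bin_id)]
  out <- sprintf("%s\t%d\t%s\t%s", m$contig, as.integer(m$pos) + 1L,
                 chromosome, m$bin_id)
  writeLines(c("#contig\tpos\tchromosome\tbin_id", out), path)
  invisible(path)
}

#' Validate a linkage map against its invariants
#'
#' Checks that every marker resolves to a known bin and (when contig
#' lengths are supplied) lies inside its contig, that (chromosome,
#' ordinal) pairs are unique and ordinals run 0,1,2,... within every
#' chromosome, and that no two markers share a (contig, pos).  Bins whose
#' markers sit on several draft contigs are legitimate (draft contigs are
#' unordered fragments) and are reported at level `"info"` only.
#'
#' @param map A `linkage_map`.
#' @param draft_lengths Optional named numeric vector of contig lengths.
#' @return data.frame of violations with columns `contig`, `pos`, `rule`,
#'   `level` (`"error"` or `"info"`) and `message`; zero rows when the map
#'   is clean.
#' @export
validate_map <- function(map, draft_lengths = NULL) {
  stopifnot(inherits(map, "linkage_map"))
  v <- list()
  add <- function(contig, pos, rule, level, message) {
    v[[length(v) + 1L]] <<- data.frame(contig = contig, pos = pos, rule = rule,
                                       level = level, message = message,
                                       stringsAsFactors = FALSE)
  }
  m <- map$markers
  b <- map$bins

  missing_bin <- !(m$bin_id %in% b$bin_id)
  for (i in which(missing_bin)) {
    add(m$contig[i], m$pos[i], "unknown_bin", "error",
        sprintf("marker bin '%s' is not in the bin table", m$bin_id[i]))
  }
  dup <- duplicated(paste(m$contig, m$pos))
  for (i in which(dup)) {
    add(m$contig[i], m$pos[i], "duplicate_marker", "error",
        "two markers share this (contig, pos)")
  }
  if (!is.null(draft_lengths)) {
    len <- draft_lengths[m$contig]
    oob <- !is.na(len) & (m$pos < 0 | m$pos >= len)
    for (i in which(oob)) {
      add(m$contig[i], m$pos[i], "out_of_range", "error",
          sprintf("marker position %d outside contig of length %d",
                  as.integer(m$pos[i]), as.integer(len[i])))
    }
    unk <- is.na(len)
    for (i in which(unk)) {
      add(m$contig[i], m$pos[i], "unknown_contig", "error",
          sprintf("contig '%s' absent from the draft assembly", m$contig[i]))
    }
  }
  if (anyDuplicated(paste(b$chromosome, b$ordinal))) {
    i <- which(duplicated(paste(b$chromosome, b$ordinal)))[1]
    add(NA_character_, NA_real_, "duplicate_ordinal", "error",
        sprintf("chromosome '%s' has two bins with ordinal %d",
                b$chromosome[i], as.integer(b$ordinal[i])))
  }
  for (chrom in unique(b$chromosome)) {
    o <- sort(b$ordinal[b$chromosome == chrom])
    if (!identical(as.integer(o), seq_along(o) - 1L)) {
      add(NA_character_, NA_real_, "non_consecutive_ordinals", "error",
          sprintf("chromosome '%s' bin ordinals are not consecutive from 0", chrom))
    }
  }
  multi <- tapply(m$contig, m$bin_id, function(x) length(unique(x)))
  for (bid in names(multi)[multi > 1L]) {
    add(NA_character_, NA_real_, "multi_contig_bin", "info",
        sprintf("bin '%s' has markers on %d draft contigs", bid,
                as.integer(multi[bid])))
  }
  if (length(v) == 0L) {
    return(data.frame(contig = character(), pos = numeric(), rule = character(),
                      level = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}

#' @export
print.linkage_map <- function(x, ...) {
  cat(sprintf("linkage_map: %d markers, %d bins, %d chromosome(s)\n",
              nrow(x$markers), nrow(x$bins), length(x$chromosomes)))
  invisible(x)
}
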