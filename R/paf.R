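# PAF input/output.  Only the 12 standard columns are used; optional SAM-style
# tags (including tp:A) are ignored.

PAF_COLS <- c("qname", "qlen", "qstart", "qend", "strand",
              "tname", "tlen", "tstart", "tend", "nmatch", "alnlen", "mapq")

#' Read a PAF mapping/overlap file
#'
#' Parses the 12 standard PAF columns (0-based, half-open coordinates);
#' any trailing tag columns are dropped.
#'
#' @param path Path to a PAF file.
#' @return data.frame with columns `qname, qlen, qstart, qend, strand,
#'   tname, tlen, tstart, tend, nmatch, alnlen, mapq`.
#' @export
read_paf <- function(path) {
  if (!file.exists(path)) stop("PAF file not found: ", path)
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                      colClasses = list(character = c(1, 5, 6))),
    error = function(e) stop("failed to parse PAF '", path, "': ", conditionMessage(e))
  )
  if (nrow(dt) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), 12), PAF_COLS))
    num <- setdiff(PAF_COLS, c("qname", "strand", "tname"))
    out[num] <- lapply(out[num], as.numeric)
    return(out)
  }
  if (ncol(dt) < 12L) stop("malformed PAF '", path, "': fewer than 12 columns")
  dt <- dt[, 1:12]
  data.table::setnames(dt, PAF_COLS)
  num <- setdiff(PAF_COLS, c("qname", "strand", "tname"))
  for (cn in num) data.table::set(dt, j = cn, value = suppressWarnings(as.numeric(dt[[cn]])))
  bad <- which(Reduce(`|`, lapply(num, function(cn) is.na(dt[[cn]]))) |
                 !(dt$strand %in% c("+", "-")))
  if (length(bad) > 0L) {
    stop("malformed PAF '", path, "' at line ", bad[1],
         ": non-numeric coordinate or bad strand")
  }
  as.data.frame(dt)
}

#' Write mappings/overlaps as PAF
#'
#' @param paf data.frame with the columns produced by [read_paf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(paf, path) {
  stopifnot(all(PAF_COLS %in% names(paf)))
  df <- paf[PAF_COLS]
  int_cols <- setdiff(PAF_COLS, c("qname", "strand", "tname"))
  df[int_cols] <- lapply(df[int_cols], function(x) format(x, scientific = FALSE, trim = TRUE))
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
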