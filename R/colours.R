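# Colour arithmetic.
#
# A colour is one linkage-map bin: a (chromosome index, bin ordinal) pair.
# Chromosomes are independent linear orders, so colours on different
# chromosomes are never comparable and never adjacent.  For storage in
# vectors and GFA tags a colour is packed into a single number as
# chromosome_index * 1e6 + ordinal; integer subtraction of packed colours
# then preserves cross-chromosome separation for any realistic distance d.

#' Chromosome stride of the packed colour encoding
#'
#' Colours are stored as `chromosome_index * colour_stride() + ordinal`.
#' No chromosome may carry `colour_stride()` or more bins.
#'
#' @return A single number, the encoding stride.
#' @export
colour_stride <- function() 1e6

#' Construct packed colours
#'
#' @param chromosome_index Integer vector, 0-based chromosome index.
#' @param ordinal Integer vector, 0-based bin ordinal within the chromosome.
#' @return Numeric vector of packed colours.
#' @examples
#' colour(0, 5)
#' colour(2, 0:3)
#' @export
colour <- function(chromosome_index, ordinal) {
  stopifnot(all(ordinal >= 0), all(ordinal < colour_stride()))
  as.numeric(chromosome_index) * colour_stride() + as.numeric(ordinal)
}

#' @rdname colour
#' @param col Numeric vector of packed colours.
#' @export
colour_chrom <- function(col) col %/% colour_stride()

#' @rdname colour
#' @export
colour_ordinal <- function(col) col %% colour_stride()

#' Are two colours within distance d of each other?
#'
#' Two colours are adjacent at distance `d` when they lie on the same
#' chromosome and their bin ordinals differ by at most `d`.  Colours from
#' different chromosomes are never adjacent, whatever `d`.
#'
#' @param c1,c2 Numeric vectors of packed colours (recycled together).
#' @param d Non-negative integer, the maximum ordinal distance.
#' @return Logical vector.
#' @examples
#' colours_adjacent(colour(0, 5), colour(0, 6), d = 1)  # TRUE
#' colours_adjacent(colour(0, 5), colour(1, 5), d = 1000)  # FALSE
#' @export
colours_adjacent <- function(c1, c2, d) {
  stopifnot(d >= 0)
  colour_chrom(c1) == colour_chrom(c2) & abs(c1 - c2) <= d
}

#' Format / parse packed colour lists for GFA and TSV tags
#'
#' Colour sets travel in `cl:Z:` tags as comma-separated packed integers.
#'
#' @param cols Numeric vector of packed colours.
#' @return `format_colours()`: a single string (empty for no colours);
#'   `parse_colours()`: a numeric vector.
#' @export
format_colours <- function(cols) {
  if (length(cols) == 0L) return("")
  paste(format(sort(cols), scientific = FALSE, trim = TRUE), collapse = ",")
}

#' @rdname format_colours
#' @param x A single string of comma-separated packed colours.
#' @export
parse_colours <- function(x) {
  if (is.na(x) || !nzchar(x)) return(numeric(0))
  sort(as.numeric(strsplit(x, ",", fixed = TRUE)[[1]]))
}
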