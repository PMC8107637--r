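#' Genomic interval (1-based, inclusive)
#'
#' Constructs a closed genomic interval in the 1-based, inclusive coordinate
#' convention used by VCF and by all printed coordinates in this package
#' (e.g. a whole-gene deletion \code{chr17:74818633-74888183}).
#'
#' @param chrom Chromosome label (e.g. \code{"chr17"}).
#' @param start First base of the interval (>= 1).
#' @param end Last base of the interval (>= \code{start}).
#'
#' @return An object of class \code{genomic_interval}: a list with elements
#'   \code{chrom}, \code{start}, \code{end}.
#' @examples
#' del <- genomic_interval("chr17", 74818633, 74888183)
#' interval_length(del)
#' @export
genomic_interval <- function(chrom, start, end) {
  stopifnot(length(chrom) == 1L, length(start) == 1L, length(end) == 1L)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (is.na(start) || is.na(end)) stop("interval coordinates must be numeric")
  if (start < 1) stop("interval start must be >= 1")
  if (end < start) stop("interval end (", end, ") must be >= start (", start, ")")
  structure(list(chrom = as.character(chrom), start = start, end = end),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:%s-%s (%s bp)\n", x$chrom,
              format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE),
              format(interval_length(x), scientific = FALSE)))
  invisible(x)
}

#' Length of an inclusive interval in base pairs
#'
#' For a 1-based inclusive interval the number of bases covered is
#' \code{end - start + 1}.
#'
#' @param x A \code{genomic_interval}.
#' @return Integer-valued length in bp.
#' @export
interval_length <- function(x) {
  stopifnot(inherits(x, "genomic_interval"))
  x$end - x$start + 1
}

#' Point-coordinate span of an interval
#'
#' The distance between the two boundary coordinates, \code{end - start}.
#' This is the convention used when a haplotype is said to "span" the
#' distance between its two boundary sites.
#'
#' @param x A \code{genomic_interval}.
#' @return Span in bp (difference of the two point coordinates).
#' @seealso [span_kb()]
#' @export
interval_span <- function(x) {
  stopifnot(inherits(x, "genomic_interval"))
  x$end - x$start
}

#' Does an interval contain a position?
#'
#' @param x A \code{genomic_interval}.
#' @param chrom Chromosome label of the query position.
#' @param pos Position(s), 1-based.
#' @return Logical vector, one element per position.
#' @export
interval_contains <- function(x, chrom, pos) {
  stopifnot(inherits(x, "genomic_interval"))
  chrom == x$chrom & pos >= x$start & pos <= x$end
}

#' Do two intervals overlap?
#'
#' @param x,y \code{genomic_interval} objects.
#' @return \code{TRUE} if they share a chromosome and at least one base.
#' @export
interval_overlaps <- function(x, y) {
  stopifnot(inherits(x, "genomic_interval"), inherits(y, "genomic_interval"))
  x$chrom == y$chrom && x$start <= y$end && y$start <= x$end
}

#' Parse "chrom:start-end" into a genomic_interval
#'
#' @param s A string like \code{"chr17:74818633-74888183"}.
#' @return A \code{genomic_interval}.
#' @export
parse_interval <- function(s) {
  stopifnot(length(s) == 1L, is.character(s))
  m <- regmatches(s, regexec("^([^:]+):([0-9]+)-([0-9]+)$", s))[[1]]
  if (length(m) != 4L) stop("cannot parse interval string: ", s)
  genomic_interval(m[2], as.numeric(m[3]), as.numeric(m[4]))
}
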