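#' Coordinate convention converters
#'
#' All coordinates inside the package are 1-based and inclusive, the native
#' convention of GTF, VCF, FASTA indexing and the Bioconductor ranges stack.
#' BED is the one external format using 0-based half-open intervals; these
#' two helpers convert at that boundary and are exact inverses of each other.
#'
#' @param start,end interval bounds. For `to_zero_based()` these are 1-based
#'   inclusive; for `to_one_based()` they are 0-based half-open.
#' @return a list with `start` and `end` in the other convention.
#' @examples
#' to_zero_based(100, 199) # list(start = 99, end = 199)
#' to_one_based(99, 199)   # list(start = 100, end = 199)
#' @export
to_zero_based <- function(start, end) {
  stopifnot(all(end >= start), all(start >= 1))
  list(start = start - 1L, end = end)
}

#' @rdname to_zero_based
#' @export
to_one_based <- function(start, end) {
  stopifnot(all(end > start), all(start >= 0))
  list(start = start + 1L, end = end)
}
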