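#' Unequal crossing over between two repeat arrays
#'
#' Applies a single (possibly unequal) homologous exchange between two tandem
#' arrays at the 0-based breakpoints `i` (in `a`) and `j` (in `b`). A
#' breakpoint of `i` means "keep the first `i` units"; `i` may run from 0
#' (keep nothing) to `length(a)` (keep everything). `i != j` is an unequal
#' alignment; `i == j` is an equal exchange that conserves both lengths.
#'
#' With `reciprocal = TRUE` both recombinant products are returned:
#' `a[0:i] + b[j:]` and `b[0:j] + a[i:]`. Their combined composition equals the
#' combined composition of the inputs exactly (copies are swapped, never
#' created or destroyed). With `reciprocal = FALSE` the exchange is a
#' unidirectional (non-reciprocal) transfer: only the single product
#' `a[0:i] + b[j:]` replaces the recipient `a`, while the donor `b` is
#' returned unchanged, so the combined composition may change — this is the
#' mechanism by which variant copies are gained or lost.
#'
#' Either product of an unequal exchange can be empty; viability selection on
#' array length is applied by the division operations, not here.
#'
#' @param a,b [repeat_array()] objects (recipient and donor chromatids).
#' @param i,j integer breakpoints, `0 <= i <= length(a)`, `0 <= j <= length(b)`.
#' @param reciprocal logical; reciprocal exchange (default) or unidirectional
#'   transfer.
#' @return A list of two `repeat_array` products. For a reciprocal exchange
#'   these are the two recombinants; for a non-reciprocal exchange the first
#'   element is the recombinant recipient and the second the unaltered donor.
#' @examples
#' p <- unequal_crossover(repeat_array(c("Z","Z","Z")),
#'                        repeat_array(c("Y","Y","Y")), i = 1, j = 2)
#' lapply(p, composition)
#' @export
unequal_crossover <- function(a, b, i, j, reciprocal = TRUE) {
  a <- as.character(a)
  b <- as.character(b)
  i <- check_breakpoint(i, length(a), "i")
  j <- check_breakpoint(j, length(b), "j")
  prod1 <- c(a[seq_len(i)], drop_head(b, j))
  if (reciprocal) {
    prod2 <- c(b[seq_len(j)], drop_head(a, i))
    list(repeat_array(prod1), repeat_array(prod2))
  } else {
    list(repeat_array(prod1), repeat_array(b))
  }
}

#' Gene conversion between aligned repeat arrays
#'
#' Non-reciprocal transfer of a tract of units from a donor array onto the
#' homologous positions of a recipient array. The recipient's length is
#' conserved (conversion never changes copy number, in contrast to unequal
#' crossing over) and the donor is untouched.
#'
#' @param donor,recipient [repeat_array()] objects aligned from their first
#'   unit.
#' @param start 0-based start of the converted tract.
#' @param tract_len tract length in units; `start + tract_len` must fit within
#'   both arrays. A zero-length tract leaves the recipient unchanged.
#' @return The recipient as a `repeat_array` with the tract overwritten by the
#'   donor's units.
#' @examples
#' gene_conversion(repeat_array(rep("Z", 4)), repeat_array(rep("Y", 4)),
#'                 start = 1, tract_len = 2) # Y Z Z Y
#' @export
gene_conversion <- function(donor, recipient, start, tract_len) {
  donor <- as.character(donor)
  recipient <- as.character(recipient)
  start <- as.integer(start)
  tract_len <- as.integer(tract_len)
  if (is.na(start) || start < 0L || is.na(tract_len) || tract_len < 0L)
    stop("start and tract_len must be non-negative integers", call. = FALSE)
  if (start + tract_len > length(donor) || start + tract_len > length(recipient))
    stop("conversion tract exceeds array bounds (start ", start,
         ", tract ", tract_len, ", donor ", length(donor),
         ", recipient ", length(recipient), ")", call. = FALSE)
  if (tract_len > 0L) {
    idx <- (start + 1L):(start + tract_len)
    recipient[idx] <- donor[idx]
  }
  repeat_array(recipient)
}

check_breakpoint <- function(x, len, what) {
  x <- as.integer(x)
  if (length(x) != 1L || is.na(x) || x < 0L || x > len)
    stop("breakpoint ", what, " must lie in [0, ", len, "]", call. = FALSE)
  x
}

drop_head <- function(x, k) {
  if (k < length(x)) x[(k + 1L):length(x)] else character(0)
}
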