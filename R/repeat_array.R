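#' Tandem repeat arrays of ITS variant units
#'
#' An rDNA cistron locus is modelled as an ordered head-to-tail tandem array of
#' repeat units, each unit carrying a variant label (canonically `"Z"` and
#' `"Y"`, the two ITS sequence types). The order of units matters: unequal
#' crossover outcomes depend on breakpoint positions within the array, so the
#' array is stored as a label sequence and compositions are derived views.
#'
#' A zero-length array is representable (it is the degenerate product of an
#' extreme unequal exchange) but corresponds to a non-viable cell state:
#' [composition()] refuses it, and the division operations in the life-cycle
#' simulator never return one.
#'
#' @param units character vector of unit labels, 5' to 3'. Labels must be
#'   non-empty strings; more than two distinct labels are allowed.
#' @return An object of class `repeat_array` (a character vector of labels).
#' @examples
#' a <- repeat_array(rep(c("Z", "Y"), c(55, 5)))
#' composition(a)
#' @seealso [composition()], [unequal_crossover()], [gene_conversion()]
#' @export
repeat_array <- function(units = character()) {
  units <- as.character(units)
  if (anyNA(units) || any(!nzchar(units)))
    stop("repeat unit labels must be non-empty strings", call. = FALSE)
  structure(units, class = "repeat_array")
}

#' @export
print.repeat_array <- function(x, ...) {
  cat("<repeat_array> ", length(x), " units\n", sep = "")
  if (length(x) > 0) {
    comp <- composition(x)
    cat("  composition: ",
        paste0(names(comp), ":", comp, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Variant composition of a repeat array
#'
#' Counts the units of each variant type in an array. The total always equals
#' the array length, so compositions are a lossless summary for statistics
#' that ignore unit order (clone sampling, ratio tests).
#'
#' @param array a [repeat_array()] (or plain character vector of labels).
#' @param types optional character vector of types to tabulate, in the desired
#'   order; types absent from the array get count 0. Defaults to the distinct
#'   labels present, in order of first appearance.
#' @return Named integer vector of unit counts; `sum()` of it is the array
#'   length.
#' @examples
#' composition(repeat_array(rep(c("Z", "Y"), c(10, 10))))
#' composition(repeat_array("Z"), types = c("Z", "Y"))
#' @export
composition <- function(array, types = NULL) {
  labs <- as.character(array)
  if (length(labs) == 0L)
    stop("empty repeat array: a cell with no repeat units is non-viable",
         call. = FALSE)
  if (is.null(types)) types <- unique(labs)
  counts <- vapply(types, function(t) sum(labs == t), integer(1))
  names(counts) <- types
  counts
}

#' Frequency of one variant type in a composition
#'
#' @param comp named integer vector of counts as returned by [composition()].
#' @param type label of the variant whose proportion is required. A type not
#'   named in `comp` has frequency 0.
#' @return Proportion in `[0, 1]`: `counts[type] / total`.
#' @examples
#' type_frequency(c(Z = 36, Y = 24), "Z") # 0.6
#' @export
type_frequency <- function(comp, type) {
  comp <- check_composition(comp)
  total <- sum(comp)
  if (total == 0)
    stop("composition total is zero: frequencies are undefined", call. = FALSE)
  cnt <- if (type %in% names(comp)) comp[[type]] else 0L
  cnt / total
}

# shared validation for user-supplied compositions
check_composition <- function(comp) {
  if (is.null(names(comp)) || any(!nzchar(names(comp))))
    stop("a composition must be a named count vector", call. = FALSE)
  if (anyNA(comp) || any(comp < 0))
    stop("composition counts must be non-negative", call. = FALSE)
  comp
}
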