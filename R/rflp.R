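#' Restriction enzyme recognition site
#'
#' Describes a recognition pattern (IUPAC nucleotide codes allowed) and the
#' 0-based offset of the cut relative to the pattern start. The packaged
#' default, pattern `"ACGT"` cut at offset 0, mimics the blunt/short-site
#' behaviour of TscAI-class enzymes used to discriminate the two ITS amplicon
#' types; the actual recognition sequence is configurable because in-silico
#' fixtures are engineered around whatever pattern is supplied.
#'
#' @param pattern IUPAC nucleotide string, e.g. `"ACGT"` or `"RGCGCY"`.
#' @param cut_offset integer in `[0, nchar(pattern)]`: the cut falls this many
#'   bases after the pattern start.
#' @return Object of class `recognition_site`.
#' @export
recognition_site <- function(pattern = "ACGT", cut_offset = 0L) {
  pattern <- toupper(as.character(pattern))
  if (length(pattern) != 1L || !nzchar(pattern))
    stop("pattern must be a non-empty string", call. = FALSE)
  letters_ok <- strsplit(pattern, "")[[1]] %in%
    names(Biostrings::IUPAC_CODE_MAP)
  if (!all(letters_ok))
    stop("pattern contains non-IUPAC letters: ",
         paste(unique(strsplit(pattern, "")[[1]][!letters_ok]), collapse = ""),
         call. = FALSE)
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(pattern))
    stop("cut_offset must lie in [0, pattern length]", call. = FALSE)
  structure(list(pattern = pattern, cut_offset = cut_offset),
            class = "recognition_site")
}

#' Locate restriction cut positions in a sequence
#'
#' IUPAC-aware forward-strand search for the recognition pattern; every match
#' position, shifted by the site's cut offset, becomes a cut coordinate.
#' Coordinates are 0-based: a cut at position `p` separates bases `1..p` from
#' `p+1..L`. Reverse-strand search is unnecessary for palindromic patterns
#' such as the default.
#'
#' @param sequence nucleotide string or [Biostrings::DNAString].
#' @param site a [recognition_site()].
#' @return Sorted, deduplicated integer vector of 0-based cut coordinates.
#' @examples
#' find_sites("ACGTACGT", recognition_site("ACGT", 1)) # 1 5
#' @export
find_sites <- function(sequence, site) {
  stopifnot(inherits(site, "recognition_site"))
  dna <- if (methods::is(sequence, "DNAString")) sequence
         else Biostrings::DNAString(as.character(sequence))
  m <- Biostrings::matchPattern(site$pattern, dna, fixed = FALSE)
  sort(unique(Biostrings::start(m) - 1L + site$cut_offset))
}

#' Fragment sizes of a digested linear amplicon
#'
#' Cuts a linear molecule of `amplicon_length` bp at the given 0-based
#' coordinates and returns the fragment lengths left to right. A linear
#' molecule with `c` cuts yields `c + 1` fragments whose lengths always sum
#' to the amplicon length.
#'
#' @param amplicon_length amplicon size in bp.
#' @param cut_positions strictly increasing 0-based cut coordinates, each in
#'   the open interval `(0, amplicon_length)`.
#' @return Object of class `digest_result` with fields `amplicon_length`,
#'   `cut_positions` and `fragments`.
#' @examples
#' digest(920, 460)$fragments        # 460 460 (ITS type Z)
#' digest(920, c(525, 860))$fragments # 525 335 60 (ITS type Y)
#' @export
digest <- function(amplicon_length, cut_positions = integer()) {
  amplicon_length <- as.integer(amplicon_length)
  cuts <- as.integer(cut_positions)
  if (is.na(amplicon_length) || amplicon_length < 1L)
    stop("amplicon_length must be a positive integer", call. = FALSE)
  if (length(cuts)) {
    if (anyNA(cuts) || any(cuts <= 0L) || any(cuts >= amplicon_length))
      stop("cut positions must lie strictly inside (0, ", amplicon_length,
           ")", call. = FALSE)
    if (is.unsorted(cuts, strictly = TRUE))
      stop("cut positions must be strictly increasing", call. = FALSE)
  }
  structure(list(amplicon_length = amplicon_length,
                 cut_positions = cuts,
                 fragments = diff(c(0L, cuts, amplicon_length))),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat("<digest_result> ", x$amplicon_length, " bp, ",
      length(x$cut_positions), " cut(s)\n", sep = "")
  cat("  fragments:", paste(x$fragments, collapse = " + "), "bp\n")
  invisible(x)
}

#' Gel-detectable fragments
#'
#' Drops fragments too small to resolve on an agarose gel. The 100 bp default
#' reflects a 3 % gel on which a 60 bp fragment escapes detection.
#'
#' @param fragments numeric fragment lengths in bp, or a `digest_result`.
#' @param min_detectable smallest detectable fragment, bp (kept when equal).
#' @return Fragment lengths `>= min_detectable`, order preserved.
#' @examples
#' detectable(c(525, 335, 60)) # 525 335
#' @export
detectable <- function(fragments, min_detectable = 100) {
  if (inherits(fragments, "digest_result")) fragments <- fragments$fragments
  fragments[fragments >= min_detectable]
}

#' Expected detectable RFLP fragment patterns of the two ITS types
#'
#' Derives the scoring patterns from the canonical cut maps of the 920 bp
#' cloned amplicon: type Z carries one site cutting at 460 (a doublet of
#' 460 bp), type Y two sites cutting at 525 and 860 (525/335/60 bp, of which
#' the 60 bp fragment falls below gel detection).
#'
#' @param min_detectable detection threshold passed to [detectable()].
#' @return Named list of expected detectable fragment multisets, e.g.
#'   `list(Z = c(460, 460), Y = c(525, 335))`.
#' @export
its_rflp_patterns <- function(min_detectable = 100) {
  list(Z = detectable(digest(920L, 460L), min_detectable),
       Y = detectable(digest(920L, c(525L, 860L)), min_detectable))
}

#' Score a clone from its observed fragment pattern
#'
#' Matches an observed fragment multiset against the expected detectable
#' pattern of each type, allowing a per-fragment sizing tolerance. Matching is
#' order-free (fragments are compared sorted). A clone matching no pattern, or
#' more than one, scores `"unknown"` — e.g. an undigested 920 bp fragment.
#'
#' @param observed_fragments numeric observed fragment lengths, bp.
#' @param patterns named list of expected fragment multisets per type; default
#'   [its_rflp_patterns()].
#' @param tolerance_bp per-fragment sizing tolerance (gel precision), bp.
#' @return The type label, or `"unknown"`.
#' @examples
#' score_clone(c(460, 460)) # "Z"
#' score_clone(c(335, 525)) # "Y"
#' score_clone(920)         # "unknown"
#' @export
score_clone <- function(observed_fragments, patterns = its_rflp_patterns(),
                        tolerance_bp = 20) {
  if (!length(patterns) || is.null(names(patterns)))
    stop("patterns must be a non-empty named list", call. = FALSE)
  obs <- sort(as.numeric(observed_fragments))
  hit <- vapply(patterns, function(exp) {
    length(exp) == length(obs) &&
      all(abs(obs - sort(as.numeric(exp))) <= tolerance_bp)
  }, logical(1))
  if (sum(hit) == 1L) names(patterns)[hit] else "unknown"
}
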