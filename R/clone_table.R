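#' Clone-count tables
#'
#' A clone-count table records, per (isolate, life-stage, transfer)
#' observation, how many of the scored clones carried each ITS type. The
#' study layout is 4 isolates x 2 stages (meiosis, mitosis) x 5 transfers
#' with 60 clones scored per observation, plus one baseline record per
#' isolate (stage `"baseline"`, transfer 0) giving the original isolate's
#' type ratio from which expected frequencies are taken.
#'
#' @param x data frame with columns `isolate`, `stage` (one of `"baseline"`,
#'   `"meiosis"`, `"mitosis"`), `transfer` (integer; 0 for baselines),
#'   `count_Z`, `count_Y`, and optionally `total` (checked against the count
#'   sum when present, added otherwise).
#' @return Validated data frame of class `clone_count_table`.
#' @export
clone_count_table <- function(x) {
  x <- as.data.frame(x)
  required <- c("isolate", "stage", "transfer", "count_Z", "count_Y")
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop("clone-count table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad_stage <- !x$stage %in% c("baseline", "meiosis", "mitosis")
  if (any(bad_stage))
    stop("invalid stage value(s) in row(s) ",
         paste(which(bad_stage), collapse = ", "),
         " (column 'stage'): expected baseline, meiosis or mitosis",
         call. = FALSE)
  for (col in c("transfer", "count_Z", "count_Y")) {
    v <- x[[col]]
    if (anyNA(v) || any(v < 0) || any(v != as.integer(v)))
      stop("column '", col, "' must contain non-negative integers (row ",
           paste(which(anyNA(v) | v < 0 | v != as.integer(v)),
                 collapse = ", "), ")", call. = FALSE)
    x[[col]] <- as.integer(v)
  }
  sums <- x$count_Z + x$count_Y
  if ("total" %in% names(x)) {
    off <- which(x$total != sums)
    if (length(off))
      stop("count_Z + count_Y does not match 'total' in row(s) ",
           paste(off, collapse = ", "), call. = FALSE)
    x$total <- as.integer(x$total)
  } else {
    x$total <- sums
  }
  class(x) <- c("clone_count_table", "data.frame")
  x
}

#' Read / write clone-count tables as tab-separated text
#'
#' @param path file path of a TSV with header columns `isolate`, `stage`,
#'   `transfer`, `count_Z`, `count_Y` (and optionally `total`).
#' @return `read_clone_counts()` returns a [clone_count_table()];
#'   `write_clone_counts()` invisibly returns its input.
#' @export
read_clone_counts <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  clone_count_table(x)
}

#' @rdname read_clone_counts
#' @param tab a [clone_count_table()] (or coercible data frame).
#' @export
write_clone_counts <- function(tab, path) {
  tab <- clone_count_table(tab)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tab)
}

#' Baseline type-Z frequency of an isolate
#'
#' Looks up the isolate's baseline record (stage `"baseline"`) and returns
#' its observed proportion of type Z; this is the expected frequency used by
#' [chisq_gof()] for that isolate's meiosis and mitosis series.
#'
#' @param tab a [clone_count_table()].
#' @param isolate isolate id.
#' @return Proportion of type Z in the baseline record.
#' @export
baseline_frequency <- function(tab, isolate) {
  tab <- clone_count_table(tab)
  row <- tab[tab$isolate == isolate & tab$stage == "baseline", , drop = FALSE]
  if (nrow(row) == 0L)
    stop("no baseline record for isolate '", isolate, "'", call. = FALSE)
  if (nrow(row) > 1L)
    stop("multiple baseline records for isolate '", isolate, "'",
         call. = FALSE)
  row$count_Z / row$total
}

#' One (isolate, stage) series of a clone-count table
#'
#' @param tab a [clone_count_table()].
#' @param isolate isolate id.
#' @param stage `"meiosis"` or `"mitosis"`.
#' @return The series rows ordered by transfer index.
#' @export
series_slice <- function(tab, isolate, stage) {
  tab <- clone_count_table(tab)
  s <- tab[tab$isolate == isolate & tab$stage == stage, , drop = FALSE]
  if (nrow(s) == 0L)
    stop("no ", stage, " series for isolate '", isolate, "'", call. = FALSE)
  s[order(s$transfer), , drop = FALSE]
}
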