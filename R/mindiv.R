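#' Minimum divisions to amplify a variant under a constrained array size
#'
#' When the total array size is fixed (or otherwise constrained), a variant's
#' copy count can at most double per cell division: each existing copy is
#' replicated exactly once, so a daughter assembled from the two sister
#' chromatids can carry at most `2 * start` copies. The minimum number of
#' divisions to go from `start` to at least `target` copies is therefore the
#' smallest `d` with `start * 2^d >= target` (0 when `start >= target`).
#' Moving a 60-copy array from 5 focal copies to 51 takes at least 4
#' divisions under this rule.
#'
#' @param start starting copy count of the focal variant, `>= 1`.
#' @param target required copy count.
#' @param total fixed total array size; `target > total` is unreachable and
#'   raises an error.
#' @return Integer number of divisions.
#' @examples
#' min_divisions_constrained(5, 51, 60) # 4
#' @seealso [reachable_compositions()] for the brute-force oracle,
#'   [min_divisions_unconstrained()] for the unrestricted case.
#' @export
min_divisions_constrained <- function(start, target, total) {
  start <- check_count(start, "start")
  target <- check_count(target, "target")
  total <- check_count(total, "total")
  if (start < 1L) stop("start must be at least 1", call. = FALSE)
  if (start > total)
    stop("start cannot exceed the constrained total", call. = FALSE)
  if (target > total)
    stop("target ", target, " exceeds the constrained array size ", total,
         ": unreachable", call. = FALSE)
  d <- 0L
  reach <- start
  while (reach < target) {       # integer doubling, exact (no log2 rounding)
    reach <- reach * 2L
    d <- d + 1L
  }
  d
}

#' Minimum divisions when array size is unrestricted
#'
#' Without a size constraint a single unequal exchange can produce an
#' arbitrarily short (or long) recombinant chromatid, so any target variant
#' *proportion* is realizable in one division — e.g. a daughter array
#' consisting almost entirely of the focal variant. The answer is therefore 0
#' when the start count already satisfies the target and 1 otherwise.
#'
#' @inheritParams min_divisions_constrained
#' @return 0L or 1L.
#' @examples
#' min_divisions_unconstrained(5, 51) # 1
#' @export
min_divisions_unconstrained <- function(start, target) {
  start <- check_count(start, "start")
  target <- check_count(target, "target")
  if (start >= target) 0L else 1L
}

#' Brute-force reachability oracle for composition changes
#'
#' Exhaustively enumerates the compositions a single cell lineage can reach
#' in a given number of divisions, under the rule that each repeat copy is
#' duplicated at most once per replication: at a division the parental array
#' (`z` focal copies out of `t`) is replicated into two sister chromatids and
#' the surviving daughter is assembled, by unequal exchange, from the pooled
#' `2z` focal and `2(t - z)` other copies. In the constrained mode the
#' daughter must again have exactly `total` units, so its focal count ranges
#' over `max(0, 2z - total) .. min(2z, total)`; in the unconstrained mode any
#' non-empty sub-assembly is allowed.
#'
#' This is an exponential-state enumeration intended as an oracle for the
#' closed-form calculators on small instances (`total <= 16`,
#' `divisions <= 6`); larger instances raise an error.
#'
#' @param start_count focal-variant copies in the starting array.
#' @param total starting (and, if `constrained`, permanent) array size.
#' @param divisions number of divisions to enumerate.
#' @param constrained logical; fix the array size at `total`?
#' @return Data frame with columns `focal` and `total`, one row per reachable
#'   composition (reachability after at most `divisions` divisions; standing
#'   still is always possible, so this equals exact-`d` reachability).
#' @examples
#' reachable_compositions(1, 2, 1) # includes 0, 1 and 2 focal copies
#' @export
reachable_compositions <- function(start_count, total, divisions,
                                   constrained = TRUE) {
  start_count <- check_count(start_count, "start_count")
  total <- check_count(total, "total")
  divisions <- check_count(divisions, "divisions")
  if (start_count > total)
    stop("start_count cannot exceed total", call. = FALSE)
  if (total > 16L || divisions > 6L)
    stop("instance too large for exhaustive enumeration ",
         "(total <= 16, divisions <= 6); use the closed-form calculators",
         call. = FALSE)
  if (!constrained && (total > 8L || divisions > 2L))
    stop("unconstrained enumeration doubles the state space per division; ",
         "limited to total <= 8 and divisions <= 2", call. = FALSE)
  states <- matrix(c(start_count, total), ncol = 2,
                   dimnames = list(NULL, c("focal", "total")))
  for (d in seq_len(divisions)) {
    nxt <- vector("list", nrow(states))
    for (s in seq_len(nrow(states))) {
      z <- states[s, 1L]
      t <- states[s, 2L]
      if (constrained) {
        zp <- max(0L, 2L * z - t):min(2L * z, t)
        nxt[[s]] <- cbind(focal = zp, total = t)
      } else {
        zp <- 0L:(2L * z)
        op <- 0L:(2L * (t - z))
        grid <- expand.grid(focal = zp, other = op)
        grid <- grid[grid$focal + grid$other >= 1L, , drop = FALSE]
        nxt[[s]] <- cbind(focal = grid$focal,
                          total = grid$focal + grid$other)
      }
    }
    states <- unique(do.call(rbind, nxt))
  }
  out <- as.data.frame(states)
  out[order(out$total, out$focal), , drop = FALSE]
}

#' Minimum divisions according to the brute-force oracle
#'
#' Sweeps [reachable_compositions()] over increasing division counts and
#' reports the first at which the target is reached: in the constrained mode,
#' at least `target` focal copies at the constrained total; in the
#' unconstrained mode, any composition whose focal proportion is at least
#' `target / total` (the size-unrestricted claim is about ratios, since a
#' short recombinant realizes an extreme ratio without extra copies).
#'
#' @inheritParams reachable_compositions
#' @param target required focal copy count (constrained) or the numerator of
#'   the required focal proportion `target / total` (unconstrained).
#' @param max_divisions give up (return `NA`) beyond this horizon.
#' @return Integer minimum divisions, or `NA` if not reached.
#' @export
oracle_min_divisions <- function(start_count, target, total,
                                 constrained = TRUE, max_divisions = 6L) {
  for (d in 0:max_divisions) {
    r <- reachable_compositions(start_count, total, d,
                                constrained = constrained)
    hit <- if (constrained) {
      any(r$focal >= target & r$total == total)
    } else {
      any(r$focal / r$total >= target / total)
    }
    if (hit) return(as.integer(d))
  }
  NA_integer_
}

check_count <- function(x, what) {
  x <- as.integer(x)
  if (length(x) != 1L || is.na(x) || x < 0L)
    stop(what, " must be a single non-negative integer", call. = FALSE)
  x
}
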