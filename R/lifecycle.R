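#' Simulation parameters for the concerted-evolution life-cycle model
#'
#' Bundles the event rates and viability bounds of the tandem-array
#' recombination model. Per cell division the replicated array pair receives
#' `Poisson(crossover_rate)` unequal exchanges, each reciprocal with
#' probability `reciprocal_fraction`, followed by `Poisson(conversion_rate)`
#' gene conversions with geometric-like tract lengths of mean
#' `conversion_tract` units. Daughters whose array length falls outside
#' `[n_min, n_max]` are handled by the boundary policy: `"resample"` redraws
#' the whole event set for that division (viability selection without lineage
#' death), `"death"` discards the offending daughter and retries only if no
#' daughter survives. Both policies give up with an error after `retry_cap`
#' attempts, signalling a non-viable parameterization.
#'
#' Defaults describe a cistron of around 120-130 repeat copies: initial
#' `array_size` 125 units, a viability floor of 12 copies (below which rRNA
#' supply cannot sustain the cell) and a ceiling of 600 copies. Twenty
#' mitotic divisions per sub-culture transfer stand in for a two-week
#' hyphal-tip culture. Rates are shared between mitosis and meiosis; a
#' stronger meiotic signal then emerges purely from the three event-bearing
#' divisions of ascospore formation.
#'
#' @param crossover_rate expected unequal exchanges per division (Poisson mean).
#' @param reciprocal_fraction probability that an exchange is reciprocal.
#' @param conversion_rate expected gene conversions per division.
#' @param conversion_tract mean conversion tract length, units (>= 1).
#' @param n_min,n_max viability bounds on array length, units.
#' @param boundary_policy `"resample"` or `"death"` (see Details).
#' @param divisions_per_transfer mitotic divisions per hyphal-tip transfer.
#' @param retry_cap attempts per division before declaring non-viability.
#' @param array_size initial array length used by the data generators.
#' @param seed optional RNG seed recorded with the parameters; generators that
#'   accept a `sim_params` honour it.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(crossover_rate = 0.05,
                       reciprocal_fraction = 0.5,
                       conversion_rate = 0,
                       conversion_tract = 3,
                       n_min = 12L,
                       n_max = 600L,
                       boundary_policy = c("resample", "death"),
                       divisions_per_transfer = 20L,
                       retry_cap = 100L,
                       array_size = 125L,
                       seed = NULL) {
  boundary_policy <- match.arg(boundary_policy)
  n_min <- as.integer(n_min)
  n_max <- as.integer(n_max)
  if (crossover_rate < 0 || conversion_rate < 0)
    stop("event rates must be non-negative", call. = FALSE)
  if (reciprocal_fraction < 0 || reciprocal_fraction > 1)
    stop("reciprocal_fraction must lie in [0, 1]", call. = FALSE)
  if (conversion_tract < 1)
    stop("conversion_tract must be at least one unit", call. = FALSE)
  if (n_min < 1L || n_min > n_max)
    stop("viability bounds require 1 <= n_min <= n_max", call. = FALSE)
  structure(list(crossover_rate = crossover_rate,
                 reciprocal_fraction = reciprocal_fraction,
                 conversion_rate = conversion_rate,
                 conversion_tract = conversion_tract,
                 n_min = n_min, n_max = n_max,
                 boundary_policy = boundary_policy,
                 divisions_per_transfer = as.integer(divisions_per_transfer),
                 retry_cap = as.integer(retry_cap),
                 array_size = as.integer(array_size),
                 seed = seed),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat("  crossover_rate:", x$crossover_rate,
      " (reciprocal fraction", x$reciprocal_fraction, ")\n")
  cat("  conversion_rate:", x$conversion_rate,
      " (mean tract", x$conversion_tract, "units)\n")
  cat("  viability: [", x$n_min, ",", x$n_max, "] units, policy",
      x$boundary_policy, "\n")
  cat("  divisions per transfer:", x$divisions_per_transfer,
      " initial array:", x$array_size, "units\n")
  invisible(x)
}

#' Cell state: one array plus a division counter
#'
#' @param array a [repeat_array()] (or character vector of unit labels).
#' @param generation integer division counter, incremented by every division
#'   operation.
#' @return Object of class `cell_state`.
#' @export
cell_state <- function(array, generation = 0L) {
  array <- repeat_array(as.character(array))
  if (length(array) < 1L)
    stop("a viable cell needs at least one repeat unit", call. = FALSE)
  structure(list(array = array, generation = as.integer(generation)),
            class = "cell_state")
}

#' @export
print.cell_state <- function(x, ...) {
  cat("<cell_state> generation", x$generation, "\n")
  print(x$array)
  invisible(x)
}

# One replication + event round on two sister copies of `units`.
# Returns the two product arrays (plain character vectors), no viability check.
divide_pair <- function(units, params) {
  a <- units
  b <- units
  n_x <- stats::rpois(1L, params$crossover_rate)
  for (e in seq_len(n_x)) {
    i <- sample.int(length(a) + 1L, 1L) - 1L
    j <- sample.int(length(b) + 1L, 1L) - 1L
    if (stats::runif(1L) < params$reciprocal_fraction) {
      new_a <- c(a[seq_len(i)], drop_head(b, j))
      new_b <- c(b[seq_len(j)], drop_head(a, i))
      a <- new_a
      b <- new_b
    } else if (stats::runif(1L) < 0.5) {
      # a is recipient, b the intact donor
      a <- c(a[seq_len(i)], drop_head(b, j))
    } else {
      b <- c(b[seq_len(j)], drop_head(a, i))
    }
  }
  n_c <- stats::rpois(1L, params$conversion_rate)
  for (e in seq_len(n_c)) {
    span <- min(length(a), length(b))
    if (span < 1L) next
    tract <- min(1L + stats::rpois(1L, params$conversion_tract - 1), span)
    start <- sample.int(span - tract + 1L, 1L) - 1L
    idx <- (start + 1L):(start + tract)
    if (stats::runif(1L) < 0.5) a[idx] <- b[idx] else b[idx] <- a[idx]
  }
  list(a, b)
}

viable_length <- function(u, params) {
  length(u) >= params$n_min && length(u) <= params$n_max
}

#' One mitotic division with sister-chromatid exchange
#'
#' Replicates the parental array into two sister chromatids, applies the
#' Poisson event model of [sim_params()] between them (unequal crossovers,
#' then gene conversions), and hands one product to each daughter. Daughters
#' outside the viability bounds are handled by the boundary policy.
#'
#' @param cell a [cell_state()].
#' @param params a [sim_params()].
#' @return List of daughter `cell_state`s: always two under the `"resample"`
#'   policy; one or two under `"death"` (a daughter outside the bounds dies).
#' @examples
#' set.seed(1)
#' kids <- mitotic_division(cell_state(rep(c("Z","Y"), c(60, 60))),
#'                          sim_params(crossover_rate = 1))
#' sapply(kids, function(k) length(k$array))
#' @export
mitotic_division <- function(cell, params) {
  stopifnot(inherits(cell, "cell_state"), inherits(params, "sim_params"))
  units <- as.character(cell$array)
  for (attempt in seq_len(params$retry_cap)) {
    prods <- divide_pair(units, params)
    ok <- vapply(prods, viable_length, logical(1), params = params)
    keep <- if (params$boundary_policy == "resample") {
      if (all(ok)) prods else NULL
    } else {
      if (any(ok)) prods[ok] else NULL
    }
    if (!is.null(keep))
      return(lapply(keep, function(u)
        cell_state(u, generation = cell$generation + 1L)))
  }
  stop("no viable daughters within ", params$retry_cap,
       " attempts: parameterization is non-viable for an array of ",
       length(units), " units with bounds [", params$n_min, ", ",
       params$n_max, "]", call. = FALSE)
}

#' Meiosis of a homothallic haploid: eight ascospores
#'
#' Homothallic selfing pairs two identical copies of the parental array, so
#' all variation among spores arises from exchange events. Ascospore
#' development comprises three successive division rounds — meiosis I with
#' inter-homolog exchanges, meiosis II and a post-meiotic mitosis with
#' sister-chromatid exchanges — each using the same event model as
#' [mitotic_division()] (the homologs of a selfer are sequence-identical, so
#' the two exchange contexts are statistically the same).
#'
#' @inheritParams mitotic_division
#' @return List of eight ascospore `cell_state`s (fewer only under the
#'   `"death"` boundary policy, if spores die at the bounds).
#' @examples
#' set.seed(1)
#' length(meiotic_ascospores(cell_state(rep("Z", 125)), sim_params()))
#' @export
meiotic_ascospores <- function(cell, params) {
  cells <- list(cell)
  for (round in 1:3)
    cells <- unlist(lapply(cells, mitotic_division, params = params),
                    recursive = FALSE)
  cells
}

#' Serial hyphal-tip transfer: one mitotic lineage
#'
#' A hyphal tip is a single mitotic lineage: each of the
#' `divisions` successive divisions keeps one uniformly chosen daughter and
#' discards the rest, and the terminal cell founds the next sub-culture.
#'
#' @inheritParams mitotic_division
#' @param divisions number of divisions to simulate (defaults to
#'   `params$divisions_per_transfer`).
#' @return The terminal `cell_state` of the lineage.
#' @export
hyphal_tip_transfer <- function(cell, params,
                                divisions = params$divisions_per_transfer) {
  divisions <- as.integer(divisions)
  stopifnot(inherits(cell, "cell_state"), inherits(params, "sim_params"))
  units <- as.character(cell$array)
  for (d in seq_len(divisions)) units <- divide_and_pick(units, params)
  cell_state(units, generation = cell$generation + divisions)
}

#' Run a single lineage to variant fixation
#'
#' Iterates single-lineage mitotic divisions until the array is monotypic
#' (homogenized to one variant — the end state of concerted evolution) or
#' until `max_divisions` is reached.
#'
#' @inheritParams mitotic_division
#' @param max_divisions censoring horizon.
#' @return List with `divisions` (count performed), `fixed_type` (label of the
#'   fixed variant, or `NA` if censored) and `censored` (logical).
#' @examples
#' set.seed(1)
#' fixation_run(cell_state(rep(c("Z","Y"), c(15, 5))),
#'              sim_params(crossover_rate = 1, reciprocal_fraction = 1,
#'                         n_min = 2, n_max = 100),
#'              max_divisions = 500)
#' @export
fixation_run <- function(cell, params, max_divisions = 10000L) {
  stopifnot(inherits(cell, "cell_state"), inherits(params, "sim_params"))
  # hot loop on bare label vectors; same event model as mitotic_division
  units <- as.character(cell$array)
  divisions <- 0L
  repeat {
    first <- units[1L]
    if (all(units == first))
      return(list(divisions = divisions, fixed_type = first,
                  censored = FALSE))
    if (divisions >= max_divisions)
      return(list(divisions = divisions, fixed_type = NA_character_,
                  censored = TRUE))
    units <- divide_and_pick(units, params)
    divisions <- divisions + 1L
  }
}

# one viable division + uniform daughter choice, on bare label vectors
divide_and_pick <- function(units, params) {
  for (attempt in seq_len(params$retry_cap)) {
    prods <- divide_pair(units, params)
    ok <- vapply(prods, viable_length, logical(1), params = params)
    keep <- if (params$boundary_policy == "resample") {
      if (all(ok)) prods else NULL
    } else {
      if (any(ok)) prods[ok] else NULL
    }
    if (!is.null(keep)) return(keep[[sample.int(length(keep), 1L)]])
  }
  stop("no viable daughters within ", params$retry_cap,
       " attempts: parameterization is non-viable", call. = FALSE)
}
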