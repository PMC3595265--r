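#' Study design for synthetic clone-count datasets
#'
#' Describes the shape of the clone-typing experiment the generators emulate:
#' a set of isolates, each followed through a meiotic and a mitotic series of
#' sequential observations, with a fixed number of clones scored per
#' observation. The defaults mirror the study layout of four two-type
#' isolates, 2 life stages, 5 transfers and 60 scored clones.
#'
#' @param isolates character vector of isolate ids.
#' @param stages life stages to simulate (subset of `"meiosis"`,
#'   `"mitosis"`).
#' @param n_transfers sequential observations per (isolate, stage) series.
#' @param clones_per_obs clones scored per observation (`k`).
#' @param baseline_freq per-isolate proportion of type Z in the original
#'   isolate, strictly inside (0, 1); recycled across isolates.
#' @param types variant labels, focal type first.
#' @param seed optional RNG seed; generation is bit-reproducible from
#'   (design, params, seed).
#' @return Object of class `study_design`.
#' @export
study_design <- function(isolates = c("CMW13582", "CMW17568",
                                      "CMW17570", "CMW23635"),
                         stages = c("meiosis", "mitosis"),
                         n_transfers = 5L,
                         clones_per_obs = 60L,
                         baseline_freq = 0.5,
                         types = c("Z", "Y"),
                         seed = NULL) {
  stages <- match.arg(stages, c("meiosis", "mitosis"), several.ok = TRUE)
  n_transfers <- as.integer(n_transfers)
  clones_per_obs <- as.integer(clones_per_obs)
  if (n_transfers < 0L) stop("n_transfers must be >= 0", call. = FALSE)
  if (clones_per_obs < 1L) stop("clones_per_obs must be >= 1", call. = FALSE)
  if (any(baseline_freq <= 0) || any(baseline_freq >= 1))
    stop("baseline_freq must lie strictly inside (0, 1)", call. = FALSE)
  if (length(types) < 2L) stop("at least two variant types", call. = FALSE)
  baseline_freq <- rep_len(baseline_freq, length(isolates))
  names(baseline_freq) <- isolates
  structure(list(isolates = as.character(isolates), stages = stages,
                 n_transfers = n_transfers, clones_per_obs = clones_per_obs,
                 baseline_freq = baseline_freq,
                 types = as.character(types), seed = seed),
            class = "study_design")
}

#' Sample scored clones from an array composition
#'
#' Cloning randomly picks recombinant colonies from the amplicon pool of a
#' culture or spore. Under the `"binomial"` model (default) PCR has amplified
#' the array into a pool vastly larger than `k`, so clone types are draws
#' with replacement from the composition frequencies. The
#' `"hypergeometric"` model instead draws `k` physical copies without
#' replacement from the array itself (requires `k <= sum(comp)`).
#'
#' @param comp named count vector from [composition()].
#' @param k number of clones to score.
#' @param model `"binomial"` or `"hypergeometric"`.
#' @return Named integer vector of clone counts per type, summing to `k`.
#' @examples
#' set.seed(1)
#' sample_clones(c(Z = 60, Y = 60), 60)
#' @export
sample_clones <- function(comp, k, model = c("binomial", "hypergeometric")) {
  model <- match.arg(model)
  comp <- check_composition(comp)
  total <- sum(comp)
  if (total == 0) stop("composition total is zero", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (model == "binomial") {
    draws <- stats::rmultinom(1L, k, prob = comp / total)[, 1L]
  } else {
    if (k > total)
      stop("cannot draw ", k, " clones without replacement from ", total,
           " physical copies", call. = FALSE)
    picked <- sample(rep(names(comp), comp), k)
    draws <- vapply(names(comp), function(t) sum(picked == t), integer(1))
  }
  names(draws) <- names(comp)
  draws
}

# deterministic baseline record: the original isolate's composition expressed
# as exact expected counts, so chisq_gof's expected frequency is the truth
baseline_counts <- function(freq, k) {
  z <- as.integer(round(freq * k))
  c(z = z, y = k - z)
}

#' Generate a null-model clone-count dataset
#'
#' Every observation is sampled from the isolate's fixed baseline frequency
#' (no drift in the underlying array): the null hypothesis of no change in
#' the type ratios, carrying only clone-sampling noise. One deterministic
#' baseline record per isolate (stage `"baseline"`, transfer 0, counts
#' `round(freq * k)`) anchors the expected frequency used by [chisq_gof()].
#'
#' @param design a [study_design()].
#' @return A [clone_count_table()].
#' @examples
#' tab <- generate_null_dataset(study_design(seed = 1))
#' nrow(tab) # 4 baselines + 4 isolates x 2 stages x 5 transfers
#' @export
generate_null_dataset <- function(design) {
  stopifnot(inherits(design, "study_design"))
  if (!is.null(design$seed)) set.seed(design$seed)
  k <- design$clones_per_obs
  rows <- list()
  for (iso in design$isolates) {
    f <- design$baseline_freq[[iso]]
    bl <- baseline_counts(f, k)
    rows[[length(rows) + 1L]] <- data.frame(
      isolate = iso, stage = "baseline", transfer = 0L,
      count_Z = bl[["z"]], count_Y = bl[["y"]])
    for (stage in design$stages) {
      for (t in seq_len(design$n_transfers)) {
        nz <- stats::rbinom(1L, k, f)
        rows[[length(rows) + 1L]] <- data.frame(
          isolate = iso, stage = stage, transfer = t,
          count_Z = nz, count_Y = k - nz)
      }
    }
  }
  clone_count_table(do.call(rbind, rows))
}

#' Generate a drift-model clone-count dataset from the simulator
#'
#' Per isolate, an initial array of `params$array_size` units at the
#' designed baseline frequency (random unit arrangement) evolves under the
#' unequal-crossover / gene-conversion model: the mitotic series follows a
#' chain of [hyphal_tip_transfer()]s, and each meiotic observation scores one
#' ascospore drawn from a [meiotic_ascospores()] run of the maintained
#' culture (set `serial_meiosis = TRUE` to passage spore-to-spore instead).
#' Each observation is a [sample_clones()] draw from the current true
#' composition; the true trajectories are returned alongside the counts for
#' parameter-recovery work.
#'
#' @param design a [study_design()].
#' @param params a [sim_params()].
#' @param serial_meiosis logical; if `TRUE` each sampled spore becomes the
#'   parent of the next meiosis.
#' @param model clone sampling model, see [sample_clones()].
#' @return List with `counts` (a [clone_count_table()]) and `trajectories`
#'   (data frame of true per-observation array compositions and lengths).
#' @export
generate_drift_dataset <- function(design, params = sim_params(),
                                   serial_meiosis = FALSE,
                                   model = "binomial") {
  stopifnot(inherits(design, "study_design"), inherits(params, "sim_params"))
  seed <- if (!is.null(design$seed)) design$seed else params$seed
  if (!is.null(seed)) set.seed(seed)
  k <- design$clones_per_obs
  types <- design$types
  focal <- types[1L]
  rows <- list()
  traj <- list()
  for (iso in design$isolates) {
    f <- design$baseline_freq[[iso]]
    n0 <- params$array_size
    nz0 <- as.integer(round(f * n0))
    units <- sample(rep(types[1:2], c(nz0, n0 - nz0)))
    founder <- cell_state(units)
    f0 <- type_frequency(composition(founder$array, types), focal)
    bl <- baseline_counts(f0, k)
    rows[[length(rows) + 1L]] <- data.frame(
      isolate = iso, stage = "baseline", transfer = 0L,
      count_Z = bl[["z"]], count_Y = bl[["y"]])
    for (stage in design$stages) {
      lineage <- founder
      for (t in seq_len(design$n_transfers)) {
        if (stage == "mitosis") {
          lineage <- hyphal_tip_transfer(lineage, params)
          observed <- lineage
        } else {
          spores <- meiotic_ascospores(lineage, params)
          observed <- spores[[sample.int(length(spores), 1L)]]
          if (serial_meiosis) lineage <- observed
        }
        comp <- composition(observed$array, types)
        counts <- sample_clones(comp, k, model = model)
        rows[[length(rows) + 1L]] <- data.frame(
          isolate = iso, stage = stage, transfer = t,
          count_Z = counts[[types[1L]]], count_Y = counts[[types[2L]]])
        traj[[length(traj) + 1L]] <- data.frame(
          isolate = iso, stage = stage, transfer = t,
          true_Z = comp[[types[1L]]], true_Y = comp[[types[2L]]],
          array_length = sum(comp))
      }
    }
  }
  list(counts = clone_count_table(do.call(rbind, rows)),
       trajectories = do.call(rbind, traj))
}

#' Engineer FASTA amplicon fixtures for the two ITS types
#'
#' Builds two synthetic 920 bp amplicon sequences whose only occurrences of
#' the recognition pattern sit exactly where the canonical cut maps demand:
#' one cut at 460 for type Z (the 460 bp doublet) and cuts at 525 and 860
#' for type Y (525/335/60 bp fragments). The random background is screened
#' and locally mutated until no spurious pattern match remains, so
#' `find_sites()` recovers precisely the engineered cut coordinates and the
#' digest/score round trip types the fixtures as Z and Y.
#'
#' @param site a [recognition_site()].
#' @param seed optional RNG seed for the background sequence.
#' @param amplicon_length amplicon size in bp.
#' @param cuts named list of cut-coordinate vectors per type.
#' @return [Biostrings::DNAStringSet] of the two amplicons, named
#'   `"type_Z"` and `"type_Y"`.
#' @examples
#' fx <- make_amplicon_fixtures(seed = 1)
#' find_sites(fx[["type_Z"]], recognition_site())
#' @export
make_amplicon_fixtures <- function(site = recognition_site(), seed = NULL,
                                   amplicon_length = 920L,
                                   cuts = list(Z = 460L, Y = c(525L, 860L))) {
  stopifnot(inherits(site, "recognition_site"))
  if (!is.null(seed)) set.seed(seed)
  seqs <- vapply(cuts, function(cc)
    engineer_amplicon(site, amplicon_length, sort(as.integer(cc))),
    character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- paste0("type_", names(cuts))
  out
}

# place concrete realizations of the (possibly ambiguous) pattern so that
# pattern_start + cut_offset lands on each required cut, then mutate away any
# accidental match elsewhere
engineer_amplicon <- function(site, len, cut_pos) {
  plen <- nchar(site$pattern)
  pat_chars <- strsplit(site$pattern, "")[[1]]
  starts0 <- cut_pos - site$cut_offset           # 0-based pattern starts
  if (any(starts0 < 0L) || any(starts0 + plen > len))
    stop("pattern placement for cut(s) ",
         paste(cut_pos, collapse = ", "),
         " does not fit inside a ", len, " bp amplicon", call. = FALSE)
  if (length(starts0) > 1L && any(diff(starts0) < plen))
    stop("required pattern placements overlap", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  realization <- vapply(pat_chars, function(ch) {
    sample(strsplit(Biostrings::IUPAC_CODE_MAP[[ch]], "")[[1]], 1L)
  }, character(1))
  required <- unlist(lapply(starts0, function(s) (s + 1L):(s + plen)))
  s <- sample(bases, len, replace = TRUE)
  for (st in starts0) s[(st + 1L):(st + plen)] <- realization
  for (iter in 1:200) {
    found <- find_sites(paste(s, collapse = ""), site)
    if (identical(found, cut_pos)) return(paste(s, collapse = ""))
    spurious <- setdiff(found, cut_pos)
    if (!length(spurious))
      stop("engineered cuts were destroyed; pattern incompatible with ",
           "placement constraints", call. = FALSE)
    for (cut in spurious) {
      span <- (cut - site$cut_offset + 1L):(cut - site$cut_offset + plen)
      mutable <- setdiff(span, required)
      if (!length(mutable))
        stop("spurious pattern match overlaps a required site; choose a ",
             "different pattern or cut map", call. = FALSE)
      pos <- mutable[sample.int(length(mutable), 1L)]
      off <- pos - (cut - site$cut_offset)       # 1-based offset in pattern
      allowed <- strsplit(Biostrings::IUPAC_CODE_MAP[[pat_chars[off]]],
                          "")[[1]]
      choices <- setdiff(bases, allowed)
      if (!length(choices)) choices <- setdiff(bases, s[pos])
      s[pos] <- sample(choices, 1L)
    }
  }
  stop("could not eliminate spurious pattern matches within 200 rounds",
       call. = FALSE)
}
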