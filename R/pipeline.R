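#' Recompute the reportable statistics from the printed summaries
#'
#' Runs every downstream transform of the published per-isolate statistics
#' ([its_study_tables()]): the df-4 tail probability of each chi-square
#' value, compared against the printed probability at its printed precision;
#' Fisher's combined statistic per life stage from the printed probability
#' lists; the critical value at the stated significance level; and the
#' per-isolate significance verdicts. Printed probabilities that disagree
#' with the df-4 tail are flagged (`agrees = FALSE`) and still used as
#' printed in the combination — the reproduction mirrors the record, it does
#' not repair it.
#'
#' @param alpha significance level for verdicts and the critical value.
#' @return Object of class `its_reproduction`: list with `per_stage` (data
#'   frames adding `p_computed` and `agrees`), `combined` (a
#'   [fisher_combine()] result per stage), `critical_value`, `verdicts`
#'   (per-isolate logical by stage) and `alpha`.
#' @examples
#' rep <- reproduce_tables()
#' rep$combined$meiosis$statistic # 68.726
#' @export
reproduce_tables <- function(alpha = 0.01) {
  tabs <- its_study_tables()
  df <- tabs$df
  per_stage <- list()
  combined <- list()
  for (stage in c("meiosis", "mitosis")) {
    tb <- tabs[[stage]]
    tb$p_computed <- chisq_sf(tb$chisq, df)
    tb$agrees <- abs(tb$p_computed - tb$p_printed) <= tb$p_tol
    per_stage[[stage]] <- tb
    combined[[stage]] <- fisher_combine(tb$p_printed)
  }
  verdicts <- data.frame(
    isolate = tabs$chisq$isolate,
    meiosis = vapply(tabs$chisq$meiosis, function(s)
      significance_call(s, alpha, df)$significant, logical(1)),
    mitosis = vapply(tabs$chisq$mitosis, function(s)
      significance_call(s, alpha, df)$significant, logical(1)))
  structure(list(per_stage = per_stage, combined = combined,
                 critical_value = chisq_critical(alpha, df),
                 verdicts = verdicts, alpha = alpha, df = df),
            class = "its_reproduction")
}

#' @export
print.its_reproduction <- function(x, ...) {
  cat("Reproduction of the ITS clone-typing statistics",
      " (alpha = ", x$alpha, ", df = ", x$df, ")\n", sep = "")
  cat("critical value: ", format(round(x$critical_value, 2), nsmall = 2),
      "\n\n", sep = "")
  for (stage in names(x$per_stage)) {
    tb <- x$per_stage[[stage]]
    cat(stage, " replicas:\n", sep = "")
    show <- data.frame(isolate = tb$isolate,
                       chisq = tb$chisq,
                       p_printed = signif(tb$p_printed, 4),
                       p_computed = signif(tb$p_computed, 4),
                       flag = ifelse(tb$agrees, "", "WARN: printed P differs"))
    print(show, row.names = FALSE)
    cat("  -2 sum ln(P) = ",
        format(round(x$combined[[stage]]$statistic, 3), nsmall = 3),
        " on df = ", x$combined[[stage]]$df,
        ", combined P = ", signif(x$combined[[stage]]$p_combined, 3),
        "\n\n", sep = "")
  }
  cat("significance verdicts (statistic > critical):\n")
  print(x$verdicts, row.names = FALSE)
  invisible(x)
}

#' Run the full clone-count analysis on real or simulated data
#'
#' End-to-end pipeline: obtain a clone-count table (a supplied table, a TSV
#' path, or a fresh [generate_drift_dataset()] draw), fit [chisq_gof()] to
#' every (isolate, stage) series against the isolate's baseline frequency,
#' combine the per-isolate probabilities per stage with [fisher_combine()],
#' and call significance throughout.
#'
#' @param data a [clone_count_table()], a data frame, a TSV path, or `NULL`
#'   to simulate from `design` and `params`.
#' @param design a [study_design()], used when `data` is `NULL`.
#' @param params a [sim_params()], used when `data` is `NULL`.
#' @param alpha significance level.
#' @param df_convention passed to [chisq_gof()].
#' @param seed optional seed applied to the simulation (overrides
#'   `design$seed`).
#' @return Object of class `study_report`: list with `per_series` (data frame
#'   of isolate, stage, statistic, df, p, significant), `combined` (per-stage
#'   [fisher_combine()] result plus verdict), `alpha`, `df_convention`,
#'   `seed`, and `data` (the analysed table).
#' @examples
#' rep <- run_study(design = study_design(seed = 42),
#'                  params = sim_params(crossover_rate = 0.1))
#' rep$per_series
#' @export
run_study <- function(data = NULL, design = study_design(),
                      params = sim_params(), alpha = 0.01,
                      df_convention = c("study", "orthodox"), seed = NULL) {
  df_convention <- match.arg(df_convention)
  trajectories <- NULL
  if (is.null(data)) {
    if (!is.null(seed)) design$seed <- seed
    sim <- generate_drift_dataset(design, params)
    data <- sim$counts
    trajectories <- sim$trajectories
    seed <- design$seed
  } else if (is.character(data)) {
    data <- read_clone_counts(data)
  } else {
    data <- clone_count_table(data)
  }
  isolates <- unique(data$isolate)
  stages <- intersect(c("meiosis", "mitosis"), unique(data$stage))
  per <- list()
  for (iso in isolates) {
    f <- baseline_frequency(data, iso)
    for (stage in stages) {
      res <- chisq_gof(series_slice(data, iso, stage), f, df_convention)
      per[[length(per) + 1L]] <- data.frame(
        isolate = iso, stage = stage,
        statistic = res$statistic, df = res$df, p = res$p,
        significant = if (is.na(res$p)) NA else
          significance_call(res, alpha)$significant)
    }
  }
  per_series <- do.call(rbind, per)
  combined <- list()
  for (stage in stages) {
    p <- per_series$p[per_series$stage == stage]
    p <- pmax(p[!is.na(p)], 1e-300)
    if (length(p)) {
      fc <- fisher_combine(p)
      combined[[stage]] <- list(
        result = fc,
        significant = significance_call(fc, alpha)$significant)
    }
  }
  structure(list(per_series = per_series, combined = combined,
                 alpha = alpha, df_convention = df_convention,
                 seed = seed, data = data, trajectories = trajectories),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Clone-count study report (", x$df_convention,
      " df convention, alpha = ", x$alpha, ")\n", sep = "")
  if (!is.null(x$seed)) cat("seed: ", x$seed, "\n", sep = "")
  show <- x$per_series
  show$statistic <- round(show$statistic, 3)
  show$p <- signif(show$p, 4)
  print(show, row.names = FALSE)
  for (stage in names(x$combined)) {
    fc <- x$combined[[stage]]$result
    cat(stage, ": -2 sum ln(P) = ", format(round(fc$statistic, 3),
                                           nsmall = 3),
        ", df = ", fc$df, ", combined P = ", signif(fc$p_combined, 3),
        if (x$combined[[stage]]$significant) "  [significant]" else "",
        "\n", sep = "")
  }
  invisible(x)
}

#' Type-I error and power of the replicated chi-square test
#'
#' Monte-Carlo calibration of the clone-count test over a grid of crossover
#' rates: each replicate simulates a drift dataset, applies [chisq_gof()]
#' per (isolate, stage) series, and records the per-series rejection rate at
#' `alpha`. A rate of 0 measures the type-I error (the dataset then carries
#' only sampling noise); positive rates trace the power curve and the
#' meiosis-vs-mitosis detection asymmetry that arises because every meiotic
#' observation passes through three event-bearing divisions.
#'
#' @param crossover_rates numeric grid of per-division crossover rates.
#' @param n_reps replicate datasets per grid point.
#' @param design a [study_design()] (its seed is ignored; seeding is handled
#'   once via `seed`).
#' @param params baseline [sim_params()]; each grid point overrides its
#'   `crossover_rate`.
#' @param alpha significance level.
#' @param df_convention passed to [chisq_gof()]; the `"orthodox"` convention
#'   is the calibrated one.
#' @param serial_meiosis passed to [generate_drift_dataset()]; sequential
#'   sexual generations (each scored spore founding the next cross) make the
#'   meiotic divergence accumulate at three divisions per round and are the
#'   setting under which the meiosis-vs-mitosis power asymmetry is expressed.
#' @param seed optional overall RNG seed.
#' @return Data frame with one row per (rate, stage): number of series,
#'   rejections, rejection rate and 95% binomial confidence bounds.
#' @export
calibration_experiment <- function(crossover_rates = c(0, 0.02, 0.05, 0.1),
                                   n_reps = 100L,
                                   design = study_design(),
                                   params = sim_params(),
                                   alpha = 0.01,
                                   df_convention = "orthodox",
                                   serial_meiosis = FALSE,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  design$seed <- NULL        # one RNG stream for the whole experiment
  out <- list()
  for (rate in crossover_rates) {
    p_i <- params
    p_i$crossover_rate <- rate
    rej <- list(meiosis = integer(), mitosis = integer())
    for (r in seq_len(n_reps)) {
      rep_r <- if (rate == 0) {
        run_study(generate_null_dataset(design), alpha = alpha,
                  df_convention = df_convention)
      } else {
        sim <- generate_drift_dataset(design, p_i,
                                      serial_meiosis = serial_meiosis)
        run_study(sim$counts, alpha = alpha, df_convention = df_convention)
      }
      for (stage in names(rej)) {
        s <- rep_r$per_series[rep_r$per_series$stage == stage, ]
        rej[[stage]] <- c(rej[[stage]], s$significant)
      }
    }
    for (stage in names(rej)) {
      n <- length(rej[[stage]])
      if (!n) next
      x <- sum(rej[[stage]])
      ci <- stats::binom.test(x, n)$conf.int
      out[[length(out) + 1L]] <- data.frame(
        crossover_rate = rate, stage = stage, n_series = n,
        rejections = x, rejection_rate = x / n,
        ci_lower = ci[1], ci_upper = ci[2])
    }
  }
  do.call(rbind, out)
}

#' Read a run configuration from flat YAML
#'
#' Configuration files are flat key-value YAML with optional `design` and
#' `params` blocks whose entries map directly onto [study_design()] and
#' [sim_params()] arguments, plus optional top-level `alpha`,
#' `df_convention` and `seed`.
#'
#' @param path path to the YAML file.
#' @return List with `design`, `params`, `alpha`, `df_convention`, `seed`.
#' @examples
#' cfg <- read_run_config(system.file("extdata", "example_config.yml",
#'                                    package = "rdnaconcert"))
#' cfg$design$isolates
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  design <- do.call(study_design, as.list(cfg$design))
  params <- do.call(sim_params, as.list(cfg$params))
  list(design = design, params = params,
       alpha = if (is.null(cfg$alpha)) 0.01 else cfg$alpha,
       df_convention = if (is.null(cfg$df_convention)) "study"
                       else cfg$df_convention,
       seed = cfg$seed)
}
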