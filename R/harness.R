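# Experiment orchestration: acquisition and accuracy metrics, the
# metaprogram-vs-program prior comparison, ablation grids, and result
# serialization (JSON-lines plus a derived CSV).

#' Acquisition trial of a run record
#'
#' The smallest trial n such that every trial >= n was answered correctly;
#' `NA` if the final trial was incorrect (the rule was never acquired).
#'
#' @param record a run record from [online_run()] or [enum_online_run()]
#' @return integer trial index or `NA`
#' @examples
#' acquisition_trial(list(trials = lapply(c(FALSE, TRUE, TRUE),
#'                        function(k) list(correct = k))))
#' @export
acquisition_trial <- function(record) {
  cv <- vapply(record$trials, function(t) isTRUE(t$correct), TRUE)
  n <- NA_integer_
  for (i in rev(seq_along(cv))) {
    if (!cv[i]) break
    n <- i
  }
  n
}

#' Mean accuracy over run records
#'
#' @param records a list of run records
#' @return fraction of correct trials
#' @export
mean_accuracy <- function(records) {
  cv <- unlist(lapply(records, function(r)
    vapply(r$trials, function(t) isTRUE(t$correct), TRUE)))
  if (!length(cv)) stop("no trials")
  mean(cv)
}

#' Fraction of best hypotheses at least as simple as their program
#'
#' Over the per-trial best hypotheses carrying scores, the fraction with
#' metaprogram log prior >= program log prior (`ln p_M(H) >= ln p_P(H~)`).
#'
#' @param records a list of run records from [online_run()]
#' @param ci if TRUE, attach a 95% bootstrap confidence interval over runs
#' @return the fraction, optionally with attribute `"ci"`
#' @export
prior_comparison <- function(records, ci = FALSE) {
  per_run <- lapply(records, function(r) {
    vals <- vapply(r$trials, function(t) {
      if (is.null(t$best) || is.null(t$best$lpm)) return(NA)
      if (!is.finite(t$best$lpm) || !is.finite(t$best$lpp)) return(NA)
      t$best$lpm >= t$best$lpp
    }, TRUE)
    vals[!is.na(vals)]
  })
  all_vals <- unlist(per_run)
  if (!length(all_vals)) stop("no scored trials")
  frac <- mean(all_vals)
  if (ci && length(per_run) > 1L) {
    boots <- vapply(seq_len(200L), function(b) {
      mean(unlist(per_run[sample.int(length(per_run), replace = TRUE)]))
    }, 0)
    attr(frac, "ci") <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
  }
  frac
}

#' Run a model x function x seed experiment grid
#'
#' For each combination, generates (or reuses) an ordered example set for
#' the function, runs the model's online 11-trial protocol, and collects
#' run records. Records are appended as JSON lines and summarized in a CSV
#' (one row per run: function, model, seed, acquisition trial, accuracy).
#'
#' @param functions character vector of built-in function ids
#' @param models subset of `c("mpl", "enum", "object-mcmc")`
#' @param seeds integer vector of run seeds
#' @param steps search steps per trial for the MCMC models
#' @param alpha full-pool probability for the `"mpl"` model (the
#'   `"object-mcmc"` model always uses alpha = 0)
#' @param prior_mode `"full"`, `"pm"`, or `"pp"`
#' @param n_candidates,n_orderings example-set generation effort
#' @param out_dir optional directory for `runs.jsonl` and `summary.csv`
#' @param quiet suppress progress output
#' @return invisibly, a list with `records` and the `summary` data frame
#' @export
run_experiment <- function(functions = c("duplicate", "head"),
                           models = "mpl", seeds = 1:2,
                           steps = 1000L, alpha = 1.0, prior_mode = "full",
                           n_candidates = 200L, n_orderings = 200L,
                           out_dir = NULL, quiet = FALSE) {
  records <- list()
  rows <- list()
  for (fid in functions) {
    fn <- get_function(fid)
    for (model in models) {
      for (seed in seeds) {
        set.seed(seed)
        s <- generate_example_set(fn, n_candidates = n_candidates)
        s <- order_examples(fn, s, n_orderings = n_orderings)
        rr <- switch(model,
          "mpl" = online_run(s, search_params(steps_per_trial = steps,
                                              alpha = alpha,
                                              prior_mode = prior_mode),
                             seed = seed),
          "object-mcmc" = online_run(s, search_params(steps_per_trial = steps,
                                                      alpha = 0,
                                                      prior_mode = prior_mode),
                                     seed = seed),
          "enum" = enum_online_run(s, enumeration_budget(max_programs = steps),
                                   seed = seed),
          stop("unknown model: ", model))
        rr$function_id <- fid
        rr$model <- model
        records[[length(records) + 1L]] <- rr
        acc <- mean_accuracy(list(rr))
        acq <- acquisition_trial(rr)
        rows[[length(rows) + 1L]] <- data.frame(
          function_id = fid, model = model, seed = seed,
          acquisition = if (is.na(acq)) NA_integer_ else acq,
          accuracy = acc, stringsAsFactors = FALSE)
        if (!quiet) {
          message(sprintf("%s / %s / seed %d: accuracy %.2f, acquired %s",
                          fid, model, seed, acc,
                          if (is.na(acq)) "never" else paste("trial", acq)))
        }
      }
    }
  }
  summary <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    con <- file(file.path(out_dir, "runs.jsonl"), "w")
    for (rr in records) {
      writeLines(jsonlite::toJSON(run_record_json(rr), auto_unbox = TRUE,
                                  digits = NA, null = "null"), con)
    }
    close(con)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  }
  invisible(list(records = records, summary = summary))
}

# serializable view of a run record
run_record_json <- function(rr) {
  list(
    function_id = rr$function_id,
    model = rr$model,
    seed = rr$seed,
    trials = lapply(rr$trials, function(t) {
      out <- list(input = as.integer(t$input),
                  predicted = if (is.null(t$predicted)) NULL else as.integer(t$predicted),
                  observed = as.integer(t$observed),
                  correct = isTRUE(t$correct))
      if (!is.null(t$best)) {
        out$best <- t$best[intersect(names(t$best),
                                     c("key", "lpm", "lpp", "llik", "lpost"))]
      }
      out
    })
  )
}
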