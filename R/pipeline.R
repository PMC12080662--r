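#' Pipeline run configuration
#'
#' A fully serializable description of an end-to-end analysis run: input
#' paths (or simulation settings when no data are given), grid and design
#' parameters, model and MCMC settings, the master seed and the output
#' directory.  A stored configuration plus its seed reproduces a run
#' exactly; each stage derives its own seed deterministically from the
#' master seed so stages are individually reproducible.
#'
#' @param out_dir output directory of the run bundle.
#' @param data,covariates paths to a long-format CSV and a covariate CSV,
#'   or `NULL` to simulate a dataset.
#' @param n_persons,adherence_mean,adherence_sd simulation settings used
#'   when no data paths are given.
#' @param vars model variables (stress first).
#' @param n_days,slots_per_day grid parameters.
#' @param chains,min_iterations,max_iterations MCMC settings.
#' @param moderators moderator covariates (empty vector disables the
#'   moderation stage).
#' @param splits split schemes to fit (subset of `"aps_bs"`,
#'   `"perc_nonp"`; empty disables the stage).
#' @param stages stages to run, in pipeline order.
#' @param seed master seed.
#' @return an object of class `run_config` (a named list).
#' @export
run_config <- function(out_dir,
                       data = NULL, covariates = NULL,
                       n_persons = 20L, adherence_mean = 0.6924,
                       adherence_sd = 0, vars = c("stress", "mchr"),
                       n_days = 7L, slots_per_day = 24L,
                       chains = 2L, min_iterations = 2000L,
                       max_iterations = 10000L,
                       moderators = character(),
                       splits = character(),
                       stages = c("grid", "compare", "random_effects",
                                  "moderation", "splits"),
                       seed = 1L) {
  structure(list(out_dir = out_dir, data = data, covariates = covariates,
                 n_persons = as.integer(n_persons),
                 adherence_mean = adherence_mean,
                 adherence_sd = adherence_sd,
                 vars = vars, n_days = as.integer(n_days),
                 slots_per_day = as.integer(slots_per_day),
                 chains = as.integer(chains),
                 min_iterations = as.integer(min_iterations),
                 max_iterations = as.integer(max_iterations),
                 moderators = moderators, splits = splits,
                 stages = stages, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path file path for the YAML representation.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(run_config, raw[setdiff(names(raw), character())])
  cfg
}

stage_seed <- function(config, stage) {
  config$seed + 1000L * match(stage, c("simulate", "grid", "compare",
                                       "random_effects", "moderation",
                                       "splits"))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- data (load or simulate), grid alignment
#' and composites, three-model lag-0 comparison, random-effects
#' augmentation of the DIC-best model, moderation with the joint Wald test,
#' and symptom-split models -- writing per-stage outputs, a log with the
#' active design-decision flags, and a copy of the configuration into the
#' output directory.  A failing stage leaves a failure marker and skips the
#' stages downstream of it.
#'
#' @param config a [run_config()].
#' @return (invisibly) a `run_bundle` list with the stage results and
#'   output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  logit <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ..., "\n",
                             sep = "", file = logf, append = TRUE)
  cat("", file = logf)
  logit("emadsem ", as.character(utils::packageVersion("emadsem")),
        " pipeline run, master seed ", config$seed)
  logit("flags: priors=diffuse-proper(N/IG/IW); ",
        "DIC=observed-data, conditional on person-level parameters, ",
        "missing slots marginalized; grid collision rule=earliest kept; ",
        "postponement=independent Bernoulli")
  write_run_config(config, file.path(config$out_dir, "config.yaml"))
  bundle <- list(config = config, results = list(), failed = NULL)
  mcmc <- mcmc_settings(chains = config$chains,
                        min_iterations = config$min_iterations,
                        max_iterations = config$max_iterations,
                        seed = config$seed)
  grid <- grid_spec(config$n_days, config$slots_per_day)

  run_stage <- function(name, fun) {
    if (!is.null(bundle$failed)) {
      logit("stage ", name, ": skipped (", bundle$failed, " failed)")
      return(invisible(NULL))
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      logit("stage ", name, ": FAILED: ", conditionMessage(res))
      writeLines(conditionMessage(res),
                 file.path(config$out_dir, paste0("FAILED_", name)))
      bundle$failed <<- name
      return(invisible(NULL))
    }
    logit("stage ", name, ": ok")
    bundle$results[[name]] <<- res
    res
  }

  # data
  dat <- run_stage("data", function() {
    if (is.null(config$data)) {
      ds <- simulate_ema_dataset(
        population_params(), n_persons = config$n_persons,
        design = ema_design(n_days = config$n_days),
        grid = grid, adherence_mean = config$adherence_mean,
        adherence_sd = config$adherence_sd,
        seed = stage_seed(config, "simulate"))
      list(long = ds$long, covariates = ds$covariates)
    } else {
      cov <- if (!is.null(config$covariates))
        utils::read.csv(config$covariates) else NULL
      list(long = utils::read.csv(config$data), covariates = cov)
    }
  })

  gridded <- run_stage("grid", function() {
    g <- grid_ema_dataset(dat$long, grid)
    write_csv17(g, file.path(config$out_dir, "gridded.csv"))
    g
  })

  cmp <- if ("compare" %in% config$stages) run_stage("compare", function() {
    mc <- mcmc; mc$seed <- stage_seed(config, "compare")
    cmp <- compare_lag0_models(gridded, config$vars, mcmc = mc)
    utils::write.csv(cmp$table,
                     file.path(config$out_dir, "comparison.csv"),
                     row.names = FALSE)
    jsonlite::write_json(cmp$selection,
                         file.path(config$out_dir, "selection.json"),
                         auto_unbox = TRUE, digits = NA)
    for (m in names(cmp$fits)) {
      tb <- render_results_table(summary(cmp$fits[[m]]))
      utils::write.csv(tb, file.path(config$out_dir,
                                     paste0("model_", m, "_table.csv")),
                       row.names = FALSE)
      writeLines(format_results_table(tb),
                 file.path(config$out_dir,
                           paste0("model_", m, "_table.txt")))
    }
    cmp
  })

  if ("random_effects" %in% config$stages)
    run_stage("random_effects", function() {
      sel <- cmp$selection$recommended
      if (cmp$fits[[sel]]$spec$lag0_mode == "covariance")
        sel <- "C" # random effects need a directed wiring
      mc <- mcmc; mc$seed <- stage_seed(config, "random_effects")
      re <- add_random_effects(cmp$fits[[sel]], gridded, mcmc = mc)
      utils::write.csv(re$before_after,
                       file.path(config$out_dir, "before_after.csv"),
                       row.names = FALSE)
      re
    })

  if ("moderation" %in% config$stages && length(config$moderators))
    run_stage("moderation", function() {
      if (is.null(dat$covariates))
        stop("moderation requested but no covariates available",
             call. = FALSE)
      mc <- mcmc; mc$seed <- stage_seed(config, "moderation")
      mod <- fit_moderation(gridded, dat$covariates, config$vars,
                            moderators = config$moderators, mcmc = mc)
      jsonlite::write_json(
        list(path = mod$path, gamma = mod$gamma, wald = mod$wald),
        file.path(config$out_dir, "moderation.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "columns")
      mod
    })

  if ("splits" %in% config$stages && length(config$splits))
    run_stage("splits", function() {
      out <- list()
      for (sch in config$splits) {
        mc <- mcmc; mc$seed <- stage_seed(config, "splits")
        sp <- fit_split_symptoms(dat$long, sch, grid, mcmc = mc)
        tb <- render_results_table(summary(sp$fit))
        utils::write.csv(tb, file.path(config$out_dir,
                                       paste0("split_", sch, ".csv")),
                         row.names = FALSE)
        jsonlite::write_json(sp$contrast,
                             file.path(config$out_dir,
                                       paste0("contrast_", sch, ".json")),
                             auto_unbox = TRUE, digits = NA)
        out[[sch]] <- sp
      }
      out
    })

  logit("done")
  class(bundle) <- "run_bundle"
  invisible(bundle)
}

#' Publication-style results table
#'
#' Formats a posterior summary the way the basic-model results are usually
#' printed: path labels with directed arrows ("A \u2192 B" meaning B
#' regressed on A) or the undirected "A \u2190\u2192 B" for a covariance,
#' standardized estimate, two-tailed significance (p below 0.025 starred),
#' and the credible interval.  DIC, convergence and iteration counts are
#' attached as attributes and printed as a footer by
#' [format_results_table()].
#'
#' @param summ a [summary.rdsem_fit()] data.frame (standardized).
#' @return data.frame with columns `label`, `est`, `p`, `lci`, `uci`,
#'   `sig`.
#' @export
render_results_table <- function(summ) {
  if (nrow(summ) == 0)
    return(data.frame(label = character(), est = numeric(), p = numeric(),
                      lci = numeric(), uci = numeric(), sig = character()))
  lab <- vapply(summ$parameter, function(nm) {
    raw <- sub("^std:", "", nm)
    m <- regmatches(raw, regexec("^lag1:(.+)->(.+)$", raw))[[1]]
    if (length(m) == 3)
      return(sprintf("%s[t-1] \u2192 %s[t]", m[2], m[3]))
    m <- regmatches(raw, regexec("^lag0:(.+)<->(.+)$", raw))[[1]]
    if (length(m) == 3)
      return(sprintf("%s[t] \u2190\u2192 %s[t]", m[2], m[3]))
    m <- regmatches(raw, regexec("^lag0:(.+)->(.+)$", raw))[[1]]
    if (length(m) == 3)
      return(sprintf("%s[t] \u2192 %s[t]", m[2], m[3]))
    m <- regmatches(raw, regexec("^between_cor:(.+)\\.(.+)$", raw))[[1]]
    if (length(m) == 3)
      return(sprintf("%s \u2190\u2192 %s (between)", m[3], m[2]))
    raw
  }, character(1))
  out <- data.frame(label = lab, est = summ$est, p = summ$p,
                    lci = summ$lci, uci = summ$uci,
                    sig = ifelse(!is.na(summ$p) & summ$p < 0.025, "*", ""))
  attr(out, "dic") <- attr(summ, "dic")
  attr(out, "iterations") <- attr(summ, "iterations")
  attr(out, "converged") <- attr(summ, "converged")
  out
}

#' @rdname render_results_table
#' @param tbl output of [render_results_table()].
#' @export
format_results_table <- function(tbl) {
  header <- sprintf("%-32s %8s %8s %8s %8s %3s", "path", "est", "p",
                    "LCI", "UCI", "")
  lines <- c(header, strrep("-", nchar(header)))
  if (nrow(tbl))
    lines <- c(lines, sprintf("%-32s %8.3f %8s %8.3f %8.3f %3s",
                              tbl$label, tbl$est,
                              ifelse(is.na(tbl$p), "",
                                     sprintf("%.3f", tbl$p)),
                              tbl$lci, tbl$uci, tbl$sig))
  dic <- attr(tbl, "dic")
  if (!is.null(dic))
    lines <- c(lines, sprintf("DIC = %.3f (pD = %.1f), %d iterations%s",
                              dic["DIC"], dic["pD"],
                              attr(tbl, "iterations"),
                              if (isFALSE(attr(tbl, "converged")))
                                " [NOT converged]" else ""))
  lines
}
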