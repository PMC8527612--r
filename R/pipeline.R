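#' Feature table for one stage of a bundle
#'
#' Convenience wrapper assembling the per-CRM feature table for a stage:
#' ATAC and Pol II signal at merged peak-by-CRM windows (no extension),
#' PRO-seq plus+minus signal at TRE-prediction windows extended 50 bp,
#' reporter expression from the paired time point (12 h genomics pair with
#' 12 h expression; 20 h genomics pair with the 24 h reporter time point),
#' activity labels at the 2x threshold, and the promoter-overlap flag.
#'
#' @param bundle a `crm_bundle` (from [simulate_crm_study()] or
#'   [read_bundle()]).
#' @param stage `"12h"` or `"20h"` (genomic stage).
#' @param threshold activity threshold (default 2).
#' @return A `crm_features` data frame.
#' @export
bundle_features <- function(bundle, stage = c("12h", "20h"), threshold = 2) {
  stage <- match.arg(stage)
  expr_col <- if (stage == "12h") "expr_12h" else "expr_24h"
  proms <- promoter_windows(bundle$tss, chrom_sizes = bundle$chrom_sizes)
  build_features(bundle$crms, bundle$stages[[stage]],
                 expr = bundle$crms[[expr_col]], promoters = proms,
                 stage = stage, threshold = threshold,
                 chrom_sizes = bundle$chrom_sizes)
}

resolve_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config
}

config_fingerprint <- function(config) {
  raw <- serialize(config, NULL, version = 2)
  # small rolling checksum; provenance only, not cryptographic
  sprintf("%08x", Reduce(function(h, b) (h * 31 + b) %% 2^28,
                         as.integer(raw), accumulate = FALSE))
}

write_provenance <- function(out_dir, command, config, seed) {
  jsonlite::write_json(
    list(command = command, seed = seed,
         config_fingerprint = config_fingerprint(config),
         package = "crmpred",
         version = as.character(utils::packageVersion("crmpred")),
         config = config[setdiff(names(config), "bundle")]),
    file.path(out_dir, paste0(command, "_run_info.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
}

cv_from_config <- function(config, seed) {
  cv_spec(k = config$k %||% 5, repeats = config$repeats %||% 200,
          stratified = config$stratified %||% TRUE, seed = seed)
}

subset_mask <- function(tab, subset) {
  switch(subset %||% "all",
         all = rep(TRUE, nrow(tab)),
         promoter = tab$promoter_overlap,
         distal = !tab$promoter_overlap,
         stop("unknown subset: ", subset))
}

#' Run a pipeline command
#'
#' End-to-end orchestration over a configuration (a named list or the path
#' of a YAML file). Supported commands:
#'
#' * `simulate` — write a synthetic bundle (`sim` block passed to
#'   [sim_config()]) under `out`.
#' * `features` — write the per-CRM feature table for `stage` as TSV.
#' * `label` — write the labeled table plus the ranked-expression TSV.
#' * `classify` — repeated stratified CV for each model in `models`
#'   (preset names); writes per-repetition metrics, summaries and pooled
#'   ROC/PRC curves. `subset` (`all`/`promoter`/`distal`) selects the
#'   evaluation subset and `train_on` (`all`/`subset`) whether models are
#'   trained on the full table or within the subset.
#' * `regress` — as `classify` for the regression models (hold-out
#'   R-squared distributions).
#' * `report` — single JSON summary with all metrics and baselines.
#'
#' Every command writes a `<command>_run_info.json` provenance file (seed,
#' config fingerprint, package version). Given the same config and seed,
#' outputs are byte-identical across runs.
#'
#' @param command one of `simulate`, `features`, `label`, `classify`,
#'   `regress`, `report`.
#' @param config named list or YAML path. Common fields: `out` (output
#'   directory), `seed`, `stage`, `bundle_dir` (a directory written by
#'   `simulate`) or `bundle` (an in-memory `crm_bundle`), `models`,
#'   `repeats`, `k`, `subset`, `train_on`, `threshold`.
#' @return Invisibly, a list of the artifacts computed (also written to
#'   disk).
#' @export
crm_run <- function(command = c("simulate", "features", "label", "classify",
                                "regress", "report"),
                    config) {
  command <- match.arg(command)
  config <- resolve_config(config)
  out_dir <- config$out %||% stop("config$out (output directory) is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1)

  get_bundle <- function() {
    if (!is.null(config[["bundle"]])) return(config[["bundle"]])
    if (!is.null(config[["bundle_dir"]]))
      return(read_bundle(config[["bundle_dir"]]))
    stop("config needs 'bundle' or 'bundle_dir' for command ", command)
  }
  get_features <- function(stage) {
    tab <- bundle_features(get_bundle(), stage,
                           threshold = config$threshold %||% 2)
    tab
  }
  stage <- config$stage %||% "20h"

  result <- switch(command,
    simulate = {
      sim_args <- config$sim %||% list()
      sim_args$seed <- sim_args$seed %||% seed
      cfg <- do.call(sim_config, sim_args)
      if (!is.null(cfg$target_r2)) cfg <- calibrate_effect(cfg, cfg$target_r2)
      bundle <- simulate_crm_study(cfg)
      write_bundle(bundle, out_dir)
      list(bundle = bundle)
    },
    features = {
      tab <- get_features(stage)
      utils::write.table(tab, file.path(out_dir,
                                        sprintf("features_%s.tsv", stage)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(features = tab)
    },
    label = {
      tab <- get_features(stage)
      bundle <- get_bundle()
      ranked <- rank_expression(bundle$crms,
                                if (stage == "12h") "12h" else "24h",
                                threshold = config$threshold %||% 2)
      utils::write.table(tab, file.path(out_dir,
                                        sprintf("labeled_%s.tsv", stage)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(ranked,
                         file.path(out_dir,
                                   sprintf("ranked_expression_%s.tsv", stage)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(features = tab, ranked = ranked)
    },
    classify = ,
    regress = {
      task <- if (command == "classify") "classify" else "regress"
      tab <- get_features(stage)
      models <- config$models %||%
        if (task == "classify") c("ATAC", "dREG", "ATAC+dREG", "PolII")
        else c("ATAC", "dREG", "ATAC*dREG")
      cv <- cv_from_config(config, seed)
      mask <- subset_mask(tab, config$subset)
      results <- list()
      for (m in models) {
        spec <- model_spec(m, task = task)
        res <- cross_validate(tab, spec, cv, eval_subset = mask,
                              train_on = config$train_on %||% "all")
        results[[m]] <- res
        safe <- gsub("[^A-Za-z0-9]+", "_", m)
        utils::write.table(res$metrics,
                           file.path(out_dir, sprintf("%s_%s_%s_metrics.tsv",
                                                      task, stage, safe)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        if (task == "classify") {
          for (ct in c("roc", "prc")) {
            cur <- cv_curve(res, ct)
            utils::write.table(cur$points,
                               file.path(out_dir,
                                         sprintf("%s_%s_%s_%s.tsv", ct,
                                                 stage, safe,
                                                 config$subset %||% "all")),
                               sep = "\t", quote = FALSE, row.names = FALSE)
          }
        }
      }
      summ <- do.call(rbind, lapply(names(results), function(m) {
        r <- results[[m]]
        data.frame(model = m, stage = stage,
                   subset = config$subset %||% "all",
                   metric = setdiff(names(r$metrics), "repetition"),
                   mean = vapply(r$summary, function(s) s[["mean"]],
                                 numeric(1)),
                   sd = vapply(r$summary, function(s) s[["sd"]], numeric(1)),
                   baseline = if (task == "classify")
                     c(0.5, r$prevalence) else NA_real_,
                   row.names = NULL)
      }))
      utils::write.table(summ, file.path(out_dir,
                                         sprintf("%s_%s_summary.tsv", task,
                                                 stage)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(results = results, summary = summ)
    },
    report = {
      tab <- get_features(stage)
      cv <- cv_from_config(config, seed)
      cls <- lapply(c("ATAC", "dREG", "ATAC+dREG", "PolII"), function(m)
        cross_validate(tab, model_spec(m, task = "classify"), cv))
      names(cls) <- c("ATAC", "dREG", "ATAC+dREG", "PolII")
      reg <- lapply(c("ATAC", "dREG", "ATAC*dREG"), function(m)
        cross_validate(tab, model_spec(m, task = "regress"), cv))
      names(reg) <- c("ATAC", "dREG", "ATAC*dREG")
      rep_out <- list(
        stage = stage, n_crms = nrow(tab),
        prevalence = mean(tab$active),
        n_promoter_overlap = sum(tab$promoter_overlap),
        classification = lapply(cls, function(r)
          list(auroc = r$summary$auroc[["mean"]],
               auprc = r$summary$auprc[["mean"]],
               auprc_minus_baseline = r$summary$auprc[["mean"]] -
                 r$prevalence)),
        regression = lapply(reg, function(r)
          list(r2_cor = r$summary$r2_cor[["mean"]],
               r2_ss = r$summary$r2_ss[["mean"]])))
      jsonlite::write_json(rep_out, file.path(out_dir,
                                              sprintf("report_%s.json",
                                                      stage)),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      rep_out
    })
  write_provenance(out_dir, command, config, seed)
  invisible(result)
}
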