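#' Run the IRScore discovery pipeline over a set of cohorts
#'
#' End-to-end: per-cohort enrichment (ssGSEA or GSVA) scaled to NES within
#' each cohort, median-split univariate Cox per signature and cohort,
#' inverse-variance meta-analytic pooling, selection of prognostic
#' signatures at `alpha`, the IRScore signed sum per cohort with its own
#' median stratification, and a per-cohort survival evaluation (log-rank +
#' Cox high vs low). A run manifest records every modeling choice so reruns
#' are reproducible.
#'
#' @param cohorts List of [cohort_dataset()]s.
#' @param signatures A [signature_collection()].
#' @param method Enrichment algorithm: `"gsva"` (default) or `"ssgsea"`.
#' @param meta_model `"random_dl"` or `"fixed"`.
#' @param alpha Selection threshold on the pooled p-value.
#' @param ties Cox tie handling.
#' @param ssgsea_alpha ssGSEA rank-weight exponent.
#' @param out_dir Optional directory; when given, TSV tables and a JSON
#'   manifest are written there.
#' @param seed Recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return List with `nes` (per-cohort NES matrices), `overlap`,
#'   `cox_table`, `meta`, `verdicts`, `irscore` (per-cohort
#'   `irscore_table`s), `evaluation` (per-cohort stratification reports),
#'   and `manifest`.
#' @export
run_irscore_pipeline <- function(cohorts, signatures,
                                 method = c("gsva", "ssgsea"),
                                 meta_model = "random_dl", alpha = 0.05,
                                 ties = "efron", ssgsea_alpha = 0.25,
                                 out_dir = NULL, seed = NULL) {
  method <- match.arg(method)
  stopifnot(length(cohorts) >= 1L, inherits(signatures, "signature_collection"))
  nm <- vapply(cohorts, `[[`, character(1L), "name")
  if (anyDuplicated(nm)) stop("cohort names must be unique", call. = FALSE)
  names(cohorts) <- nm

  nes_list <- lapply(cohorts, function(co) {
    es <- if (method == "gsva") gsva_scores(co$expression, signatures)
          else ssgsea_scores(co$expression, signatures, alpha = ssgsea_alpha)
    normalize_to_nes(es)
  })
  surv_list <- lapply(cohorts, `[[`, "survival")
  cox_table <- cohort_signature_cox(nes_list, surv_list, ties = ties)
  sel <- select_signatures(cox_table, model = meta_model, alpha = alpha)

  irscore <- list(); evaluation <- list()
  for (cn in names(cohorts)) {
    tab <- tryCatch(compute_irscore(nes_list[[cn]], sel$verdicts),
                    error = function(e) e)
    irscore[[cn]] <- tab
    evaluation[[cn]] <- if (inherits(tab, "error")) tab
      else evaluate_stratification(tab, surv_list[[cn]])
  }

  manifest <- run_manifest(method = method, meta_model = meta_model, alpha = alpha,
                           ties = ties, ssgsea_alpha = ssgsea_alpha, seed = seed,
                           cohorts = nm, verdicts = sel$verdicts)
  res <- list(nes = nes_list,
              overlap = attr(nes_list[[1L]], "overlap"),
              cox_table = cox_table, meta = sel$meta, verdicts = sel$verdicts,
              n_selected = sel$n_selected, n_good = sel$n_good, n_bad = sel$n_bad,
              irscore = irscore, evaluation = evaluation, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' Score a new cohort against a frozen verdict list
#'
#' The validation use-case: NES is recomputed within the new cohort (scaling
#' never leaks across cohorts) and the frozen signed sum is applied, with a
#' fresh median split and survival evaluation.
#'
#' @param cohort A [cohort_dataset()].
#' @param signatures The [signature_collection()] the verdicts refer to.
#' @param verdicts Frozen verdict frame from a discovery run.
#' @inheritParams run_irscore_pipeline
#' @return List with `irscore` and `evaluation` for the new cohort.
#' @export
score_new_cohort <- function(cohort, signatures, verdicts,
                             method = c("gsva", "ssgsea"), ssgsea_alpha = 0.25) {
  method <- match.arg(method)
  es <- if (method == "gsva") gsva_scores(cohort$expression, signatures)
        else ssgsea_scores(cohort$expression, signatures, alpha = ssgsea_alpha)
  nes <- normalize_to_nes(es)
  tab <- compute_irscore(nes, verdicts)
  list(irscore = tab, evaluation = evaluate_stratification(tab, cohort$survival))
}

run_manifest <- function(method, meta_model, alpha, ties, ssgsea_alpha, seed,
                         cohorts, verdicts) {
  sel <- sort(verdicts$signature[verdicts$selected])
  list(package = "irscore",
       version = as.character(utils::packageVersion("irscore")),
       timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
       seed = seed,
       enrichment_method = method, ssgsea_alpha = ssgsea_alpha,
       meta_model = meta_model, alpha = alpha, ties = ties,
       cohorts = cohorts,
       n_selected = length(sel),
       verdict_digest = paste(sel, collapse = "|"))
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(res$cox_table, file.path(out_dir, "cox_table.tsv"))
  write_tsv(res$meta, file.path(out_dir, "meta_table.tsv"))
  write_tsv(res$verdicts, file.path(out_dir, "verdicts.tsv"))
  if (!is.null(res$overlap)) write_tsv(res$overlap, file.path(out_dir, "overlap_report.tsv"))
  for (cn in names(res$irscore)) {
    if (!inherits(res$irscore[[cn]], "error"))
      write_tsv(res$irscore[[cn]], file.path(out_dir, paste0("irscore_", cn, ".tsv")))
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Read a pipeline configuration file
#'
#' YAML with any subset of the keys `method`, `meta_model`, `alpha`, `ties`,
#' `ssgsea_alpha`, `seed`, plus a `simulation` block whose keys must match
#' [simulation_config()] arguments. Unknown keys are an error rather than
#' being silently ignored.
#'
#' @param path YAML file.
#' @return List with `pipeline` arguments and a `simulation` config (or
#'   `NULL`).
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("method", "meta_model", "alpha", "ties", "ssgsea_alpha", "seed",
               "simulation")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  sim <- NULL
  if (!is.null(cfg$simulation)) {
    sim_allowed <- names(formals(simulation_config))
    unknown <- setdiff(names(cfg$simulation), sim_allowed)
    if (length(unknown)) stop("unknown simulation key(s): ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    sim <- do.call(simulation_config, cfg$simulation)
  }
  list(pipeline = cfg[setdiff(names(cfg), "simulation")], simulation = sim)
}

#' Planted-signature recovery experiment
#'
#' Runs the full discovery pipeline (enrich, NES, median split, per-cohort
#' Cox, meta-analytic pooling, selection) on replicated synthetic
#' multi-cohort studies and scores recovery against the generator's ground
#' truth. Optionally evaluates the frozen verdicts on one extra held-out
#' cohort per replicate.
#'
#' @param cfg A [simulation_config()]; replicate r uses seed
#'   `cfg$seed + r * 1000`.
#' @param n_replicates Number of independent replicates.
#' @param method Enrichment algorithm for the pipeline runs.
#' @param heldout Also generate and score a held-out cohort per replicate.
#' @return `data.frame` with one row per replicate: `sensitivity` (fraction
#'   of planted signatures selected), `direction_accuracy` (fraction of
#'   recovered planted signatures with the correct good/bad call),
#'   `null_selection_rate`, and, when `heldout`, `heldout_hr` and
#'   `heldout_logrank_p` for the high-vs-low IRScore split of the held-out
#'   cohort.
#' @export
recovery_experiment <- function(cfg, n_replicates = 50L, method = "ssgsea",
                                heldout = TRUE) {
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    rcfg <- cfg
    rcfg$seed <- cfg$seed + r * 1000L
    gen <- generate_cohorts(rcfg, n_cohorts = rcfg$n_cohorts + as.integer(heldout))
    disc <- gen$cohorts[seq_len(rcfg$n_cohorts)]
    res <- run_irscore_pipeline(disc, gen$signatures, method = method)
    truth <- gen$truth$signatures
    v <- res$verdicts[match(truth$signature, res$verdicts$signature), ]
    planted <- truth$direction != "null"
    rec <- v$selected & planted
    sens <- if (any(planted)) sum(rec) / sum(planted) else NA_real_
    diracc <- if (any(rec)) mean(v$direction[rec] == truth$direction[rec]) else NA_real_
    nullrate <- if (any(!planted)) mean(v$selected[!planted]) else NA_real_
    row <- data.frame(replicate = r, sensitivity = sens,
                      direction_accuracy = diracc, null_selection_rate = nullrate)
    if (heldout && any(v$selected)) {
      ho <- score_new_cohort(gen$cohorts[[rcfg$n_cohorts + 1L]], gen$signatures,
                             res$verdicts, method = method)
      row$heldout_hr <- ho$evaluation$cox$hr
      row$heldout_logrank_p <- ho$evaluation$logrank$p
    } else if (heldout) {
      row$heldout_hr <- NA_real_
      row$heldout_logrank_p <- NA_real_
    }
    rows[[r]] <- row
  }
  do.call(rbind, rows)
}
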