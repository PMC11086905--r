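# End-to-end orchestration: simulate (or load) -> rank per outcome ->
# compare to the reference form -> assemble the short form, with a run
# manifest capturing config, seeds, versions, timings and warnings.

#' Build a validated pipeline configuration
#'
#' The configuration is a plain list (readable from JSON via
#' [read_pipeline_config()]) with fields:
#' \describe{
#'   \item{seed}{master seed; all stage seeds derive from it.}
#'   \item{output_dir}{artifact directory.}
#'   \item{synthetic}{list of [synthetic_config()] arguments (simulated
#'     cohort), or `NULL` when `inputs` is given.}
#'   \item{inputs}{list of paths `bank`, `responses`, `outcomes` for a real
#'     cohort; responses are reverse-coded on load.}
#'   \item{cv}{list of [cv_config()] arguments shared by both outcomes.}
#'   \item{outcomes}{subset of `c("SI", "SI_P")` to rank.}
#'   \item{compare_top_n}{ranking depth for the reference comparison.}
#'   \item{quotas}{named per-criterion quota list.}
#'   \item{primary, fallback}{which outcome's ranking seeds the short form
#'     and which supplies missing criteria.}
#'   \item{reference_items}{item ids of the reference form (`NULL` for the
#'     built-in 8-item reference).}
#' }
#'
#' @param config list (or path to a JSON file) with the fields above; missing
#'   fields take defaults.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  defaults <- list(seed = 1L, output_dir = "sfirank-output",
                   synthetic = list(), inputs = NULL,
                   cv = list(), outcomes = c("SI", "SI_P"),
                   compare_top_n = 10L,
                   quotas = list(A = 2L, B1 = 2L, B2 = 2L, B3 = 2L, B4 = 1L),
                   primary = "SI", fallback = "SI_P",
                   reference_items = NULL)
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  stop_if(!all(cfg$outcomes %in% c("SI", "SI_P")),
          "outcomes must be a subset of SI, SI_P")
  stop_if(!(cfg$primary %in% cfg$outcomes),
          "primary outcome is not among the requested outcomes")
  if (!is.null(cfg$inputs)) {
    for (f in c("bank", "responses", "outcomes")) {
      pth <- cfg$inputs[[f]]
      stop_if(is.null(pth) || !file.exists(pth),
              sprintf("inputs$%s path missing or not found: %s", f,
                      pth %||% "<unset>"))
    }
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from JSON
#' @param path JSON file.
#' @return the parsed list (validate with [pipeline_config()]).
#' @export
read_pipeline_config <- function(path) {
  stop_if(!file.exists(path), paste0("config file not found: ", path))
  jsonlite::read_json(path, simplifyVector = TRUE)
}

load_or_simulate <- function(cfg) {
  if (!is.null(cfg$inputs)) {
    bank <- load_item_bank(cfg$inputs$bank)
    responses <- read_response_matrix(cfg$inputs$responses)
    responses <- apply_reverse_coding(responses, bank)
    oc <- utils::read.csv(cfg$inputs$outcomes, stringsAsFactors = FALSE)
    outcomes <- outcome_labels(oc$si, oc$si_p,
                               respondent_ids = as.character(oc[[1L]]))
    keep <- match(rownames(responses), outcomes$respondent_ids)
    stop_if(anyNA(keep), "outcome file does not cover all respondents")
    list(bank = bank, responses = responses,
         outcomes = outcome_labels(outcomes$si[keep], outcomes$si_p[keep],
                                   respondent_ids = rownames(responses)),
         simulated = FALSE)
  } else {
    args <- cfg$synthetic
    args$seed <- args$seed %||% (cfg$seed + 1000L)
    cohort <- generate_cohort(do.call(synthetic_config, args))
    cohort$simulated <- TRUE
    cohort
  }
}

#' Run the full pipeline
#'
#' Executes the stages in order -- data (simulate or load), ranking per
#' outcome, reference comparison, short-form assembly -- writing each stage's
#' artifacts before the next begins. Rerunning with the same configuration
#' reproduces identical artifacts.
#'
#' Artifacts under `output_dir`: cohort CSVs (when simulated),
#' `ranking_<outcome>.csv`, `sfi_<outcome>.csv`, `metrics_<outcome>.json`,
#' `overlap_<outcome>.json`, `short_form.csv`, `short_form.md`,
#' `manifest.json`.
#'
#' @param config a [pipeline_config()], raw list, or JSON path.
#' @return the run manifest (list), invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(if (is.list(config)) config else
    read_pipeline_config(config))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(cfg),
                   package_version = as.character(utils::packageVersion("sfirank")),
                   r_version = R.version.string,
                   stages = list(), warnings = list())
  t_all <- proc.time()[["elapsed"]]

  t0 <- proc.time()[["elapsed"]]
  cohort <- load_or_simulate(cfg)
  if (isTRUE(cohort$simulated)) {
    write_cohort(cohort, file.path(cfg$output_dir, "cohort"))
  }
  manifest$stages$data <- list(
    n = nrow(cohort$responses), p = ncol(cohort$responses),
    simulated = isTRUE(cohort$simulated),
    prevalence_si = cohort$outcomes$prevalence_si,
    prevalence_si_p = cohort$outcomes$prevalence_si_p,
    seconds = round(proc.time()[["elapsed"]] - t0, 2))

  rankings <- list()
  for (oc in cfg$outcomes) {
    t0 <- proc.time()[["elapsed"]]
    cvc <- do.call(cv_config, utils::modifyList(
      list(seed = cfg$seed + match(oc, c("SI", "SI_P"))), as.list(cfg$cv)))
    res <- run_repeated_cv(cohort, outcome = oc, config = cvc)
    rankings[[oc]] <- res$ranking
    tag <- tolower(sub("_", "", oc))
    write_ranking_table(res$ranking,
                        file.path(cfg$output_dir, sprintf("ranking_%s.csv", tag)))
    utils::write.csv(data.frame(item_id = names(res$sfi$counts),
                                sfi = res$sfi$counts),
                     file.path(cfg$output_dir, sprintf("sfi_%s.csv", tag)),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(as.list(res$metrics),
                         file.path(cfg$output_dir, sprintf("metrics_%s.json", tag)),
                         auto_unbox = TRUE, digits = NA)
    manifest$stages[[paste0("rank_", oc)]] <- list(
      cv = unclass(cvc), n_fold_models = res$sfi$n_fold_models,
      n_failed = res$n_failed,
      metrics = as.list(res$metrics),
      seconds = round(proc.time()[["elapsed"]] - t0, 2))
    if (res$n_failed > 0) {
      manifest$warnings[[paste0("dropped_fold_models_", oc)]] <- res$n_failed
    }
  }

  t0 <- proc.time()[["elapsed"]]
  reference <- if (is.null(cfg$reference_items)) {
    default_reference_short_form(cohort$bank)
  } else {
    reference_short_form(unlist(cfg$reference_items), cohort$bank)
  }
  for (oc in names(rankings)) {
    rep_ <- compare_rankings(rankings[[oc]], reference, cohort$bank,
                             top_n = cfg$compare_top_n)
    tag <- tolower(sub("_", "", oc))
    jsonlite::write_json(
      list(outcome = oc, top_n = rep_$top_n, similarity = rep_$similarity,
           ranking_proportions = as.list(rep_$ranking_proportions),
           reference_proportions = as.list(rep_$reference_proportions)),
      file.path(cfg$output_dir, sprintf("overlap_%s.json", tag)),
      auto_unbox = TRUE, digits = NA)
    manifest$stages[[paste0("compare_", oc)]] <- list(
      similarity = rep_$similarity)
  }
  manifest$stages$compare_seconds <- round(proc.time()[["elapsed"]] - t0, 2)

  t0 <- proc.time()[["elapsed"]]
  fallback <- if (!is.null(cfg$fallback) && cfg$fallback %in% names(rankings))
    rankings[[cfg$fallback]] else NULL
  sf <- assemble_short_form(rankings[[cfg$primary]], fallback, cohort$bank,
                            quotas = unlist(cfg$quotas))
  render_short_form(sf, cohort$bank, "csv",
                    path = file.path(cfg$output_dir, "short_form.csv"))
  render_short_form(sf, cohort$bank, "markdown",
                    path = file.path(cfg$output_dir, "short_form.md"))
  manifest$stages$build <- list(
    n_items = nrow(sf$selected),
    composition = as.list(table(sf$selected$criterion)),
    seconds = round(proc.time()[["elapsed"]] - t0, 2))

  manifest$total_seconds <- round(proc.time()[["elapsed"]] - t_all, 2)
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
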