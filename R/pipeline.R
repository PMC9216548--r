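#' Build a validated pipeline run configuration
#'
#' Collects the paths and tuning parameters of the end-to-end analysis.
#' Defaults are the package's standard constants: tendency alpha 0.05,
#' Duda-Hart alpha 0.001, MPL method `iqr` with threshold 0.5, cluster
#' search up to k = 10. Values from a YAML config file (keys named as the
#' arguments) are applied first; arguments given here override them.
#' All alphas must lie in (0, 1\] and input paths are validated before
#' any computation.
#'
#' @param matrix path to the beta matrix (TSV/CSV).
#' @param samples optional path to the sample sheet.
#' @param out_dir output directory (created if absent).
#' @param group_a,group_b optional condition labels (matched against the
#'   sample sheet CONDITION column) enabling the differential stage.
#' @param alpha_tendency,alpha_dh significance levels.
#' @param mpl_method,mpl_threshold MPL measure and high-plasticity cut.
#' @param k_max cluster search upper bound.
#' @param seed integer seed recorded in the manifest.
#' @param config_file optional YAML file of defaults.
#' @return a validated `run_config` list.
#' @export
run_config <- function(matrix = NULL, samples = NULL, out_dir = "mplkit_out",
                       group_a = NULL, group_b = NULL,
                       alpha_tendency = 0.05, alpha_dh = 0.001,
                       mpl_method = "iqr", mpl_threshold = 0.5,
                       k_max = 10L, seed = 1L, config_file = NULL) {
  cfg <- list(matrix = matrix, samples = samples, out_dir = out_dir,
              group_a = group_a, group_b = group_b,
              alpha_tendency = alpha_tendency, alpha_dh = alpha_dh,
              mpl_method = mpl_method, mpl_threshold = mpl_threshold,
              k_max = k_max, seed = seed)
  if (!is.null(config_file)) {
    if (!file.exists(config_file))
      stop("config file not found: ", config_file, call. = FALSE)
    from_file <- yaml::read_yaml(config_file)
    supplied <- !vapply(cfg, is.null, logical(1)) &
      names(cfg) %in% names(as.list(match.call())[-1])
    for (key in intersect(names(from_file), names(cfg)))
      if (!supplied[[key]]) cfg[[key]] <- from_file[[key]]
  }
  for (a in c("alpha_tendency", "alpha_dh")) {
    v <- cfg[[a]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 || v > 1)
      stop("usage error: ", a, " must lie in (0, 1]", call. = FALSE)
  }
  if (!(cfg$mpl_method %in% MPL_METHODS))
    stop("usage error: unknown mpl_method '", cfg$mpl_method, "'",
         call. = FALSE)
  if (cfg$mpl_threshold < 0 || cfg$mpl_threshold > 1)
    stop("usage error: mpl_threshold must lie in [0, 1]", call. = FALSE)
  if (cfg$k_max < 2) stop("usage error: k_max must be >= 2", call. = FALSE)
  if (is.null(cfg$matrix))
    stop("usage error: a beta matrix path is required", call. = FALSE)
  if (!file.exists(cfg$matrix))
    stop("usage error: matrix file not found: ", cfg$matrix, call. = FALSE)
  if (!is.null(cfg$samples) && !file.exists(cfg$samples))
    stop("usage error: sample sheet not found: ", cfg$samples, call. = FALSE)
  if (xor(is.null(cfg$group_a), is.null(cfg$group_b)))
    stop("usage error: group_a and group_b must be given together",
         call. = FALSE)
  if (!is.null(cfg$group_a) && is.null(cfg$samples))
    stop("usage error: differential groups need a sample sheet",
         call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

stage_log <- function(stage, t0, n_in, n_out) {
  message(sprintf("[%s] sites in: %s, out: %s, elapsed: %.2fs",
                  stage, n_in, n_out,
                  as.numeric(proc.time()[3]) - t0))
}

#' Run the full methylation-plasticity pipeline
#'
#' Stages, in order: sample QC, r-beta profiles, plasticity scoring,
#' tendency classification, split-methylation detection, differential
#' methylation (when two condition groups are configured) and sample
#' stratification (when split sites were found). Each stage writes one
#' or more TSVs into the output directory; inputs on disk are never
#' modified. A JSON manifest listing every output file with its row
#' count is written last and returned.
#'
#' @param config a [run_config()].
#' @return the manifest (list), invisibly. Stage failures raise errors
#'   annotated with the stage name.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  emit <- function(name, df) {
    path <- file.path(config$out_dir, name)
    data.table::fwrite(df, path, sep = "\t", na = "NA", quote = FALSE)
    outputs[[name]] <<- list(file = name, rows = nrow(df))
    path
  }
  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  t0 <- as.numeric(proc.time()[3])
  m <- with_stage("read", read_beta_matrix(config$matrix))
  sheet <- if (!is.null(config$samples))
    with_stage("read", read_sample_sheet(config$samples)) else NULL

  qc <- with_stage("qc", qc_filter_samples(m))
  emit("qc_report.tsv",
       if (nrow(qc$report)) data.frame(SAMPLE = qc$report$sample_id,
                                       REASON = qc$report$reason)
       else data.frame(SAMPLE = character(), REASON = character()))
  mq <- qc$matrix
  if (!is.null(sheet)) sheet <- sheet[sheet$sample_id %in% sample_ids(mq), ]
  stage_log("qc", t0, ncol(m$values), ncol(mq$values))

  t0 <- as.numeric(proc.time()[3])
  profs <- with_stage("profiles", lapply(seq_len(nrow(mq$values)), function(i)
    rbeta_profile(mq$values[i, ], site_id = site_ids(mq)[i],
                  dataset_id = if (is.null(mq$dataset_id)) "all"
                               else mq$dataset_id)))
  with_stage("profiles",
             profiles_to_tsv(profs, file.path(config$out_dir,
                                              "profiles.tsv")))
  outputs[["profiles.tsv"]] <- list(file = "profiles.tsv",
                                    rows = 101L * length(profs))
  stage_log("profiles", t0, nrow(mq$values), length(profs))

  t0 <- as.numeric(proc.time()[3])
  plas <- with_stage("plasticity",
                     plasticity_table(mq, method = config$mpl_method))
  emit("plasticity.tsv", plas)
  high <- with_stage("plasticity",
                     high_plasticity_sites(mq, config$mpl_threshold,
                                           config$mpl_method))
  emit("high_plasticity.tsv", high)
  stage_log("plasticity", t0, nrow(mq$values), nrow(high))

  t0 <- as.numeric(proc.time()[3])
  tend <- with_stage("tendency",
                     tendency_table(mq, groups = sheet,
                                    alpha = config$alpha_tendency))
  emit("tendency.tsv", tend$calls)
  emit("tendency_summary.tsv", tend$summary)
  stage_log("tendency", t0, nrow(mq$values), nrow(tend$calls))

  t0 <- as.numeric(proc.time()[3])
  split <- with_stage("split",
                      detect_split_sites(mq, k_max = config$k_max,
                                         alpha = config$alpha_dh))
  emit("split.tsv", split$table)
  split_sites <- split$table$SITE[split$table$K >= 2]
  stage_log("split", t0, nrow(mq$values), length(split_sites))

  if (!is.null(config$group_a)) {
    t0 <- as.numeric(proc.time()[3])
    ga <- sheet$sample_id[sheet$condition == config$group_a]
    gb <- sheet$sample_id[sheet$condition == config$group_b]
    if (length(ga) == 0 || length(gb) == 0)
      stop("stage 'diff' failed: no samples with condition ",
           config$group_a, " / ", config$group_b, call. = FALSE)
    diff <- with_stage("diff",
                       differential_table(mq, ga, gb,
                                          alpha = config$alpha_tendency))
    emit("differential.tsv", diff)
    stage_log("diff", t0, nrow(mq$values), nrow(diff))
  }

  if (length(split_sites) > 0) {
    t0 <- as.numeric(proc.time()[3])
    strat <- with_stage("stratify",
                        stratify(mq, split_sites, calls = split))
    emit("stratification.tsv", strat$labels)
    grp_path <- file.path(config$out_dir, "stratification_groups.json")
    jsonlite::write_json(list(sites = strat$sites_used,
                              group_count = strat$group_count,
                              group_sizes = strat$group_sizes),
                         grp_path, auto_unbox = TRUE)
    outputs[["stratification_groups.json"]] <-
      list(file = "stratification_groups.json",
           rows = strat$group_count)
    stage_log("stratify", t0, length(split_sites), strat$group_count)
  }

  manifest <- list(seed = config$seed,
                   parameters = list(alpha_tendency = config$alpha_tendency,
                                     alpha_dh = config$alpha_dh,
                                     mpl_method = config$mpl_method,
                                     mpl_threshold = config$mpl_threshold,
                                     k_max = config$k_max),
                   outputs = unname(outputs))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Write a simulated corpus to disk
#'
#' Convenience wrapper for the command-line `simulate` subcommand: runs
#' [preset_corpus()] and writes `beta.tsv`, `samples.tsv` and `truth.tsv`
#' into a directory.
#'
#' @param out_dir destination directory.
#' @param seed RNG seed.
#' @return paths of the written files, invisibly.
#' @export
simulate_to_dir <- function(out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  corpus <- preset_corpus(seed)
  p1 <- write_beta_matrix(corpus$beta, file.path(out_dir, "beta.tsv"))
  p2 <- write_sample_sheet(corpus$samples, file.path(out_dir, "samples.tsv"))
  p3 <- file.path(out_dir, "truth.tsv")
  data.table::fwrite(corpus$truth$sites, p3, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(c(p1, p2, p3))
}
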