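.pipeline_keys <- c("simulate", "control", "mf", "filters", "correction",
                    "report", "seed")

.write_stage_tsv <- function(x, path, stage, params) {
  header <- sprintf("# mtmeth %s | stage=%s | %s",
                    as.character(utils::packageVersion("mtmeth")), stage,
                    paste(names(params), unlist(params), sep = "=", collapse = " "))
  writeLines(header, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  path
}

#' Run the full workflow from one configuration
#'
#' Orchestrates the stages in dependency order: simulate a cohort and an
#' unmethylated amplicon control, write and re-read the call tables (so the
#' run exercises the on-disk formats), filter NUMT-like reads, compute
#' per-site methylation frequencies, estimate the control false-positive
#' rate and apply the per-site correction and exclusion, build the gene-level
#' and high-MF reports, and compare the two groups. Every output lands under
#' `out_dir` with a `manifest.yaml` recording the package version, the full
#' configuration, every seed, and the MD5 hash of every written file; report
#' tables carry a header comment naming the stage and its parameters.
#'
#' The configuration is a YAML file or list with keys `simulate` (with
#' `case`, `control` sub-lists of [sim_config()] arguments plus `n_case`,
#' `n_control`), `control` (`coverage_multiplier`, `fpr_call`), `mf`
#' ([mf_config()] arguments), `filters` (`min_alignment_bp`,
#' `qscore_cutoff`), `correction` (`exclusion_threshold`, `clamp_at_zero`),
#' `report` (`high_mf_threshold`), `seed`. Unknown top-level keys are an
#' error naming them. Rerunning an identical configuration reproduces
#' identical outputs.
#'
#' @param config Path to a YAML configuration or an equivalent list.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the cohort `sheet`, the `control_profile`,
#'   the named list of corrected per-site tables, the `comparison`, the
#'   report tibbles, and `manifest_path`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .pipeline_keys)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config$simulate)) stop("configuration needs a `simulate` block", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L

  sim <- config$simulate
  case_cfg <- do.call(sim_config, c(sim$case, list(seed = seed)))
  control_cfg <- do.call(sim_config, c(sim$control, list(seed = seed)))
  cohort <- simulate_cohort(case_cfg, control_cfg,
                            n_case = sim$n_case %||% 4L,
                            n_control = sim$n_control %||% 3L,
                            dir = file.path(out_dir, "data"), base_seed = seed)

  ctl_args <- config$control %||% list()
  ctl_sim <- simulate_control(control_cfg,
                              coverage_multiplier = ctl_args$coverage_multiplier %||% 4,
                              fpr_call = ctl_args$fpr_call %||% 0.03)
  write_methcalls(ctl_sim$calls, file.path(out_dir, "data", "control_calls.tsv"))

  mf_args <- config$mf %||% list()
  cfg_mf <- do.call(mf_config, mf_args)
  flt <- config$filters %||% list()
  min_align <- flt$min_alignment_bp %||% 1000L
  qcut <- flt$qscore_cutoff %||% 7
  corr <- config$correction %||% list()

  control_calls <- read_methcalls(file.path(out_dir, "data", "control_calls.tsv"),
                                  quiet = TRUE)
  profile <- estimate_fpr(control_calls, cfg_mf, caller_label = "simulated")

  site_tables <- list()
  for (i in seq_len(nrow(cohort$sheet))) {
    sid <- cohort$sheet$sample_id[i]
    calls <- read_methcalls(cohort$sheet$calls_path[i], quiet = TRUE)
    reads <- read_read_summary(cohort$sheet$summary_path[i], quiet = TRUE)
    reads <- stratify_pass_fail(reads, qcut)
    kept <- numt_filter(reads, min_align)$retained
    calls <- filter_calls(calls, kept)
    st <- site_mf(calls, cfg_mf)
    st <- adjust_mf(st, profile, clamp_at_zero = corr$clamp_at_zero %||% TRUE)
    st <- exclude_sites(st, profile,
                        exclusion_threshold = corr$exclusion_threshold %||% 0.2)$retained
    site_tables[[sid]] <- st
    .write_stage_tsv(st, file.path(out_dir, paste0(sid, "_sites.tsv")),
                     "correct", list(fpr = signif(profile$fpr, 6),
                                     exclusion_threshold = corr$exclusion_threshold %||% 0.2))
  }

  rep_args <- config$report %||% list()
  pooled <- dplyr::bind_rows(site_tables, .id = "sample_id")
  gene_map_in_range <- max(pooled$position) < 16569
  high <- if (gene_map_in_range) {
    high_mf_sites(pooled, threshold = rep_args$high_mf_threshold %||% 0.2)
  } else tibble::tibble()
  genes <- if (gene_map_in_range) per_gene_summary(pooled) else tibble::tibble()
  if (gene_map_in_range) {
    .write_stage_tsv(high, file.path(out_dir, "high_mf_sites.tsv"), "report",
                     list(threshold = rep_args$high_mf_threshold %||% 0.2))
    .write_stage_tsv(genes, file.path(out_dir, "per_gene_summary.tsv"), "report",
                     list(threshold = rep_args$high_mf_threshold %||% 0.2))
  }

  comparison <- compare_groups(site_tables, cohort$sheet)
  comp_tab <- tibble::tibble(
    pooling = c("site_pooled", "per_sample_mean"),
    statistic = c(comparison$site_pooled$statistic, comparison$per_sample_mean$statistic),
    p_value = c(comparison$site_pooled$p_value, comparison$per_sample_mean$p_value),
    n1 = c(comparison$site_pooled$n1, comparison$per_sample_mean$n1),
    n2 = c(comparison$site_pooled$n2, comparison$per_sample_mean$n2)
  )
  .write_stage_tsv(comp_tab, file.path(out_dir, "comparison.tsv"), "compare",
                   list(groups = paste(comparison$groups, collapse = "-vs-")))

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.yaml"))
  manifest <- list(
    package = "mtmeth",
    version = as.character(utils::packageVersion("mtmeth")),
    seed = seed,
    config = config,
    sample_seeds = as.list(cohort$seeds),
    files = stats::setNames(as.list(unname(tools::md5sum(files))),
                            sub(paste0(out_dir, "/?"), "", files))
  )
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(list(sheet = cohort$sheet, profile = profile,
                 site_tables = site_tables, comparison = comparison,
                 high_mf_sites = high, per_gene = genes,
                 manifest_path = manifest_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
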