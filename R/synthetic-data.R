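#' Simulation configuration
#'
#' Defines a synthetic nanopore methylation-calling run with known ground
#' truth: reads placed on a (circular) contig, per-molecule CpG methylation
#' states, Gaussian LLR emissions, per-call state-flip error rates, a
#' qscore model coupling read quality to methylation, and optional NUMT
#' contaminant reads.
#'
#' Two truth regimes exist. `site_independent` draws each molecule's state at
#' each CpG independently with the per-site probability `truth` (native
#' tissue). `whole_molecule` draws each molecule entirely methylated with
#' probability `pi` (the dilution-series design, which mixes fully
#' methylated and fully unmethylated molecules); with `balanced = TRUE`
#' exactly `round(pi * n_reads)` molecules are methylated, mirroring a
#' pipetted dilution ratio rather than a Bernoulli draw.
#'
#' The emitted LLR is drawn from N(`llr_mean_meth`, `llr_sd`) for an
#' (observed-)methylated state and N(`llr_mean_unmeth`, `llr_sd`) otherwise
#' -- the simplest emission producing ambiguous calls in `[-2, 2]`; it is not
#' claimed to match any caller's true emission. `fpr_call`/`fnr_call` flip
#' the molecule's true state before emission. The read's mean qscore is
#' `qscore_base - qscore_delta * (methylated fraction of its covered CpGs) +
#' N(0, qscore_sd)`, clamped at 0; reads at or above `qscore_cutoff` pass.
#'
#' @param contig Contig name (default `"chrM"`).
#' @param contig_length Contig length in bp (default 16569).
#' @param cpg_positions 0-based plus-strand CpG cytosine positions; default a
#'   regular grid every 38 bp (~435 sites on the mitochondrial contig,
#'   matching its CpG density).
#' @param truth Per-site methylation probability (scalar recycled, or vector
#'   over sites); used in `site_independent` mode. Default 0.03, the scale of
#'   corrected blood-derived mtDNA methylation.
#' @param molecule_mode `"site_independent"` or `"whole_molecule"`.
#' @param pi Fraction of fully methylated molecules (`whole_molecule` only).
#' @param balanced Draw exactly `round(pi * n_reads)` methylated molecules.
#' @param coverage Target mean coverage (X); used to derive `n_reads` when
#'   `n_reads` is NULL.
#' @param n_reads Number of reads; overrides `coverage`.
#' @param read_length_mean,read_length_sdlog Log-normal read length model
#'   (mean in bp, log-scale SD; `sdlog = 0` gives fixed-length reads).
#'   Defaults 4900 bp / 0.5, the whole-genome run scale. Lengths are clamped
#'   to the contig.
#' @param circular Place reads on a circular contig (default `TRUE`, the
#'   mitochondrial genome); use `FALSE` for linear fragments.
#' @param llr_mean_meth,llr_mean_unmeth,llr_sd LLR emission parameters
#'   (defaults +6 / -6 / 3).
#' @param fpr_call,fnr_call Per-call state-flip probabilities (defaults 0).
#' @param qscore_base,qscore_delta,qscore_sd,qscore_cutoff Qscore model
#'   (defaults 10 / 4 / 1 / 7).
#' @param numt_fraction Fraction of reads that are short NUMT-like
#'   contaminants (alignment length uniform in 100-500 bp; default 0).
#' @param group_dist CpGs closer than this on the same read are reported as
#'   one multi-CpG call group (default 10 bp, the k-mer window scale).
#' @param seed Integer seed; every draw derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(contig = "chrM", contig_length = 16569L,
                       cpg_positions = NULL, truth = 0.03,
                       molecule_mode = c("site_independent", "whole_molecule"),
                       pi = NULL, balanced = FALSE,
                       coverage = 100, n_reads = NULL,
                       read_length_mean = 4900, read_length_sdlog = 0.5,
                       circular = TRUE,
                       llr_mean_meth = 6, llr_mean_unmeth = -6, llr_sd = 3,
                       fpr_call = 0, fnr_call = 0,
                       qscore_base = 10, qscore_delta = 4, qscore_sd = 1,
                       qscore_cutoff = 7,
                       numt_fraction = 0, group_dist = 10L, seed = 1L) {
  molecule_mode <- match.arg(molecule_mode)
  contig_length <- as.integer(contig_length)
  if (is.null(cpg_positions)) {
    cpg_positions <- seq(50L, contig_length - 50L, by = 38L)
  }
  cpg_positions <- sort(unique(as.integer(cpg_positions)))
  if (length(cpg_positions) < 1) stop("cpg_positions must be non-empty", call. = FALSE)
  if (any(cpg_positions < 0) || any(cpg_positions >= contig_length)) {
    stop("cpg_positions must lie in [0, contig_length)", call. = FALSE)
  }
  truth <- rep_len(as.numeric(truth), length(cpg_positions))
  stopifnot(all(truth >= 0 & truth <= 1),
            fpr_call >= 0, fpr_call <= 1, fnr_call >= 0, fnr_call <= 1,
            llr_sd > 0, qscore_sd >= 0, numt_fraction >= 0, numt_fraction <= 1,
            read_length_mean > 0, read_length_sdlog >= 0)
  if (molecule_mode == "whole_molecule") {
    if (is.null(pi) || length(pi) != 1 || pi < 0 || pi > 1) {
      stop("whole_molecule mode requires a scalar pi in [0, 1]", call. = FALSE)
    }
  }
  if (is.null(n_reads)) {
    n_reads <- max(1L, as.integer(round(coverage * contig_length / read_length_mean)))
  }
  structure(
    list(contig = contig, contig_length = contig_length,
         cpg_positions = cpg_positions, truth = truth,
         molecule_mode = molecule_mode, pi = pi, balanced = isTRUE(balanced),
         n_reads = as.integer(n_reads),
         read_length_mean = read_length_mean,
         read_length_sdlog = read_length_sdlog,
         circular = isTRUE(circular),
         llr_mean_meth = llr_mean_meth, llr_mean_unmeth = llr_mean_unmeth,
         llr_sd = llr_sd, fpr_call = fpr_call, fnr_call = fnr_call,
         qscore_base = qscore_base, qscore_delta = qscore_delta,
         qscore_sd = qscore_sd, qscore_cutoff = qscore_cutoff,
         numt_fraction = numt_fraction, group_dist = as.integer(group_dist),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Sequence context for a call group: 5 bp A flank, the member CGs separated
# by T fillers preserving their spacing. Contains exactly `k` CG motifs.
.group_sequence <- function(offsets) {
  k <- length(offsets)
  if (k == 1) return("AAAAACGAAAAA")
  parts <- character(2L * k + 1L)
  parts[1] <- "AAAAA"
  j <- 2L
  for (i in seq_len(k)) {
    parts[j] <- "CG"; j <- j + 1L
    if (i < k) {
      parts[j] <- strrep("T", offsets[i + 1L] - offsets[i] - 2L)
      j <- j + 1L
    }
  }
  parts[j] <- "AAAAA"
  paste(parts, collapse = "")
}

#' Simulate one methylation-calling run
#'
#' Realises a [sim_config()]: places reads uniformly on the contig (with
#' wrap-around when circular), draws each molecule's true CpG states per the
#' molecule mode, applies per-call state flips, emits Gaussian LLRs, groups
#' CpGs falling within `group_dist` on the same read into multi-CpG call
#' groups (the group inherits its first member's state and a single LLR),
#' and derives each read's mean qscore from its true methylated fraction.
#' Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_sample`:
#'   \describe{
#'     \item{calls}{per-read methylation-call tibble (the 11-column dialect).}
#'     \item{reads}{per-read summary tibble (`read_name`, `mean_qscore`,
#'       `aligned_target`, `aligned_length`, `strand`, `passed`, plus the
#'       simulation-only flag `numt`).}
#'     \item{truth}{list: `site_truth` (position, m), `molecule_truth`
#'       (read_name, position, methylated: the pre-flip state of every
#'       covered CpG), `numt_reads`.}
#'     \item{config}{the realised configuration.}
#'   }
#' @export
simulate_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .simulate_sample_impl(config))
}

.simulate_sample_impl <- function(cfg) {
  L <- cfg$contig_length
  P <- cfg$cpg_positions
  n <- cfg$n_reads
  n_numt <- as.integer(round(cfg$numt_fraction * n))
  n_mt <- n - n_numt

  len_mt <- if (cfg$read_length_sdlog == 0) {
    rep(round(cfg$read_length_mean), n_mt)
  } else {
    meanlog <- log(cfg$read_length_mean) - cfg$read_length_sdlog^2 / 2
    round(stats::rlnorm(n_mt, meanlog, cfg$read_length_sdlog))
  }
  len_mt <- pmin(pmax(len_mt, 50), L)
  len_numt <- if (n_numt > 0) round(stats::runif(n_numt, 100, 500)) else integer(0)
  len <- as.integer(c(len_mt, len_numt))
  is_numt <- c(rep(FALSE, n_mt), rep(TRUE, n_numt))

  starts <- if (cfg$circular) {
    sample.int(L, n, replace = TRUE) - 1L
  } else {
    as.integer(floor(stats::runif(n) * (L - len + 1)))
  }
  ends <- starts + len - 1L
  strand <- sample(c("+", "-"), n, replace = TRUE)
  read_name <- sprintf("read_%06d", seq_len(n))

  # covered CpG indices per read: [start, min(end, L-1)] plus the wrapped
  # prefix [0, end - L] for circular reads running past the origin
  i1 <- findInterval(starts - 1L, P) + 1L
  i2 <- findInterval(pmin(ends, L - 1L), P)
  counts1 <- pmax(0L, i2 - i1 + 1L)
  site_idx <- sequence(counts1, from = pmax(i1, 1L))
  read_idx <- rep(seq_len(n), counts1)
  if (cfg$circular) {
    counts2 <- ifelse(ends >= L, pmax(0L, findInterval(ends - L, P)), 0L)
    site_idx <- c(site_idx, sequence(counts2, from = 1L))
    read_idx <- c(read_idx, rep(seq_len(n), counts2))
  }

  # molecule truth
  if (cfg$molecule_mode == "whole_molecule") {
    mol_state <- if (cfg$balanced) {
      k <- round(cfg$pi * n)
      st <- integer(n)
      st[sample.int(n, k)] <- 1L
      st
    } else {
      stats::rbinom(n, 1L, cfg$pi)
    }
    truth_state <- mol_state[read_idx]
  } else {
    truth_state <- stats::rbinom(length(site_idx), 1L, cfg$truth[site_idx])
  }

  # observed state after per-call flips
  u <- stats::runif(length(site_idx))
  obs_state <- ifelse(truth_state == 1L,
                      ifelse(u < cfg$fnr_call, 0L, 1L),
                      ifelse(u < cfg$fpr_call, 1L, 0L))

  if (length(site_idx) == 0) {
    stop("no read covers any CpG position; increase n_reads or read length",
         call. = FALSE)
  }

  # group CpGs within group_dist on the same read; the group inherits its
  # first member's observed state and one LLR
  ord <- order(read_idx, site_idx)
  read_idx <- read_idx[ord]; site_idx <- site_idx[ord]
  truth_state <- truth_state[ord]; obs_state <- obs_state[ord]
  pos <- P[site_idx]
  new_grp <- c(TRUE, diff(read_idx) != 0L | diff(pos) > cfg$group_dist)
  grp <- cumsum(new_grp)
  n_grp <- max(grp, 0L)

  first_of_grp <- which(new_grp)
  grp_read <- read_idx[first_of_grp]
  grp_start <- pos[first_of_grp]
  last_of_grp <- c(first_of_grp[-1L] - 1L, length(pos))  # groups are contiguous runs
  grp_end <- pos[last_of_grp]
  grp_k <- as.integer(tabulate(grp, nbins = n_grp))
  grp_obs <- obs_state[first_of_grp]
  llr <- stats::rnorm(n_grp,
                      ifelse(grp_obs == 1L, cfg$llr_mean_meth, cfg$llr_mean_unmeth),
                      cfg$llr_sd)

  seqs <- character(n_grp)
  singleton <- grp_k == 1L
  seqs[singleton] <- "AAAAACGAAAAA"
  if (any(!singleton)) {
    for (g in which(!singleton)) {
      members <- pos[first_of_grp[g]:last_of_grp[g]]
      seqs[g] <- .group_sequence(members - members[1L])
    }
  }

  calls <- tibble::tibble(
    chromosome = cfg$contig,
    strand = strand[grp_read],
    start = as.integer(grp_start),
    end = as.integer(grp_end),
    read_name = read_name[grp_read],
    log_lik_ratio = llr,
    log_lik_methylated = llr / 2,
    log_lik_unmethylated = -llr / 2,
    num_calling_strands = 1L,
    num_motifs = grp_k,
    sequence = seqs
  )

  # qscore: depressed by the read's true methylated CpG fraction
  frac <- rep(0, n)
  covered <- tapply(truth_state, read_idx, mean)
  frac[as.integer(names(covered))] <- as.numeric(covered)
  q <- cfg$qscore_base - cfg$qscore_delta * frac +
    stats::rnorm(n, 0, cfg$qscore_sd)
  q <- pmax(0, q)

  reads <- tibble::tibble(
    read_name = read_name,
    mean_qscore = q,
    aligned_target = cfg$contig,
    aligned_length = len,
    strand = strand,
    passed = q >= cfg$qscore_cutoff,
    numt = is_numt
  )

  truth <- list(
    site_truth = tibble::tibble(position = P, m = cfg$truth),
    molecule_truth = tibble::tibble(read_name = read_name[read_idx],
                                    position = pos,
                                    methylated = truth_state),
    numt_reads = read_name[is_numt]
  )
  structure(list(calls = calls, reads = reads, truth = truth, config = cfg),
            class = "sim_sample")
}

#' @export
print.sim_sample <- function(x, ...) {
  cat(sprintf("<sim_sample> %s: %d read(s), %d call group(s), %d CpG site(s), seed %d\n",
              x$config$contig, nrow(x$reads), nrow(x$calls),
              length(x$config$cpg_positions), x$config$seed))
  invisible(x)
}

#' Simulate an unmethylated amplicon control
#'
#' A long-range PCR product carries no methylation, so the control is the
#' sample configuration with truth forced to zero and (optionally) deeper
#' coverage -- amplicon runs are much deeper than native runs. The per-call
#' false-methylation probability `fpr_call` is the error the control is
#' meant to measure; its output feeds [estimate_fpr()].
#'
#' @param config A [sim_config()]; its truth is overridden to all-zero.
#' @param coverage_multiplier Multiplier on `n_reads` (default 1).
#' @param fpr_call Per-call false-methylation probability (default 0.03,
#'   the observed scale of caller false positives).
#' @return A `sim_sample` (see [simulate_sample()]).
#' @export
simulate_control <- function(config, coverage_multiplier = 1, fpr_call = 0.03) {
  stopifnot(inherits(config, "sim_config"), coverage_multiplier > 0)
  cfg <- config
  cfg$truth <- rep(0, length(cfg$cpg_positions))
  cfg$molecule_mode <- "site_independent"
  cfg$fpr_call <- fpr_call
  cfg$n_reads <- max(1L, as.integer(round(cfg$n_reads * coverage_multiplier)))
  simulate_sample(cfg)
}

#' Simulate a two-group cohort
#'
#' Draws `n_case` + `n_control` samples from two configurations sharing the
#' same CpG positions, with per-sample seeds derived deterministically from
#' `base_seed`. When `dir` is given, writes an immediately runnable input
#' tree (per-sample call and read-summary TSVs, a sample sheet, and a YAML
#' manifest recording every seed); otherwise the samples stay in memory.
#'
#' @param case_config,control_config [sim_config()]s with identical
#'   `cpg_positions`.
#' @param n_case,n_control Samples per group.
#' @param dir Output directory, or NULL for in-memory results.
#' @param base_seed Base seed; sample i uses `base_seed + 1000 * i`.
#' @return List: `sheet` (sample sheet tibble; with file paths when written),
#'   `samples` (named list of `sim_sample`s), `seeds` (named integer vector),
#'   `dir`.
#' @export
simulate_cohort <- function(case_config, control_config,
                            n_case = 4L, n_control = 3L,
                            dir = NULL, base_seed = NULL) {
  stopifnot(inherits(case_config, "sim_config"),
            inherits(control_config, "sim_config"),
            n_case >= 1, n_control >= 1)
  if (!identical(case_config$cpg_positions, control_config$cpg_positions)) {
    stop("group configs must share cpg_positions", call. = FALSE)
  }
  if (is.null(base_seed)) base_seed <- case_config$seed
  ids <- c(sprintf("case_%d", seq_len(n_case)),
           sprintf("control_%d", seq_len(n_control)))
  groups <- c(rep("case", n_case), rep("control", n_control))
  seeds <- as.integer(base_seed + 1000L * seq_along(ids))
  names(seeds) <- ids

  samples <- vector("list", length(ids))
  names(samples) <- ids
  for (i in seq_along(ids)) {
    cfg <- if (groups[i] == "case") case_config else control_config
    cfg$seed <- seeds[i]
    samples[[i]] <- simulate_sample(cfg)
  }
  sheet <- tibble::tibble(sample_id = ids, group = groups,
                          tissue = "simulated", caller = "simulated")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    calls_path <- file.path(dir, paste0(ids, "_calls.tsv"))
    summary_path <- file.path(dir, paste0(ids, "_reads.tsv"))
    for (i in seq_along(ids)) {
      write_methcalls(samples[[i]]$calls, calls_path[i])
      write_read_summary(samples[[i]]$reads, summary_path[i])
    }
    sheet$calls_path <- calls_path
    sheet$summary_path <- summary_path
    # the on-disk sheet uses paths relative to its own directory, so the
    # output tree is relocatable and reruns are byte-identical
    disk_sheet <- sheet
    disk_sheet$calls_path <- basename(calls_path)
    disk_sheet$summary_path <- basename(summary_path)
    write_sample_sheet(disk_sheet, file.path(dir, "sample_sheet.tsv"))
    manifest <- list(
      base_seed = base_seed,
      seeds = as.list(seeds),
      n_case = n_case, n_control = n_control,
      case_config = .config_as_list(case_config),
      control_config = .config_as_list(control_config)
    )
    yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  }
  list(sheet = sheet, samples = samples, seeds = seeds, dir = dir)
}

.config_as_list <- function(cfg) {
  out <- unclass(cfg)
  out$cpg_positions <- as.integer(out$cpg_positions)
  out$truth <- as.numeric(out$truth)
  out
}
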