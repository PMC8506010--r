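#' Filter putative NUMT reads by alignment length
#'
#' Nuclear copies of mitochondrial DNA segments (NUMTs) can contaminate
#' reads aligned to the mitochondrial reference; most such segments are
#' shorter than 500 bp. Reads are therefore retained only when their
#' alignment to the mitochondrial reference is strictly longer than
#' `min_alignment_bp` (default 1000 bp, i.e. "more than 1 kb"): a read of
#' exactly 1000 bp is removed.
#'
#' @param reads Per-read summary tibble with `aligned_length`.
#' @param min_alignment_bp Exclusive lower bound in bp (default 1000).
#' @return List with `retained` and `removed` tibbles (a disjoint partition
#'   of the input). Restrict call tables to the retained reads with
#'   [filter_calls()].
#' @export
numt_filter <- function(reads, min_alignment_bp = 1000L) {
  stopifnot(min_alignment_bp > 0, "aligned_length" %in% names(reads))
  if (any(is.na(reads$aligned_length))) {
    stop("aligned_length must be present for every read", call. = FALSE)
  }
  keep <- reads$aligned_length > min_alignment_bp
  list(retained = reads[keep, , drop = FALSE],
       removed = reads[!keep, , drop = FALSE])
}

#' Restrict a call table to a set of reads
#'
#' @param calls Methylation-call tibble.
#' @param reads Per-read summary tibble (e.g. `numt_filter(...)$retained`).
#' @param missing_reads Calls whose read is absent from `reads` are dropped;
#'   `"warn"` (default) reports how many, `"error"` stops, `"silent"` says
#'   nothing (the usual case after an intentional filter).
#' @return The filtered call tibble.
#' @export
filter_calls <- function(calls, reads, missing_reads = c("silent", "warn", "error")) {
  missing_reads <- match.arg(missing_reads)
  unknown <- setdiff(unique(calls$read_name), reads$read_name)
  if (length(unknown) > 0 && missing_reads != "silent") {
    msg <- sprintf("%d read(s) in the call table are absent from the read set",
                   length(unknown))
    if (missing_reads == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  calls[calls$read_name %in% reads$read_name, , drop = FALSE]
}

#' Stratify reads into base-caller pass/fail strata by mean qscore
#'
#' The base-caller reports a Phred-scale mean quality score per read and
#' classifies reads below its cutoff as failed. The boundary is inclusive:
#' a read with mean qscore exactly at the cutoff (default 7, the base-caller
#' default) passes.
#'
#' @param reads Per-read summary tibble with `mean_qscore`.
#' @param qscore_cutoff Inclusive pass threshold (default 7).
#' @return `reads` with a (re)computed logical `passed` column; attribute
#'   `stratum_counts` holds the per-stratum read counts.
#' @export
stratify_pass_fail <- function(reads, qscore_cutoff = 7) {
  stopifnot(qscore_cutoff >= 0, "mean_qscore" %in% names(reads))
  reads$passed <- reads$mean_qscore >= qscore_cutoff
  attr(reads, "stratum_counts") <- c(pass = sum(reads$passed),
                                     fail = sum(!reads$passed))
  reads
}

#' Subsample reads to target coverages and trace the mean MF
#'
#' Emulates calling methylation on growing subsets of a run: reads are
#' shuffled once (seeded, without replacement) and prefixes of the shuffled
#' order are taken until each target mean coverage is reached, so the subsets
#' are nested across ascending targets and the coverage-vs-MF curve is
#' monotone in the data it uses. The subsampling unit is the read, since
#' coverage is read-driven.
#'
#' @param calls Methylation-call tibble.
#' @param reads Per-read summary tibble with `aligned_length`.
#' @param targets Ascending numeric vector of target mean coverages (X).
#' @param seed Integer seed; the same seed reproduces the same subsets.
#' @param contig_length Reference length in bp used to convert summed
#'   alignment length to mean coverage (default 16569, the human
#'   mitochondrial genome).
#' @param config An [mf_config()] for the per-subset MF computation.
#' @return Tibble with one row per target: `target`, `n_reads`,
#'   `mean_coverage` (achieved), `n_sites`, `mean_mf`. Targets above the
#'   available coverage are capped with a warning. Attribute `read_subsets`
#'   holds the read-name vectors (nested).
#' @export
subsample_to_coverage <- function(calls, reads, targets, seed = 1L,
                                  contig_length = 16569L, config = mf_config()) {
  stopifnot(length(targets) >= 1, !is.unsorted(targets))
  ord <- withr::with_seed(seed, sample.int(nrow(reads)))
  shuffled <- reads[ord, , drop = FALSE]
  cum_cov <- cumsum(shuffled$aligned_length) / contig_length
  total_cov <- cum_cov[length(cum_cov)]

  res <- vector("list", length(targets))
  subsets <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    t <- targets[i]
    if (t >= total_cov) {
      if (t > total_cov) {
        warning(sprintf("target %gX exceeds available coverage %.1fX; capped",
                        t, total_cov), call. = FALSE)
      }
      k <- nrow(shuffled)
    } else {
      k <- which(cum_cov >= t)[1]
    }
    sub_reads <- shuffled[seq_len(k), , drop = FALSE]
    sub_calls <- filter_calls(calls, sub_reads)
    st <- site_mf(sub_calls, config)
    res[[i]] <- tibble::tibble(
      target = t, n_reads = k, mean_coverage = cum_cov[k],
      n_sites = nrow(st),
      mean_mf = if (nrow(st) > 0) mean(st$mf) else NA_real_
    )
    subsets[[i]] <- sub_reads$read_name
  }
  out <- dplyr::bind_rows(res)
  attr(out, "read_subsets") <- subsets
  out
}
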