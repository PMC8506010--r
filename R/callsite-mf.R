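#' Configuration for call classification and site aggregation
#'
#' @param llr_upper LLR above which (strictly) a call is methylated
#'   (default 2, the caller's default threshold).
#' @param llr_lower LLR below which (strictly) a call is unmethylated
#'   (default -2). Calls in `[llr_lower, llr_upper]` are ambiguous and are
#'   excluded from both numerator and denominator of the methylation
#'   frequency.
#' @param split_groups Report each CpG of a multi-CpG k-mer group as its own
#'   site record (default `TRUE`).
#' @param min_called Minimum confidently-called coverage for a site to be
#'   reported (default 1).
#' @return A list of class `mf_config`.
#' @export
mf_config <- function(llr_upper = 2, llr_lower = -2, split_groups = TRUE,
                      min_called = 1L) {
  stopifnot(is.numeric(llr_upper), is.numeric(llr_lower), llr_lower < llr_upper,
            min_called >= 1)
  structure(list(llr_upper = llr_upper, llr_lower = llr_lower,
                 split_groups = isTRUE(split_groups),
                 min_called = as.integer(min_called)),
            class = "mf_config")
}

#' Classify per-read calls by log-likelihood ratio
#'
#' A call with LLR strictly greater than `llr_upper` is methylated, strictly
#' less than `llr_lower` unmethylated, and ambiguous otherwise (ties at the
#' thresholds are ambiguous: the rule is a strict inequality).
#'
#' @param llr Numeric vector of finite log-likelihood ratios.
#' @param config An [mf_config()].
#' @return Character vector in `{"methylated", "unmethylated", "ambiguous"}`.
#' @export
classify_calls <- function(llr, config = mf_config()) {
  if (!is.numeric(llr) || any(!is.finite(llr))) {
    stop("llr must be finite numeric", call. = FALSE)
  }
  out <- rep("ambiguous", length(llr))
  out[llr > config$llr_upper] <- "methylated"
  out[llr < config$llr_lower] <- "unmethylated"
  out
}

# Reference CpG positions of one group, derived from its k-mer context: the
# CG offsets in `sequence`, anchored so the first CpG sits at `start`.
group_positions_from_sequence <- function(start, end, sequence, num_motifs) {
  ofs <- gregexpr("CG", sequence, fixed = TRUE)[[1]]
  if (identical(ofs[1L], -1L) || length(ofs) < num_motifs) {
    return(NULL)
  }
  ofs <- ofs[seq_len(num_motifs)]
  pos <- start + ofs - ofs[1L]
  if (pos[num_motifs] != end) return(NULL)
  pos
}

#' Expand multi-CpG call groups into one record per reference CpG
#'
#' Callers group CpGs that fall in the same k-mer window and report a single
#' LLR for the group. Split-group reporting emits one record per CpG in the
#' group, each inheriting the full group LLR and read name (evidence is not
#' divided), so that methylation frequency can be computed per reference CpG
#' site.
#'
#' CpG positions within a group are taken from `reference_cpg_positions`
#' (0-based plus-strand cytosine coordinates) when supplied; otherwise they
#' are derived from the CG offsets in the group's `sequence` context anchored
#' at `start`. A group whose span does not contain exactly `num_motifs` CpGs
#' is an error naming the offending record.
#'
#' @param calls Methylation-call tibble (see [read_methcalls()]).
#' @param reference_cpg_positions Optional sorted integer vector of reference
#'   CpG positions (0-based).
#' @return The input with one row per CpG, plus columns `position` (0-based
#'   reference CpG coordinate) and `motif_index`.
#' @export
split_groups <- function(calls, reference_cpg_positions = NULL) {
  if (nrow(calls) == 0) {
    calls$position <- integer(0)
    calls$motif_index <- integer(0)
    return(calls)
  }
  single <- calls$num_motifs == 1L
  out_single <- calls[single, , drop = FALSE]
  out_single$position <- out_single$start
  out_single$motif_index <- 1L
  multi <- calls[!single, , drop = FALSE]
  if (nrow(multi) == 0) return(out_single)

  pos_list <- vector("list", nrow(multi))
  for (i in seq_len(nrow(multi))) {
    k <- multi$num_motifs[i]
    if (!is.null(reference_cpg_positions)) {
      pos <- reference_cpg_positions[reference_cpg_positions >= multi$start[i] &
                                       reference_cpg_positions <= multi$end[i]]
      if (length(pos) != k) {
        stop(sprintf(
          "split_groups: group %s:%d-%d (read %s) spans %d reference CpG(s), expected %d",
          multi$chromosome[i], multi$start[i], multi$end[i], multi$read_name[i],
          length(pos), k), call. = FALSE)
      }
    } else {
      pos <- group_positions_from_sequence(multi$start[i], multi$end[i],
                                           multi$sequence[i], k)
      if (is.null(pos)) {
        stop(sprintf(
          "split_groups: group %s:%d-%d (read %s) has a sequence context inconsistent with num_motifs = %d",
          multi$chromosome[i], multi$start[i], multi$end[i], multi$read_name[i], k),
          call. = FALSE)
      }
    }
    pos_list[[i]] <- pos
  }
  k_each <- multi$num_motifs
  out_multi <- multi[rep(seq_len(nrow(multi)), k_each), , drop = FALSE]
  out_multi$position <- as.integer(unlist(pos_list))
  out_multi$motif_index <- as.integer(sequence(k_each))
  out <- dplyr::bind_rows(out_single, out_multi)
  dplyr::arrange(out, .data$chromosome, .data$position, .data$read_name)
}

#' Per-site methylation frequency
#'
#' Classifies per-read calls by LLR, optionally expands CpG groups
#' ([split_groups()]), and aggregates them per reference CpG site into the
#' methylation frequency MF = n_methylated / (n_methylated + n_unmethylated):
#' the proportion of confidently-called reads supporting methylation at the
#' site. Ambiguous calls are counted (`n_ambiguous`) but excluded from both
#' numerator and denominator. Sites with fewer than `min_called` confident
#' calls are omitted.
#'
#' Stratification: `strand` restricts or splits by the read's alignment
#' strand (plus = L-strand, minus = H-strand of the mitochondrial genome);
#' `stratum` restricts or splits by the base-caller pass/fail stratum, which
#' requires `reads` (a per-read summary with a `passed` column, see
#' [stratify_pass_fail()]). With pooled strata the counts are exactly the sum
#' of the per-stratum counts, so the pooled MF is the coverage-weighted mean
#' of the stratum MFs.
#'
#' @param calls Methylation-call tibble.
#' @param config An [mf_config()].
#' @param strand One of `"pooled"`, `"plus"`, `"minus"`, `"both"`.
#' @param stratum One of `"combined"`, `"pass_only"`, `"fail_only"`, `"both"`.
#' @param reads Per-read summary tibble; required unless
#'   `stratum = "combined"`.
#' @param reference_cpg_positions Optional reference CpG positions passed to
#'   [split_groups()].
#' @param missing_reads What to do with calls whose read is absent from
#'   `reads` when a pass/fail stratum is requested: `"warn"` (drop with a
#'   warning) or `"error"`.
#' @return Per-site tibble with columns `chromosome`, `position` (0-based),
#'   `strand_stratum`, `pass_stratum`, `n_methylated`, `n_unmethylated`,
#'   `n_ambiguous`, `called_sites`, `mf`. Empty input yields an empty table.
#' @export
site_mf <- function(calls, config = mf_config(),
                    strand = c("pooled", "plus", "minus", "both"),
                    stratum = c("combined", "pass_only", "fail_only", "both"),
                    reads = NULL, reference_cpg_positions = NULL,
                    missing_reads = c("warn", "error")) {
  strand <- match.arg(strand)
  stratum <- match.arg(stratum)
  missing_reads <- match.arg(missing_reads)
  empty <- tibble::tibble(
    chromosome = character(), position = integer(),
    strand_stratum = character(), pass_stratum = character(),
    n_methylated = integer(), n_unmethylated = integer(),
    n_ambiguous = integer(), called_sites = integer(), mf = double()
  )
  if (nrow(calls) == 0) return(empty)
  if (length(unique(calls$chromosome)) > 1) {
    stop("site_mf expects calls on a single contig per invocation", call. = FALSE)
  }

  recs <- if (config$split_groups) {
    split_groups(calls, reference_cpg_positions)
  } else {
    dplyr::mutate(calls, position = .data$start)
  }
  recs$state <- classify_calls(recs$log_lik_ratio, config)

  if (stratum != "combined") {
    if (is.null(reads)) {
      stop("pass/fail stratification requires a per-read summary (`reads`)",
           call. = FALSE)
    }
    if (!"passed" %in% names(reads)) reads <- stratify_pass_fail(reads)
    unknown <- setdiff(unique(recs$read_name), reads$read_name)
    if (length(unknown) > 0) {
      msg <- sprintf("%d call read(s) absent from the read summary", length(unknown))
      if (missing_reads == "error") stop(msg, call. = FALSE)
      warning(msg, "; their calls are dropped", call. = FALSE)
      recs <- recs[!recs$read_name %in% unknown, , drop = FALSE]
    }
    recs <- dplyr::left_join(recs,
                             dplyr::select(reads, "read_name", "passed"),
                             by = "read_name")
    recs <- switch(stratum,
      pass_only = dplyr::filter(recs, .data$passed),
      fail_only = dplyr::filter(recs, !.data$passed),
      both = recs)
    recs$pass_stratum <- ifelse(recs$passed, "pass_only", "fail_only")
  } else {
    recs$pass_stratum <- "combined"
  }

  if (strand %in% c("plus", "minus")) {
    recs <- dplyr::filter(recs, .data$strand == if (strand == "plus") "+" else "-")
  }
  recs$strand_stratum <- if (strand == "pooled") "pooled" else {
    ifelse(recs$strand == "+", "plus", "minus")
  }
  if (nrow(recs) == 0) return(empty)

  grouping <- c("chromosome", "position", "strand_stratum")
  if (stratum == "both") grouping <- c(grouping, "pass_stratum") else {
    recs$pass_stratum <- stratum
    grouping <- c(grouping, "pass_stratum")
  }
  out <- recs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(
      n_methylated = sum(.data$state == "methylated"),
      n_unmethylated = sum(.data$state == "unmethylated"),
      n_ambiguous = sum(.data$state == "ambiguous"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      called_sites = .data$n_methylated + .data$n_unmethylated,
      mf = ifelse(.data$called_sites > 0,
                  .data$n_methylated / .data$called_sites, NA_real_)
    ) |>
    dplyr::filter(.data$called_sites >= config$min_called) |>
    dplyr::arrange(.data$position, .data$strand_stratum, .data$pass_stratum)
  out
}

#' Summarise a per-site table at the sample level
#'
#' The sample-level statistic reported throughout this workflow: the
#' unweighted mean (and sample SD) of the per-site methylation frequencies,
#' together with the site count and the mean confidently-called coverage.
#'
#' @param site_table Non-empty per-site tibble from [site_mf()]. If an
#'   adjusted column `mf_adjusted` is present (see [adjust_mf()]) it is
#'   summarised instead of the raw `mf`.
#' @return One-row tibble with `n_sites`, `mean_mf`, `sd_mf` (NA for a single
#'   site), `mean_coverage`.
#' @export
per_sample_summary <- function(site_table) {
  if (nrow(site_table) == 0) stop("empty site table", call. = FALSE)
  v <- if ("mf_adjusted" %in% names(site_table)) site_table$mf_adjusted else site_table$mf
  tibble::tibble(
    n_sites = nrow(site_table),
    mean_mf = mean(v),
    sd_mf = if (nrow(site_table) > 1) stats::sd(v) else NA_real_,
    mean_coverage = mean(site_table$called_sites)
  )
}
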