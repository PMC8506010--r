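#' Estimate the false-positive rate from an unmethylated amplicon control
#'
#' Long-range PCR amplification erases base modifications, so a sequenced
#' amplicon of the mitochondrial genome is a methylation-free baseline: every
#' methylated call on it is a false positive. The false-positive rate is
#' FPR = (number of called methylated cytosines) / (number of all called
#' cytosines), where "called" means confidently classified (ambiguous calls
#' are excluded from both counts, consistent with the MF denominator).
#'
#' Several amplicons (e.g. two overlapping long-range PCR products) may be
#' supplied as a list; their calls are pooled for the global FPR, and the
#' per-amplicon per-site control MFs are retained so [exclude_sites()] can
#' apply either the pooled or the per-amplicon-maximum rule.
#'
#' @param control_calls Methylation-call tibble from the control, or a list
#'   of such tibbles (one per amplicon).
#' @param config An [mf_config()].
#' @param caller_label Label of the caller the control was run with; one FPR
#'   is estimated per caller and applied uniformly to that caller's samples.
#' @return An object of class `control_profile`: `fpr`, `per_site` (pooled
#'   per-site control MF table), `per_site_by_amplicon` (list, or NULL),
#'   `n_calls_total`, `n_calls_methylated`, `caller_label`.
#' @export
estimate_fpr <- function(control_calls, config = mf_config(),
                         caller_label = "caller") {
  amplicons <- if (is.data.frame(control_calls)) list(control_calls) else control_calls
  stopifnot(length(amplicons) >= 1, all(vapply(amplicons, is.data.frame, logical(1))))
  pooled <- dplyr::bind_rows(amplicons)
  recs <- if (config$split_groups) split_groups(pooled) else pooled
  state <- classify_calls(recs$log_lik_ratio, config)
  n_meth <- sum(state == "methylated")
  n_total <- n_meth + sum(state == "unmethylated")
  if (n_total == 0) {
    stop("control contains no confidently-called cytosines; cannot estimate FPR",
         call. = FALSE)
  }
  fpr <- n_meth / n_total
  if (fpr == 1) {
    warning("degenerate control: every confidently-called cytosine is methylated",
            call. = FALSE)
  }
  per_site <- site_mf(pooled, config)
  per_site_by_amplicon <- if (length(amplicons) > 1) {
    lapply(amplicons, site_mf, config = config)
  } else NULL
  structure(
    list(fpr = fpr, per_site = per_site,
         per_site_by_amplicon = per_site_by_amplicon,
         n_calls_total = n_total, n_calls_methylated = n_meth,
         caller_label = caller_label),
    class = "control_profile"
  )
}

#' @export
print.control_profile <- function(x, ...) {
  cat(sprintf(
    "<control_profile> %s: FPR = %.4f (%d methylated / %d called), %d control site(s)\n",
    x$caller_label, x$fpr, x$n_calls_methylated, x$n_calls_total, nrow(x$per_site)))
  invisible(x)
}

#' Adjust site methylation frequencies for the control false-positive rate
#'
#' Subtracts the control-derived FPR from each site's methylation frequency.
#' The subtraction is uniform, so site ordering by MF is preserved. Adjusted
#' values below zero are clamped to zero by default; disable clamping for
#' diagnostics (e.g. bias checks against a known truth).
#'
#' @param site_table Per-site tibble from [site_mf()].
#' @param profile A `control_profile` from [estimate_fpr()], or a bare
#'   numeric FPR in `[0, 1]`.
#' @param clamp_at_zero Clamp negative adjusted MFs to 0 (default `TRUE`).
#' @return `site_table` with an added `mf_adjusted` column.
#' @export
adjust_mf <- function(site_table, profile, clamp_at_zero = TRUE) {
  fpr <- if (inherits(profile, "control_profile")) profile$fpr else profile
  stopifnot(is.numeric(fpr), length(fpr) == 1, fpr >= 0, fpr <= 1)
  adj <- site_table$mf - fpr
  if (clamp_at_zero) adj <- pmax(0, adj)
  site_table$mf_adjusted <- adj
  site_table
}

#' Exclude sites that are methylated in the amplicon control
#'
#' A CpG site whose methylation frequency in the (methylation-free) PCR
#' product exceeds the exclusion threshold (strictly; default 0.2) is
#' systematically miscalled and is removed from downstream analyses. Sites
#' absent from the control cannot be tested and are retained (and listed).
#'
#' @param site_table Per-site tibble from [site_mf()] (possibly adjusted).
#' @param profile A `control_profile` from [estimate_fpr()].
#' @param exclusion_threshold Control-MF threshold, strict (default 0.2).
#' @param combine When the profile holds several overlapping amplicons:
#'   `"pooled"` tests the MF of their pooled calls (default), `"max"` the
#'   per-amplicon maximum.
#' @return List with `retained` (filtered site table), `excluded` (tibble of
#'   excluded positions with their control MF), and `not_in_control`
#'   (positions retained untested).
#' @export
exclude_sites <- function(site_table, profile, exclusion_threshold = 0.2,
                          combine = c("pooled", "max")) {
  combine <- match.arg(combine)
  stopifnot(inherits(profile, "control_profile"),
            exclusion_threshold > 0, exclusion_threshold < 1)
  control <- if (combine == "max" && !is.null(profile$per_site_by_amplicon)) {
    dplyr::bind_rows(profile$per_site_by_amplicon) |>
      dplyr::group_by(.data$position) |>
      dplyr::summarise(control_mf = max(.data$mf), .groups = "drop")
  } else {
    dplyr::tibble(position = profile$per_site$position,
                  control_mf = profile$per_site$mf)
  }
  if (nrow(control) == 0) {
    warning("empty control site map: no sites can be excluded; all retained",
            call. = FALSE)
    return(list(retained = site_table,
                excluded = tibble::tibble(position = integer(), control_mf = double()),
                not_in_control = sort(unique(site_table$position))))
  }
  excluded <- control[control$control_mf > exclusion_threshold, , drop = FALSE]
  not_in_control <- sort(setdiff(unique(site_table$position), control$position))
  if (length(not_in_control) > 0) {
    message(sprintf("exclude_sites: %d position(s) absent from the control were retained untested",
                    length(not_in_control)))
  }
  list(
    retained = site_table[!site_table$position %in% excluded$position, , drop = FALSE],
    excluded = dplyr::arrange(excluded, .data$position),
    not_in_control = not_in_control
  )
}
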