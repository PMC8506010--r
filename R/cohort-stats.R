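#' Mann-Whitney U test
#'
#' Two-sided nonparametric comparison of two groups of methylation
#' frequencies. Uses the exact distribution when the combined sample size is
#' at most `exact_max_n` and there are no ties, and the normal approximation
#' with tie and continuity correction otherwise. All p-values in this
#' workflow are exploratory and uncorrected for multiple testing.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @param exact_max_n Largest n1+n2 for which the exact distribution is used
#'   (default 16).
#' @return Object of class `mw_test`: `statistic` (U for `x` relative to
#'   `y`), `p_value`, `n1`, `n2`, `method`, `two_sided`.
#' @export
mann_whitney <- function(x, y, exact_max_n = 16L) {
  if (length(x) < 1 || length(y) < 1) {
    stop("both groups must contain at least one value", call. = FALSE)
  }
  stopifnot(is.numeric(x), is.numeric(y), all(is.finite(x)), all(is.finite(y)))
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= exact_max_n && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  structure(
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         n1 = length(x), n2 = length(y),
         method = if (exact) "Mann-Whitney U (exact)" else
           "Mann-Whitney U (normal approximation, tie-corrected)",
         two_sided = TRUE),
    class = "mw_test"
  )
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("%s: U = %g, n1 = %d, n2 = %d, two-sided p = %.4g (exploratory, uncorrected)\n",
              x$method, x$statistic, x$n1, x$n2, x$p_value))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with midranks under ties; the p-value uses the exact
#' distribution for at most 10 tie-free pairs and the t approximation
#' otherwise. A constant input vector has no defined rank correlation; the
#' result is flagged and `rho` is `NA`.
#'
#' @param x,y Paired numeric vectors, length >= 3.
#' @return Object of class `spearman_cor`: `rho`, `p_value`, `n_pairs`,
#'   `method`, `constant_input`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman's rho is undefined", call. = FALSE)
    return(structure(list(rho = NA_real_, p_value = NA_real_, n_pairs = length(x),
                          method = "Spearman (undefined: constant input)",
                          constant_input = TRUE),
                     class = "spearman_cor"))
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  exact <- length(x) <= 10 && !ties
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = exact))
  structure(
    list(rho = unname(ct$estimate), p_value = ct$p.value, n_pairs = length(x),
         method = if (exact) "Spearman (exact)" else "Spearman (t approximation)",
         constant_input = FALSE),
    class = "spearman_cor"
  )
}

#' @export
print.spearman_cor <- function(x, ...) {
  cat(sprintf("%s: rho = %.4f, n = %d, p = %.4g (exploratory, uncorrected)\n",
              x$method, x$rho, x$n_pairs, x$p_value))
  invisible(x)
}

.value_col <- function(tab) if ("mf_adjusted" %in% names(tab)) "mf_adjusted" else "mf"

#' Compare methylation between two cohorts
#'
#' Group-wise Mann-Whitney comparison of per-site methylation frequencies.
#' Two pooling units are computed and reported side by side, making the unit
#' of analysis explicit:
#' \describe{
#'   \item{site_pooled}{all per-site MFs across every sample of a group form
#'     one vector (large n; this is the unit behind very small cohort
#'     p-values, but it pseudo-replicates sites across samples).}
#'   \item{per_sample_mean}{one value per sample (the sample's mean MF);
#'     conservative, n = number of samples.}
#' }
#'
#' @param site_tables Named list of per-site tibbles, one per sample
#'   (`mf_adjusted` used when present); names are sample ids.
#' @param sheet Sample sheet tibble with `sample_id` and `group`
#'   (`case`/`control`); every sample must belong to exactly one group.
#' @return Object of class `cohort_comparison`: `group_summary` tibble,
#'   `site_pooled` and `per_sample_mean` (both `mw_test`, case vs control),
#'   `n1`/`n2` made explicit in each test.
#' @export
compare_groups <- function(site_tables, sheet) {
  stopifnot(is.list(site_tables), !is.null(names(site_tables)),
            all(c("sample_id", "group") %in% names(sheet)))
  if (anyDuplicated(sheet$sample_id)) {
    stop("each sample must be assigned to exactly one group", call. = FALSE)
  }
  missing <- setdiff(sheet$sample_id, names(site_tables))
  if (length(missing) > 0) {
    stop("no site table for sample(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  groups <- unique(sheet$group)
  if (length(groups) != 2) stop("exactly two groups required", call. = FALSE)

  long <- dplyr::bind_rows(lapply(sheet$sample_id, function(sid) {
    tab <- site_tables[[sid]]
    tibble::tibble(sample_id = sid,
                   group = sheet$group[sheet$sample_id == sid],
                   mf = tab[[.value_col(tab)]])
  }))
  for (g in groups) {
    if (sum(long$group == g) == 0) stop("group '", g, "' has zero sites", call. = FALSE)
  }
  g1 <- if ("case" %in% groups) "case" else groups[1]
  g2 <- setdiff(groups, g1)[1]

  group_summary <- long |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_samples = dplyr::n_distinct(.data$sample_id),
                     n_sites = dplyr::n(),
                     mean_mf = mean(.data$mf),
                     sd_mf = stats::sd(.data$mf), .groups = "drop")

  site_pooled <- mann_whitney(long$mf[long$group == g1], long$mf[long$group == g2])
  means <- long |>
    dplyr::group_by(.data$sample_id, .data$group) |>
    dplyr::summarise(mean_mf = mean(.data$mf), .groups = "drop")
  per_sample_mean <- mann_whitney(means$mean_mf[means$group == g1],
                                  means$mean_mf[means$group == g2])
  structure(
    list(groups = c(g1, g2), group_summary = group_summary,
         site_pooled = site_pooled, per_sample_mean = per_sample_mean),
    class = "cohort_comparison"
  )
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("Cohort comparison (%s vs %s); p-values exploratory, uncorrected\n",
              x$groups[1], x$groups[2]))
  print(x$group_summary)
  cat("site-pooled:     "); print(x$site_pooled)
  cat("per-sample mean: "); print(x$per_sample_mean)
  invisible(x)
}

#' Plus- vs minus-strand methylation concordance
#'
#' Pairs CpG sites measured on both read strands (plus = L-strand, minus =
#' H-strand), reports their Spearman correlation, the per-individual
#' plus-vs-minus Mann-Whitney test, and the mean plus-minus difference. Any
#' region's strand-stratified table can be supplied (e.g. a nuclear 45S rRNA
#' comparator region extracted via a BED interval).
#'
#' @param site_table Strand-stratified per-site tibble from
#'   `site_mf(..., strand = "both")` containing both `plus` and `minus`
#'   rows (`mf_adjusted` used when present).
#' @return Object of class `strand_concordance`: `n_pairs`, `correlation`
#'   (`spearman_cor`), `test` (`mw_test` plus vs minus), `mean_difference`
#'   (plus minus minus), `pairs` (wide tibble).
#' @export
strand_concordance <- function(site_table) {
  strata <- unique(site_table$strand_stratum)
  if (!all(c("plus", "minus") %in% strata)) {
    stop("both plus- and minus-strand site records are required", call. = FALSE)
  }
  vcol <- .value_col(site_table)
  wide <- site_table |>
    dplyr::select("chromosome", "position", "strand_stratum", value = dplyr::all_of(vcol)) |>
    tidyr::pivot_wider(names_from = "strand_stratum", values_from = "value")
  wide <- wide[is.finite(wide$plus) & is.finite(wide$minus), , drop = FALSE]
  if (nrow(wide) == 0) stop("no CpG positions shared by both strands", call. = FALSE)
  structure(
    list(n_pairs = nrow(wide),
         correlation = spearman_cor(wide$plus, wide$minus),
         test = mann_whitney(wide$plus, wide$minus),
         mean_difference = mean(wide$plus - wide$minus),
         pairs = wide),
    class = "strand_concordance"
  )
}

#' @export
print.strand_concordance <- function(x, ...) {
  cat(sprintf("Strand concordance over %d shared CpG site(s); mean plus-minus difference = %.4f\n",
              x$n_pairs, x$mean_difference))
  print(x$correlation); print(x$test)
  invisible(x)
}

#' Concordance between two methylation callers
#'
#' Compares per-site tables produced by two callers on the same samples at
#' two levels: the correlation of individual CpG-site MFs (pooled over
#' samples) and the correlation of per-sample mean MFs. Site-level
#' concordance between callers is typically much weaker than sample-level
#' concordance, so both are always reported side by side. Correlations with
#' fewer than 3 pairs are flagged as underpowered rather than computed.
#'
#' @param table_a,table_b Per-site tibbles with `position`, a value column
#'   (`mf_adjusted` or `mf`) and optionally `sample_id`.
#' @return Object of class `tool_concordance`: `per_site` and `per_sample`
#'   (`spearman_cor` or an underpowered placeholder), `n_shared_sites`,
#'   `n_samples`.
#' @export
tool_concordance <- function(table_a, table_b) {
  prep <- function(tab) {
    if (!"sample_id" %in% names(tab)) tab$sample_id <- "sample"
    tibble::tibble(sample_id = tab$sample_id, position = tab$position,
                   value = tab[[.value_col(tab)]])
  }
  a <- prep(table_a); b <- prep(table_b)
  joined <- dplyr::inner_join(a, b, by = c("sample_id", "position"),
                              suffix = c("_a", "_b"))
  if (nrow(joined) == 0) {
    stop("the two tables share no (sample, position) pairs", call. = FALSE)
  }
  underpowered <- function(n) {
    structure(list(rho = NA_real_, p_value = NA_real_, n_pairs = n,
                   method = "Spearman (underpowered: fewer than 3 pairs)",
                   constant_input = FALSE),
              class = "spearman_cor")
  }
  per_site <- if (nrow(joined) >= 3) {
    spearman_cor(joined$value_a, joined$value_b)
  } else underpowered(nrow(joined))
  means <- joined |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(mean_a = mean(.data$value_a), mean_b = mean(.data$value_b),
                     .groups = "drop")
  per_sample <- if (nrow(means) >= 3) {
    spearman_cor(means$mean_a, means$mean_b)
  } else underpowered(nrow(means))
  structure(
    list(per_site = per_site, per_sample = per_sample,
         n_shared_sites = nrow(joined), n_samples = nrow(means)),
    class = "tool_concordance"
  )
}

#' @export
print.tool_concordance <- function(x, ...) {
  cat(sprintf("Caller concordance: %d shared site value(s), %d sample(s)\n",
              x$n_shared_sites, x$n_samples))
  cat("per-site:   "); print(x$per_site)
  cat("per-sample: "); print(x$per_sample)
  invisible(x)
}
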