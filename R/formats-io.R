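#' @keywords internal
"_PACKAGE"

# Canonical column order of the per-read methylation-call dialect (the
# tab-separated output of HMM-based CpG callers).
methcall_columns <- c(
  "chromosome", "strand", "start", "end", "read_name",
  "log_lik_ratio", "log_lik_methylated", "log_lik_unmethylated",
  "num_calling_strands", "num_motifs", "sequence"
)

count_cg <- function(sequence) {
  hits <- gregexpr("CG", sequence, fixed = TRUE)
  vapply(hits, function(h) if (identical(h[1L], -1L)) 0L else length(h), integer(1))
}

#' Read a per-read methylation-call table
#'
#' Parses the tab-separated per-read CpG call dialect emitted by signal-level
#' methylation callers: one row per read x CpG group, carrying the
#' log-likelihood ratio (LLR) of methylation, the two component
#' log-likelihoods, the group span on the reference (0-based, inclusive), the
#' number of CpG motifs in the group and the k-mer sequence context.
#'
#' Every row is validated: `end >= start`, `num_motifs >= 1`, a finite LLR
#' consistent with `log_lik_methylated - log_lik_unmethylated` (tolerance
#' 1e-6) when both components are present, and a sequence containing at least
#' `num_motifs` occurrences of `"CG"`. Rows failing validation are rejected
#' with the offending file line numbers; nothing is dropped silently
#' (parsed + rejected = data lines).
#'
#' @param path Path to a tab-separated file with a header naming the eleven
#'   dialect columns.
#' @param on_error `"skip"` rejects invalid rows with a warning; `"fail"`
#'   stops at the first invalid row.
#' @param quiet Suppress the parsed/rejected row-count message.
#' @return A tibble with the eleven dialect columns, plus attributes
#'   `n_parsed` and `n_rejected`.
#' @seealso [write_methcalls()], [site_mf()]
#' @export
read_methcalls <- function(path, on_error = c("skip", "fail"), quiet = FALSE) {
  on_error <- match.arg(on_error)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(methcall_columns, names(df))
  if (length(missing) > 0) {
    stop("methylation-call table ", path, " is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[methcall_columns]
  num_cols <- c("start", "end", "log_lik_ratio", "log_lik_methylated",
                "log_lik_unmethylated", "num_calling_strands", "num_motifs")
  for (cc in num_cols) df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))

  n_total <- nrow(df)
  bad <- !is.finite(df$log_lik_ratio) |
    !is.finite(df$start) | !is.finite(df$end) |
    df$end < df$start |
    !df$strand %in% c("+", "-") |
    is.na(df$num_motifs) | df$num_motifs < 1 |
    is.na(df$num_calling_strands) | df$num_calling_strands < 1 |
    (is.finite(df$log_lik_methylated) & is.finite(df$log_lik_unmethylated) &
       abs(df$log_lik_ratio - (df$log_lik_methylated - df$log_lik_unmethylated)) > 1e-6) |
    count_cg(df$sequence) < ifelse(is.na(df$num_motifs), 1, df$num_motifs)
  bad[is.na(bad)] <- TRUE

  if (any(bad)) {
    lines <- which(bad) + 1L  # header occupies line 1
    msg <- paste0("invalid methylation-call row(s) at file line(s): ",
                  paste(utils::head(lines, 20), collapse = ", "),
                  if (length(lines) > 20) sprintf(" (and %d more)", length(lines) - 20))
    if (on_error == "fail") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  for (cc in c("start", "end", "num_calling_strands", "num_motifs")) {
    df[[cc]] <- as.integer(df[[cc]])
  }
  if (!quiet) {
    message(sprintf("read_methcalls: %d row(s) parsed, %d rejected (%s)",
                    nrow(df), sum(bad), basename(path)))
  }
  out <- tibble::as_tibble(df)
  attr(out, "n_parsed") <- nrow(df)
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Write a per-read methylation-call table
#'
#' Counterpart of [read_methcalls()]; writes the canonical eleven-column
#' tab-separated dialect so that `read_methcalls(write_methcalls(x))` is an
#' identity on the records.
#'
#' @param calls Tibble with the eleven dialect columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_methcalls <- function(calls, path) {
  missing <- setdiff(methcall_columns, names(calls))
  if (length(missing) > 0) {
    stop("calls are missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  readr::write_tsv(calls[methcall_columns], path, progress = FALSE)
  invisible(path)
}

#' Read a bedMethyl per-site methylation table
#'
#' Parses the 9+2 column bedMethyl dialect (chrom, start, end, name, score,
#' strand, thickStart, thickEnd, itemRgb, coverage, percent methylated) used
#' by reference-anchored callers for per-site output. The percent field is
#' mapped to a methylation frequency in `[0, 1]`, coverage to `called_sites`,
#' and column 6 to the strand stratum (`+` = plus, `-` = minus, otherwise
#' pooled). Positions stay 0-based as in BED.
#'
#' @param path Path to a headerless bedMethyl file.
#' @param on_error `"skip"` or `"fail"` for rows with percent outside
#'   `[0, 100]` or negative coverage.
#' @param quiet Suppress the row-count message.
#' @return A per-site tibble with columns `chromosome`, `position`,
#'   `strand_stratum`, `pass_stratum`, `n_methylated`, `n_unmethylated`,
#'   `n_ambiguous` (NA: not carried by the format), `called_sites`, `mf`.
#' @export
read_bedmethyl <- function(path, on_error = c("skip", "fail"), quiet = FALSE) {
  on_error <- match.arg(on_error)
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (ncol(df) < 11) {
    stop("bedMethyl file ", path, " has ", ncol(df), " column(s); 11 required", call. = FALSE)
  }
  start <- suppressWarnings(as.numeric(df[[2]]))
  coverage <- suppressWarnings(as.numeric(df[[10]]))
  percent <- suppressWarnings(as.numeric(df[[11]]))
  bad <- is.na(start) | is.na(coverage) | is.na(percent) |
    percent < 0 | percent > 100 | coverage < 0
  if (any(bad)) {
    msg <- paste0("invalid bedMethyl row(s) at line(s): ",
                  paste(utils::head(which(bad), 20), collapse = ", "))
    if (on_error == "fail") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  keep <- !bad
  n_meth <- as.integer(round(coverage[keep] * percent[keep] / 100))
  out <- tibble::tibble(
    chromosome = df[[1]][keep],
    position = as.integer(start[keep]),
    strand_stratum = dplyr::case_when(
      df[[6]][keep] == "+" ~ "plus",
      df[[6]][keep] == "-" ~ "minus",
      TRUE ~ "pooled"
    ),
    pass_stratum = "combined",
    n_methylated = n_meth,
    n_unmethylated = as.integer(coverage[keep]) - n_meth,
    n_ambiguous = NA_integer_,
    called_sites = as.integer(coverage[keep]),
    mf = percent[keep] / 100
  )
  if (!quiet) {
    message(sprintf("read_bedmethyl: %d row(s) parsed, %d rejected (%s)",
                    nrow(out), sum(bad), basename(path)))
  }
  attr(out, "n_parsed") <- nrow(out)
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Write a per-site table in bedMethyl dialect
#'
#' @param site_table Per-site tibble as produced by [site_mf()] or
#'   [read_bedmethyl()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedmethyl <- function(site_table, path) {
  stopifnot(all(c("chromosome", "position", "called_sites", "mf") %in% names(site_table)))
  strand6 <- if ("strand_stratum" %in% names(site_table)) {
    dplyr::case_when(
      site_table$strand_stratum == "plus" ~ "+",
      site_table$strand_stratum == "minus" ~ "-",
      TRUE ~ "."
    )
  } else "."
  bed <- tibble::tibble(
    chrom = site_table$chromosome,
    start = site_table$position,
    end = site_table$position + 1L,
    name = "m",
    score = pmin(1000L, as.integer(site_table$called_sites)),
    strand = strand6,
    thickStart = site_table$position,
    thickEnd = site_table$position + 1L,
    itemRgb = "0,0,0",
    coverage = as.integer(site_table$called_sites),
    percent = site_table$mf * 100
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a gene map from BED
#'
#' Reads a BED4/BED6 gene map (0-based, half-open) and returns intervals
#' ordered by coordinate. Overlapping intervals are flagged (the
#' mitochondrial annotation contains genuine overlaps such as ATPase8/ATPase6)
#' and optionally reported with a warning.
#'
#' @param path Path to a BED4 or BED6 file.
#' @param warn_overlaps Warn when intervals overlap (default `TRUE`).
#' @return Tibble with columns `name`, `start`, `end` (0-based half-open),
#'   `strand`, ordered by `start`; attribute `overlapping` lists names of
#'   intervals overlapping their coordinate-sorted successor.
#' @export
read_gene_map <- function(path, warn_overlaps = TRUE) {
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (nrow(df) == 0) {
    warning("gene map ", path, " is empty", call. = FALSE)
    return(tibble::tibble(name = character(), start = integer(),
                          end = integer(), strand = character()))
  }
  if (ncol(df) < 4) stop("gene map ", path, " needs >= 4 BED columns", call. = FALSE)
  map <- tibble::tibble(
    name = df[[4]],
    start = as.integer(df[[2]]),
    end = as.integer(df[[3]]),
    strand = if (ncol(df) >= 6) df[[6]] else "."
  )
  if (any(is.na(map$start) | is.na(map$end)) || any(map$start >= map$end)) {
    stop("gene map ", path, " contains invalid intervals (need start < end)", call. = FALSE)
  }
  map <- dplyr::arrange(map, start, end)
  ov <- which(map$start[-1] < cummax(map$end[-nrow(map)]))
  overlapping <- unique(c(map$name[ov], map$name[ov + 1L]))
  if (length(ov) > 0 && warn_overlaps) {
    warning("gene map contains overlapping intervals: ",
            paste(overlapping, collapse = ", "), call. = FALSE)
  }
  attr(map, "overlapping") <- overlapping
  map
}

#' Write a gene map as BED6
#'
#' @param gene_map Tibble with `name`, `start`, `end`, `strand` (0-based,
#'   half-open), as returned by [read_gene_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_map <- function(gene_map, path) {
  bed <- tibble::tibble(
    chrom = "chrM",
    start = gene_map$start,
    end = gene_map$end,
    name = gene_map$name,
    score = 0L,
    strand = ifelse(gene_map$strand %in% c("+", "-"), gene_map$strand, ".")
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

read_summary_columns <- c("read_name", "mean_qscore", "aligned_target",
                          "aligned_length", "strand")

#' Read a per-read summary table
#'
#' Reads the per-read metadata table (one row per read: mean Phred quality
#' score, aligned contig, alignment length in bp, strand, and optionally a
#' pass flag). This mirrors a sequencer's sequencing-summary file; the
#' methylation-call tables do not carry qscores, so read-level stratification
#' draws on this table.
#'
#' @param path Path to a tab-separated file with a header.
#' @param quiet Suppress the row-count message.
#' @return Tibble with `read_name`, `mean_qscore`, `aligned_target`,
#'   `aligned_length`, `strand`, and `passed` if present in the file.
#' @export
read_read_summary <- function(path, quiet = FALSE) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(read_summary_columns, names(df))
  if (length(missing) > 0) {
    stop("read summary ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df$mean_qscore <- as.numeric(df$mean_qscore)
  df$aligned_length <- as.integer(df$aligned_length)
  if (any(df$aligned_length < 0, na.rm = TRUE) || any(df$mean_qscore < 0, na.rm = TRUE)) {
    stop("read summary ", path, ": aligned_length and mean_qscore must be >= 0",
         call. = FALSE)
  }
  if ("passed" %in% names(df)) df$passed <- as.logical(df$passed)
  if (!quiet) message(sprintf("read_read_summary: %d read(s) (%s)", nrow(df), basename(path)))
  tibble::as_tibble(df)
}

#' Write a per-read summary table
#'
#' @param reads Tibble as returned by [read_read_summary()] or
#'   [simulate_sample()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_read_summary <- function(reads, path) {
  keep <- intersect(c(read_summary_columns, "passed"), names(reads))
  missing <- setdiff(read_summary_columns, keep)
  if (length(missing) > 0) {
    stop("read summary is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  readr::write_tsv(reads[keep], path, progress = FALSE)
  invisible(path)
}

#' Read a cohort sample sheet
#'
#' A sample sheet binds call tables to a comparison: one row per sample with
#' `sample_id`, `group` (`case` or `control`), and optionally `tissue`,
#' `caller`, `calls_path`, `summary_path`. Paths are resolved relative to the
#' sheet's directory and must exist.
#'
#' @param path Path to a tab-separated sheet with a header.
#' @param check_files Verify that referenced files exist (default `TRUE`).
#' @return Tibble of sample sheet rows with resolved absolute paths.
#' @export
read_sample_sheet <- function(path, check_files = TRUE) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop("sample sheet ", path, " needs columns sample_id and group", call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("sample sheet ", path, ": duplicated sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(df$group), c("case", "control"))
  if (length(unknown) > 0) {
    stop("sample sheet ", path, ": unknown group label(s): ",
         paste(unknown, collapse = ", "), " (expected case/control)", call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  for (pc in intersect(c("calls_path", "summary_path"), names(df))) {
    resolved <- ifelse(file.exists(df[[pc]]), df[[pc]], file.path(base, df[[pc]]))
    if (check_files && !all(file.exists(resolved))) {
      stop("sample sheet ", path, ": missing file(s) in ", pc, ": ",
           paste(df[[pc]][!file.exists(resolved)], collapse = ", "), call. = FALSE)
    }
    df[[pc]] <- resolved
  }
  tibble::as_tibble(df)
}

#' Write a cohort sample sheet
#'
#' @param sheet Tibble with at least `sample_id` and `group`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  stopifnot(all(c("sample_id", "group") %in% names(sheet)))
  readr::write_tsv(sheet, path, progress = FALSE)
  invisible(path)
}
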