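#' Bundled mitochondrial gene map
#'
#' The standard human mitochondrial (rCRS-style, 16,569 bp) annotation: the
#' 13 protein-coding genes, 2 rRNAs, 22 tRNAs, and the non-coding D-loop
#' (which wraps the origin and is represented by two intervals). Coordinates
#' are 0-based half-open as in BED. Known biological overlaps (e.g.
#' ATPase8/ATPase6, ND4L/ND4, tRNA-Ile/tRNA-Gln) are present and flagged.
#' Users may substitute any BED via [read_gene_map()].
#'
#' @return Gene-map tibble (see [read_gene_map()]).
#' @export
mito_gene_map <- function() {
  path <- system.file("extdata", "mito_genes.bed", package = "mtmeth", mustWork = TRUE)
  read_gene_map(path, warn_overlaps = FALSE)
}

#' Annotate 1-based mitochondrial positions with gene labels
#'
#' Maps each position to the covering gene interval. Positions outside every
#' interval are labelled `"non-coding"`. Positions covered by ATPase6 or
#' ATPase8 are reported with the combined label `"ATPase6/8"` (the two genes
#' overlap and sites there are conventionally reported jointly); other
#' multiply-covered positions get the covering names joined with `/`.
#'
#' Annotation is total over `[1, contig_length]`; positions outside that
#' range are an error. Note that reporting positions are 1-based
#' (`chrM:<pos>`), while [site_mf()] tables are 0-based: convert with
#' `position + 1`.
#'
#' @param positions Integer vector of 1-based positions.
#' @param gene_map Gene-map tibble (default the bundled [mito_gene_map()]).
#' @param contig_length Contig length in bp (default 16569).
#' @return Character vector of gene labels, one per position.
#' @export
annotate_positions <- function(positions, gene_map = mito_gene_map(),
                               contig_length = 16569L) {
  if (any(!is.finite(positions)) || any(positions < 1) || any(positions > contig_length)) {
    stop("positions must lie in [1, ", contig_length, "]", call. = FALSE)
  }
  vapply(positions, function(p) {
    covering <- gene_map$name[gene_map$start < p & p <= gene_map$end]
    if (length(covering) == 0) return("non-coding")
    covering[covering %in% c("ATPase6", "ATPase8")] <- "ATPase6/8"
    covering <- unique(covering)
    paste(covering, collapse = "/")
  }, character(1))
}

.report_value_col <- function(site_table) {
  if ("mf_adjusted" %in% names(site_table)) "mf_adjusted" else "mf"
}

#' List unique CpG sites with high methylation frequency
#'
#' Collects the unique reference CpG positions whose (adjusted, if present)
#' methylation frequency exceeds `threshold` (strictly) in at least one
#' sample, deduplicated across samples, with gene labels and a 1-based
#' `chrM:<pos>` site label.
#'
#' @param site_table Per-site tibble (adjusted and exclusion-filtered), for
#'   one sample or, with a `sample_id` column, for several.
#' @param threshold Strict MF threshold (default 0.2).
#' @param gene_map Gene map for annotation.
#' @param contig_length Contig length for annotation bounds.
#' @return Tibble with `chromosome`, `position` (1-based), `site_label`,
#'   `gene`, `n_samples` (samples exceeding the threshold there), `max_mf`;
#'   one row per unique position, ordered by position. `nrow()` is the
#'   unique-site count.
#' @export
high_mf_sites <- function(site_table, threshold = 0.2, gene_map = mito_gene_map(),
                          contig_length = 16569L) {
  if (nrow(site_table) == 0) {
    return(tibble::tibble(chromosome = character(), position = integer(),
                          site_label = character(), gene = character(),
                          n_samples = integer(), max_mf = double()))
  }
  vcol <- .report_value_col(site_table)
  if (!"sample_id" %in% names(site_table)) site_table$sample_id <- "sample"
  hits <- site_table[site_table[[vcol]] > threshold, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(tibble::tibble(chromosome = character(), position = integer(),
                          site_label = character(), gene = character(),
                          n_samples = integer(), max_mf = double()))
  }
  hits$value <- hits[[vcol]]
  out <- hits |>
    dplyr::group_by(.data$chromosome, .data$position) |>
    dplyr::summarise(n_samples = dplyr::n_distinct(.data$sample_id),
                     max_mf = max(.data$value), .groups = "drop") |>
    dplyr::mutate(position = .data$position + 1L) |>
    dplyr::arrange(.data$position)
  out$site_label <- sprintf("%s:%d", out$chromosome, out$position)
  out$gene <- annotate_positions(out$position, gene_map, contig_length)
  out[, c("chromosome", "position", "site_label", "gene", "n_samples", "max_mf")]
}

#' Per-gene methylation summary
#'
#' Aggregates a per-site table by gene (the backing table of a radar-style
#' genome view): site count, mean and maximum MF per gene, ordered by the
#' gene's genomic start coordinate (non-coding last).
#'
#' @param site_table Per-site tibble; uses `mf_adjusted` if present.
#' @param gene_map Gene map for annotation.
#' @param contig_length Contig length for annotation bounds.
#' @return Tibble with `gene`, `n_sites`, `mean_mf`, `max_mf`.
#' @export
per_gene_summary <- function(site_table, gene_map = mito_gene_map(),
                             contig_length = 16569L) {
  if (nrow(site_table) == 0) {
    return(tibble::tibble(gene = character(), n_sites = integer(),
                          mean_mf = double(), max_mf = double()))
  }
  vcol <- .report_value_col(site_table)
  tab <- site_table
  tab$gene <- annotate_positions(tab$position + 1L, gene_map, contig_length)
  tab$value <- tab[[vcol]]
  out <- tab |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_sites = dplyr::n(),
                     mean_mf = mean(.data$value),
                     max_mf = max(.data$value), .groups = "drop")
  gene_order <- gene_map |>
    dplyr::mutate(name = ifelse(.data$name %in% c("ATPase6", "ATPase8"),
                                "ATPase6/8", .data$name)) |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(first_start = min(.data$start), .groups = "drop")
  out$first_start <- gene_order$first_start[match(out$gene, gene_order$name)]
  out$first_start[is.na(out$first_start)] <- Inf  # combined/non-coding labels last
  out <- dplyr::arrange(out, .data$first_start, .data$gene)
  out$first_start <- NULL
  out
}
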