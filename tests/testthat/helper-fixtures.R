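# Small in-code fixtures shared across the suite.

# A minimal well-formed methylation-call tibble: one row per (read, site),
# singleton CpG groups with a 12-mer context carrying one CG.
make_calls <- function(llr, position = seq_along(llr) * 100L,
                       read_name = sprintf("read_%03d", seq_along(llr)),
                       strand = "+", chromosome = "chrM") {
  tibble::tibble(
    chromosome = chromosome,
    strand = rep_len(strand, length(llr)),
    start = as.integer(position),
    end = as.integer(position),
    read_name = rep_len(read_name, length(llr)),
    log_lik_ratio = llr,
    log_lik_methylated = llr / 2,
    log_lik_unmethylated = -llr / 2,
    num_calling_strands = 1L,
    num_motifs = 1L,
    sequence = "AAAAACGAAAAA"
  )
}

# A per-site table in the site_mf() layout (0-based positions).
make_sites <- function(position, mf, called_sites = 100L, chromosome = "chrM",
                       strand_stratum = "pooled") {
  n_meth <- as.integer(round(mf * called_sites))
  tibble::tibble(
    chromosome = chromosome,
    position = as.integer(position),
    strand_stratum = rep_len(strand_stratum, length(position)),
    pass_stratum = "combined",
    n_methylated = n_meth,
    n_unmethylated = as.integer(called_sites) - n_meth,
    n_ambiguous = 0L,
    called_sites = as.integer(rep_len(called_sites, length(position))),
    mf = mf
  )
}

# A per-read summary tibble.
make_reads <- function(aligned_length, mean_qscore = 10,
                       read_name = sprintf("read_%03d", seq_along(aligned_length)),
                       strand = "+") {
  tibble::tibble(
    read_name = read_name,
    mean_qscore = rep_len(mean_qscore, length(aligned_length)),
    aligned_target = "chrM",
    aligned_length = as.integer(aligned_length),
    strand = rep_len(strand, length(aligned_length))
  )
}

# Brute-force per-site recount oracle: classify every split record by the
# strict thresholds and count states per position, independent of site_mf().
brute_force_mf <- function(calls, llr_upper = 2, llr_lower = -2) {
  recs <- mtmeth::split_groups(calls)
  out <- list()
  for (p in sort(unique(recs$position))) {
    llr <- recs$log_lik_ratio[recs$position == p]
    n_m <- sum(llr > llr_upper)
    n_u <- sum(llr < llr_lower)
    out[[length(out) + 1]] <- data.frame(
      position = p, n_methylated = n_m, n_unmethylated = n_u,
      n_ambiguous = length(llr) - n_m - n_u,
      mf = if (n_m + n_u > 0) n_m / (n_m + n_u) else NA_real_
    )
  }
  do.call(rbind, out)
}

# Full-enumeration two-sided Mann-Whitney p oracle for small tie-free samples.
enumerate_mw_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  u_stat <- function(idx) {
    xx <- pooled[idx]
    yy <- pooled[-idx]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u_obs <- u_stat(seq_len(n1))
  all_u <- apply(utils::combn(length(pooled), n1), 2, u_stat)
  mu <- n1 * (length(pooled) - n1) / 2
  mean(abs(all_u - mu) >= abs(u_obs - mu) - 1e-9)
}
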