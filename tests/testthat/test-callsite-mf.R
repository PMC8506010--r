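test_that("calls are classified by strict LLR thresholds", {
  cfg <- mf_config()
  expect_equal(classify_calls(2.5, cfg), "methylated")
  expect_equal(classify_calls(-2.5, cfg), "unmethylated")
  # ties at the thresholds are ambiguous: the rule is a strict inequality
  expect_equal(classify_calls(c(2, -2, 0, 1.999, -1.999), cfg),
               rep("ambiguous", 5))
  expect_error(classify_calls(c(1, NA)), "finite")
  expect_error(classify_calls(Inf), "finite")
  expect_error(mf_config(llr_upper = -3, llr_lower = 3))
})

test_that("split_groups emits one record per CpG with the group LLR inherited", {
  g1 <- make_calls(3.5, position = 100L)
  out1 <- split_groups(g1)
  expect_equal(nrow(out1), 1)
  expect_equal(out1$position, 100L)

  # three CpGs at offsets 0, 6, 10 from start 200
  g3 <- tibble::tibble(
    chromosome = "chrM", strand = "+", start = 200L, end = 210L,
    read_name = "read_a", log_lik_ratio = 4.2,
    log_lik_methylated = 2.1, log_lik_unmethylated = -2.1,
    num_calling_strands = 1L, num_motifs = 3L,
    sequence = "AAAAACGTTTTCGTTCGAAAAA"
  )
  out3 <- split_groups(g3)
  expect_equal(nrow(out3), 3)
  expect_equal(out3$position, c(200L, 206L, 210L))
  expect_equal(unique(out3$log_lik_ratio), 4.2)
  expect_equal(unique(out3$read_name), "read_a")

  # explicit reference positions override the sequence-derived ones
  out_ref <- split_groups(g3, reference_cpg_positions = c(200L, 206L, 210L, 999L))
  expect_equal(out_ref$position, c(200L, 206L, 210L))
  # a span with the wrong CpG count is an error naming the record
  expect_error(split_groups(g3, reference_cpg_positions = c(200L, 210L)),
               "read_a")
  bad <- g3; bad$sequence <- "AAAAACGAAAAA"  # one CG, claims three
  expect_error(split_groups(bad), "inconsistent")
})

test_that("site MF is the methylated proportion of confident calls", {
  calls <- make_calls(c(5, 4, 3, -5), position = 500L,
                      read_name = sprintf("r%d", 1:4))
  st <- site_mf(calls)
  expect_equal(nrow(st), 1)
  expect_equal(st$mf, 0.75)  # 3 methylated / 4 called
  expect_equal(st$called_sites, 4L)

  # all-ambiguous sites carry no MF and are omitted
  amb <- make_calls(c(0.5, -1, 1.5), position = 600L,
                    read_name = sprintf("r%d", 1:3))
  expect_equal(nrow(site_mf(amb)), 0)
  expect_equal(nrow(site_mf(make_calls(numeric(0)))), 0)
})

test_that("site counts conserve records and are invariant to order and read relabeling", {
  set.seed(401)
  n <- 600
  calls <- make_calls(runif(n, -8, 8),
                      position = sample(c(100L, 200L, 300L, 400L), n, TRUE),
                      read_name = sprintf("r%04d", seq_len(n)))
  st <- site_mf(calls)
  expect_equal(sum(st$n_methylated + st$n_unmethylated + st$n_ambiguous), n)
  expect_true(all(st$mf >= 0 & st$mf <= 1))

  shuffled <- calls[sample.int(n), ]
  shuffled$read_name <- sprintf("relabeled_%04d", seq_len(n))
  expect_equal(as.data.frame(site_mf(shuffled)), as.data.frame(st))
})

test_that("site_mf matches a brute-force recount on random tables", {
  set.seed(402)
  for (rep in 1:3) {
    n <- sample(200:1000, 1)
    calls <- make_calls(runif(n, -6, 6),
                        position = sample(seq(100L, 1000L, by = 50L), n, TRUE),
                        read_name = sprintf("r%04d", seq_len(n)))
    oracle <- brute_force_mf(calls)
    oracle <- oracle[oracle$n_methylated + oracle$n_unmethylated > 0, ]
    st <- site_mf(calls)
    expect_equal(st$position, oracle$position)
    expect_equal(st$n_methylated, oracle$n_methylated)
    expect_equal(st$n_unmethylated, oracle$n_unmethylated)
    expect_equal(st$n_ambiguous, oracle$n_ambiguous)
    expect_equal(st$mf, oracle$mf)
  }
})

test_that("pooled strand counts are exactly the sum of plus and minus counts", {
  set.seed(403)
  n <- 500
  calls <- make_calls(runif(n, -6, 6),
                      position = sample(c(100L, 200L, 300L), n, TRUE),
                      read_name = sprintf("r%04d", seq_len(n)),
                      strand = sample(c("+", "-"), n, TRUE))
  pooled <- site_mf(calls)
  both <- site_mf(calls, strand = "both")
  sums <- both |>
    dplyr::group_by(position) |>
    dplyr::summarise(n_methylated = sum(n_methylated),
                     n_unmethylated = sum(n_unmethylated),
                     n_ambiguous = sum(n_ambiguous), .groups = "drop")
  expect_equal(pooled$n_methylated, sums$n_methylated)
  expect_equal(pooled$n_unmethylated, sums$n_unmethylated)
  expect_equal(pooled$n_ambiguous, sums$n_ambiguous)
  # hence pooled MF is the coverage-weighted mean of the strand MFs
  w <- both |>
    dplyr::group_by(position) |>
    dplyr::summarise(mf = sum(mf * called_sites) / sum(called_sites), .groups = "drop")
  expect_equal(pooled$mf, w$mf)
})

test_that("pass/fail stratified MF requires a read summary and recovers the combined counts", {
  set.seed(404)
  n <- 300
  reads <- make_reads(rep(2000L, 40), mean_qscore = c(rep(9, 20), rep(5, 20)),
                      read_name = sprintf("r%03d", 1:40))
  calls <- make_calls(runif(n, -6, 6), position = sample(c(10L, 20L), n, TRUE),
                      read_name = sample(reads$read_name, n, TRUE))
  expect_error(site_mf(calls, stratum = "pass_only"), "read summary")
  both <- site_mf(calls, reads = reads, stratum = "both")
  combined <- site_mf(calls)
  sums <- both |>
    dplyr::group_by(position) |>
    dplyr::summarise(n_methylated = sum(n_methylated),
                     n_unmethylated = sum(n_unmethylated), .groups = "drop")
  expect_equal(combined$n_methylated, sums$n_methylated)
  expect_equal(combined$n_unmethylated, sums$n_unmethylated)

  orphan <- calls
  orphan$read_name[1] <- "unknown_read"
  expect_warning(site_mf(orphan, reads = reads, stratum = "pass_only"), "absent")
  expect_error(site_mf(orphan, reads = reads, stratum = "pass_only",
                       missing_reads = "error"), "absent")
})

test_that("per_sample_summary reports mean, SD, and degenerate cases", {
  st <- make_sites(c(0L, 10L, 20L, 30L), mf = c(0, 0, 1, 1))
  s <- per_sample_summary(st)
  expect_equal(s$mean_mf, 0.5)
  expect_equal(s$n_sites, 4L)
  expect_equal(s$mean_coverage, 100)

  single <- make_sites(0L, mf = 0.3)
  expect_true(is.na(per_sample_summary(single)$sd_mf))
  expect_error(per_sample_summary(make_sites(integer(0), numeric(0))), "empty")
})

test_that("a noiseless high-coverage generator sample recovers its uniform truth", {
  m <- 0.1
  s <- simulate_sample(sim_config(contig_length = 2000L,
                                  cpg_positions = seq(100L, 1900L, by = 100L),
                                  truth = m, coverage = 400,
                                  read_length_mean = 600, read_length_sdlog = 0,
                                  llr_sd = 1, seed = 405))
  st <- site_mf(s$calls)
  mc_se <- sqrt(m * (1 - m) / mean(st$called_sites)) / sqrt(nrow(st))
  expect_lt(abs(per_sample_summary(st)$mean_mf - m), 3 * mc_se)
})
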