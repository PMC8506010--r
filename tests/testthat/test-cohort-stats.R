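test_that("Mann-Whitney matches the textbook exact case and handles identical groups", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)  # 2/20 orderings are as extreme
  expect_equal(c(r$n1, r$n2), c(3L, 3L))

  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1), "at least one")
})

test_that("exact Mann-Whitney p equals full enumeration for n1+n2 <= 12", {
  set.seed(701)
  for (i in 1:20) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    x <- runif(n1); y <- runif(n2) + runif(1, -0.5, 0.5)
    r <- mann_whitney(x, y)
    expect_equal(r$p_value, enumerate_mw_p(x, y), tolerance = 1e-12,
                 info = sprintf("case %d (n1=%d, n2=%d)", i, n1, n2))
  }
})

test_that("Spearman hits the monotone extremes and equals Pearson on midranks", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(spearman_cor(x, x^2)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)

  set.seed(702)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    x <- sample(1:8, n, TRUE) + runif(n) * (i %% 2)  # ties half the time
    y <- sample(1:8, n, TRUE) + runif(n) * (i %% 2)
    got <- spearman_cor(x, y)$rho
    oracle <- stats::cor(rank(x), rank(y))  # Pearson on midranks
    expect_equal(got, oracle, tolerance = 1e-12)
  }
  expect_warning(r0 <- spearman_cor(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r0$rho) && r0$constant_input)
  expect_error(spearman_cor(1:2, 2:1), "at least 3")
})

test_that("small exact Spearman p matches brute-force permutation", {
  x <- c(3, 1, 4, 2, 5)
  y <- c(2, 1, 5, 3, 4)
  got <- spearman_cor(x, y)
  # enumerate all 120 permutations of y directly
  perm_idx <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perm_idx <- perm_idx[apply(perm_idx, 1, function(r) length(unique(r)) == 5), ]
  rho_obs <- cor(rank(x), rank(y))
  rhos <- apply(perm_idx, 1, function(p) cor(rank(x), rank(y[p])))
  expect_equal(got$p_value, mean(abs(rhos) >= abs(rho_obs) - 1e-12))
})

test_that("compare_groups reports both pooling units and validates its inputs", {
  set.seed(703)
  tabs <- list(
    s1 = make_sites(1:50 * 10L, mf = runif(50, 0, 0.1)),
    s2 = make_sites(1:50 * 10L, mf = runif(50, 0, 0.1)),
    s3 = make_sites(1:50 * 10L, mf = runif(50, 0, 0.1)),
    s4 = make_sites(1:50 * 10L, mf = runif(50, 0, 0.1))
  )
  sheet <- tibble::tibble(sample_id = c("s1", "s2", "s3", "s4"),
                          group = c("case", "case", "control", "control"))
  cmp <- compare_groups(tabs, sheet)
  expect_s3_class(cmp, "cohort_comparison")
  expect_equal(cmp$site_pooled$n1, 100L)       # site pooling concatenates samples
  expect_equal(cmp$per_sample_mean$n1, 2L)     # one mean per sample
  # identical cohorts are not significant
  same <- compare_groups(tabs[c(1, 1, 2, 2)] |>
                           stats::setNames(c("a1", "a2", "b1", "b2")),
                         tibble::tibble(sample_id = c("a1", "a2", "b1", "b2"),
                                        group = c("case", "case", "control", "control")))
  expect_gt(same$site_pooled$p_value, 0.05)

  expect_error(compare_groups(tabs, sheet[c(1, 1, 2, 3), ]), "exactly one group")
  expect_error(compare_groups(tabs[1:3], sheet), "no site table")
  expect_error(compare_groups(tabs, dplyr::mutate(sheet, group = "case")),
               "exactly two groups")
})

test_that("a shifted cohort is detected by the site-pooled comparison", {
  # effect at the blood-arm scale: truth 0.027 vs 0.034 at 250X over 300 sites
  P <- seq(30L, 3590L, by = 12L)
  base <- function(truth, seed) sim_config(
    contig_length = 3600L, cpg_positions = P, truth = truth, coverage = 250,
    read_length_mean = 1200, read_length_sdlog = 0.3, llr_sd = 1, seed = seed)
  n_rep <- 30
  hits <- 0
  for (r in seq_len(n_rep)) {
    co <- simulate_cohort(base(0.027, 7000 + r), base(0.034, 7000 + r),
                          n_case = 4, n_control = 3, base_seed = 7000 + 97 * r)
    tabs <- lapply(co$samples, function(s) site_mf(s$calls))
    cmp <- compare_groups(tabs, co$sheet)
    hits <- hits + (cmp$site_pooled$p_value < 0.05)
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("strand concordance pairs shared sites and needs both strands", {
  set.seed(704)
  pos <- 1:40 * 10L
  mfp <- runif(40, 0, 0.3)
  tab <- dplyr::bind_rows(
    make_sites(pos, mfp, strand_stratum = "plus"),
    make_sites(pos, pmin(1, mfp + rnorm(40, 0, 0.02)), strand_stratum = "minus")
  )
  res <- strand_concordance(tab)
  expect_equal(res$n_pairs, 40L)
  expect_gt(res$correlation$rho, 0.5)
  expect_lt(abs(res$mean_difference), 0.02)

  ident <- dplyr::bind_rows(make_sites(pos, mfp, strand_stratum = "plus"),
                            make_sites(pos, mfp, strand_stratum = "minus"))
  expect_equal(strand_concordance(ident)$correlation$rho, 1)
  expect_error(strand_concordance(make_sites(pos, mfp, strand_stratum = "plus")),
               "both plus- and minus")
})

test_that("symmetric strand truth yields positive concordance and near-zero strand difference", {
  s <- simulate_sample(sim_config(contig_length = 4000L,
                                  cpg_positions = seq(40L, 3960L, by = 16L),
                                  truth = runif(246, 0.02, 0.3), coverage = 300,
                                  read_length_mean = 1200, llr_sd = 1, seed = 705))
  tab <- site_mf(s$calls, strand = "both")
  res <- strand_concordance(tab)
  expect_gt(res$correlation$rho, 0)
  expect_lt(abs(res$mean_difference), 0.01)
})

test_that("caller concordance separates site-level from sample-level agreement", {
  pos <- 1:30 * 10L
  mfs <- seq(0.01, 0.30, length.out = 30)
  a <- dplyr::bind_rows(lapply(1:4, function(i)
    dplyr::mutate(make_sites(pos, pmin(1, mfs + i / 100)), sample_id = paste0("s", i))))
  expect_equal(tool_concordance(a, a)$per_site$rho, 1)
  expect_equal(tool_concordance(a, a)$per_sample$rho, 1)

  # independent per-site noise around common per-sample means
  set.seed(706)
  shift <- c(0, 0.05, 0.1, 0.15)
  noisy <- function() dplyr::bind_rows(lapply(1:4, function(i)
    dplyr::mutate(make_sites(pos, pmin(1, pmax(0, shift[i] + runif(30, 0, 0.1)))),
                  sample_id = paste0("s", i))))
  res <- tool_concordance(noisy(), noisy())
  expect_lt(res$per_site$rho, res$per_sample$rho)

  # a single shared position is flagged as underpowered, disjoint is an error
  one <- make_sites(10L, 0.1)
  r1 <- tool_concordance(one, one)
  expect_true(is.na(r1$per_site$rho))
  expect_match(r1$per_site$method, "underpowered")
  expect_error(tool_concordance(make_sites(10L, 0.1), make_sites(20L, 0.1)),
               "share no")
})
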