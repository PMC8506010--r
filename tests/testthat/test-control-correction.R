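test_that("FPR is the methylated fraction of confidently-called control cytosines", {
  clean <- make_calls(rep(-5, 1000), position = rep(seq(0L, 99L) * 10L, 10),
                      read_name = rep(sprintf("r%03d", 1:10), each = 100))
  pr <- estimate_fpr(clean)
  expect_s3_class(pr, "control_profile")
  expect_equal(pr$fpr, 0)
  expect_equal(pr$n_calls_total, 1000L)

  allm <- make_calls(rep(5, 10), read_name = sprintf("r%d", 1:10))
  expect_warning(pr1 <- estimate_fpr(allm), "degenerate")
  expect_equal(pr1$fpr, 1)

  # ambiguous calls count in neither numerator nor denominator
  mixed <- make_calls(c(5, -5, 0, 1, -1), read_name = sprintf("r%d", 1:5))
  expect_equal(estimate_fpr(mixed)$fpr, 0.5)
  amb <- make_calls(c(0, 1, -1))
  expect_error(estimate_fpr(amb), "no confidently-called")
})

test_that("FPR estimate recovers the simulated per-call false-methylation rate", {
  p <- 0.03
  ctl <- simulate_control(sim_config(contig_length = 4000L,
                                     cpg_positions = seq(50L, 3950L, by = 20L),
                                     coverage = 130, read_length_mean = 1000,
                                     llr_sd = 1, seed = 501),
                          fpr_call = p)
  pr <- estimate_fpr(ctl$calls)
  n <- pr$n_calls_total
  expect_gt(n, 20000)
  expect_lt(abs(pr$fpr - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("FPR is invariant to record order and pooling amplicons equals concatenation", {
  set.seed(502)
  a <- make_calls(runif(400, -8, 8), position = sample(seq(0L, 990L, 10L), 400, TRUE),
                  read_name = sprintf("r%03d", 1:400))
  b <- make_calls(runif(300, -8, 8), position = sample(seq(0L, 990L, 10L), 300, TRUE),
                  read_name = sprintf("s%03d", 1:300))
  pooled_list <- estimate_fpr(list(a, b))
  concat <- estimate_fpr(dplyr::bind_rows(a, b))
  expect_equal(pooled_list$fpr, concat$fpr)
  expect_equal(pooled_list$n_calls_total, concat$n_calls_total)
  shuffled <- estimate_fpr(dplyr::bind_rows(b, a)[sample.int(700), ])
  expect_equal(shuffled$fpr, concat$fpr)
})

test_that("FPR subtraction is monotone, clamped at zero, and the identity at FPR 0", {
  st <- make_sites(c(0L, 10L, 20L), mf = c(0.057, 0.010, 0.50))
  adj <- adjust_mf(st, 0.029)
  expect_equal(adj$mf_adjusted, c(0.028, 0, 0.471))
  expect_equal(order(adj$mf), order(adj$mf_adjusted))
  noclamp <- adjust_mf(st, 0.029, clamp_at_zero = FALSE)
  expect_equal(noclamp$mf_adjusted[2], -0.019)
  expect_equal(adjust_mf(st, 0)$mf_adjusted, st$mf)
})

test_that("sites with control MF above the strict 0.2 threshold are excluded", {
  # control grid 0.00-1.00 step 0.01: the largest retained control MF is 0.20
  grid <- seq(0, 1, by = 0.01)
  control_calls <- make_calls(
    llr = as.vector(vapply(grid, function(p) {
      c(rep(5, round(p * 100)), rep(-5, 100 - round(p * 100)))
    }, numeric(100))),
    position = rep(seq_along(grid) * 10L, each = 100),
    read_name = rep(sprintf("r%03d", 1:100), times = length(grid))
  )
  profile <- estimate_fpr(control_calls)
  sample_sites <- make_sites(seq_along(grid) * 10L, mf = rep(0.1, length(grid)))
  res <- exclude_sites(sample_sites, profile)
  retained_control_mf <- profile$per_site$mf[profile$per_site$position %in%
                                               res$retained$position]
  expect_equal(max(retained_control_mf), 0.20)
  expect_equal(nrow(res$retained), sum(grid <= 0.2 + 1e-12))
  expect_true(all(res$excluded$control_mf > 0.2))
})

test_that("positions absent from the control are retained and an empty control warns", {
  ctl_calls <- make_calls(c(rep(5, 30), rep(-5, 70)), position = 10L,
                          read_name = sprintf("r%03d", 1:100))
  profile <- estimate_fpr(ctl_calls)  # control covers position 10 only
  st <- make_sites(c(10L, 20L), mf = c(0.1, 0.9))
  res <- suppressMessages(exclude_sites(st, profile))
  expect_equal(res$not_in_control, 20L)
  expect_true(20L %in% res$retained$position)

  empty_profile <- profile
  empty_profile$per_site <- profile$per_site[0, ]
  expect_warning(res2 <- exclude_sites(st, empty_profile), "empty control")
  expect_equal(nrow(res2$retained), 2)
})

test_that("adjustment and exclusion commute", {
  set.seed(503)
  ctl_calls <- make_calls(runif(2000, -8, 8),
                          position = sample(seq(0L, 490L, 10L), 2000, TRUE),
                          read_name = sprintf("r%04d", 1:2000))
  profile <- estimate_fpr(ctl_calls)
  st <- make_sites(seq(0L, 490L, 10L), mf = runif(50))
  a <- exclude_sites(adjust_mf(st, profile), profile)$retained
  b <- adjust_mf(exclude_sites(st, profile)$retained, profile)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("max-combining over overlapping amplicons excludes sites the pooled rule keeps", {
  # amplicon A clean at the site, amplicon B heavily miscalled there
  a <- make_calls(rep(-5, 300), position = 10L, read_name = sprintf("a%03d", 1:300))
  b <- make_calls(c(rep(5, 30), rep(-5, 70)), position = 10L,
                  read_name = sprintf("b%03d", 1:100))
  profile <- estimate_fpr(list(a, b))
  st <- make_sites(10L, mf = 0.5)
  expect_equal(nrow(exclude_sites(st, profile, combine = "pooled")$retained), 1)
  expect_equal(nrow(exclude_sites(st, profile, combine = "max")$retained), 0)
})

test_that("adjusted MF is unbiased for the truth at blood-scale coverage", {
  # known truth and a control-estimated FPR; clamping disabled so the
  # diagnostic sees the signed error
  m <- 0.03
  base <- sim_config(contig_length = 3600L, cpg_positions = seq(30L, 3590L, by = 12L),
                     truth = m, coverage = 250, read_length_mean = 1200,
                     read_length_sdlog = 0.3, llr_sd = 1, fpr_call = 0.03,
                     seed = 504)
  ctl <- simulate_control(base, coverage_multiplier = 4, fpr_call = 0.03)
  profile <- estimate_fpr(ctl$calls)
  samp <- simulate_sample(base)
  st <- adjust_mf(site_mf(samp$calls), profile, clamp_at_zero = FALSE)
  err <- st$mf_adjusted - m
  mc_se <- stats::sd(err) / sqrt(length(err))
  expect_gt(length(err), 290)
  expect_lt(abs(mean(err)), 3 * mc_se + m * profile$fpr)  # residual -m*fpr interaction
})
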