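test_that("chi-squared departure equals the 1-df closed form", {
  null_fit <- chi_squared_departure(50, 50, 0.5)
  expect_equal(null_fit$chi2, 0)
  expect_equal(null_fit$p_value, 1)

  skew <- chi_squared_departure(75, 25, 0.5)
  expect_equal(skew$chi2, 25)
  expect_equal(skew$p_value, 5.733031e-07, tolerance = 1e-6)

  triploid <- chi_squared_departure(10, 20, 2 / 3)
  expect_equal(triploid$chi2, 15)
  expect_equal(triploid$p_value, 1.075112e-04, tolerance = 1e-6)

  expect_error(chi_squared_departure(0, 0), "M \\+ P > 0")

  # cross-check against the stock goodness-of-fit test on random inputs
  withr::with_seed(5, {
    for (i in 1:25) {
      M <- rpois(1, 80) + 1
      P <- rpois(1, 60) + 1
      t0 <- runif(1, 0.2, 0.8)
      got <- chi_squared_departure(M, P, t0)
      ref <- suppressWarnings(stats::chisq.test(c(M, P), p = c(t0, 1 - t0)))
      expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
      expect_equal(got$chi2, chi2_closed_form(M, P, t0), tolerance = 1e-12)
    }
  })
})

test_that("BH adjustment equals the literal step-up procedure", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_equal(benjamini_hochberg(rep(0.04, 10)), rep(0.04, 10))
  expect_equal(benjamini_hochberg(numeric(0)), numeric(0))
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(benjamini_hochberg(c(0.1, -0.01)), "\\[0, 1\\]")

  withr::with_seed(99, {
    for (i in 1:40) {
      m <- sample(c(1:50, 200, 1000), 1)
      p <- runif(m)
      if (i %% 3 == 0) p <- round(p, 1)  # force ties
      q <- benjamini_hochberg(p)
      expect_equal(q, bh_step_up_oracle(p), tolerance = 1e-12)
      expect_true(all(q >= 0 & q <= 1))
      expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p
    }
  })
})

test_that("status calls require both directions, nest strong in moderate, and gate on q", {
  cfg <- caller_config()
  expect_equal(call_status(0.95, 0.92, 1e-6, cfg), "MEG_strong")
  expect_equal(call_status(0.80, 0.78, 1e-6, cfg), "MEG_moderate")
  expect_equal(call_status(0.80, 0.70, 1e-4, cfg), "biparental")  # one direction fails
  expect_equal(call_status(0.05, 0.08, 1e-9, cfg), "PEG_strong")
  expect_equal(call_status(0.20, 0.12, 1e-9, cfg), "PEG_moderate")
  expect_equal(call_status(0.75, 0.95, 1e-9, cfg), "biparental")  # strict > 0.75
  expect_equal(call_status(0.95, 0.95, 0.2, cfg), "biparental")   # not significant
  expect_equal(call_status(NA, 0.95, 1e-9, cfg), "undetermined")

  lax <- caller_config(require_significance = FALSE)
  expect_equal(call_status(0.95, 0.95, 0.2, lax), "MEG_strong")

  expect_error(caller_config(meg_moderate = 0.95, meg_strong = 0.9), "thresholds")
  expect_error(caller_config(null_maternal_proportion = 0.8), "thresholds")
})

test_that("mirroring theta about 0.5 swaps MEG and PEG calls", {
  withr::with_seed(31, {
    t1 <- runif(500)
    t2 <- pmin(1, pmax(0, t1 + rnorm(500, 0, 0.1)))
    q <- runif(500, 0, 0.1)
  })
  cfg <- caller_config()
  calls <- call_status(t1, t2, q, cfg)
  mirrored <- call_status(1 - t1, 1 - t2, q, cfg)
  map <- c(MEG_strong = "PEG_strong", MEG_moderate = "PEG_moderate",
           PEG_strong = "MEG_strong", PEG_moderate = "MEG_moderate",
           biparental = "biparental", undetermined = "undetermined")
  expect_equal(mirrored, unname(map[calls]))
})

test_that("imprintome calling pools directions, adjusts over tested genes, and flags one-sided genes", {
  design <- tiny_design()
  dirs <- design$direction_id
  gase <- tibble::tibble(
    gene_id = rep(c("gMEG", "gNULL", "gONE"), each = 2),
    direction_id = rep(dirs, 3),
    M = c(950, 920, 500, 510, 700, 1),
    P = c(50, 80, 500, 490, 300, 1),
    n_sites = 3L) |>
    dplyr::mutate(n_reads = M + P, estimable = n_reads >= 10,
                  theta = ifelse(estimable, M / n_reads, NA_real_))
  imp <- call_imprinting(gase, directions = dirs)
  imp_by <- split(imp, imp$gene_id)

  expect_equal(imp_by$gMEG$M_pooled, 950 + 920)
  expect_equal(imp_by$gMEG$chi2,
               chi2_closed_form(1870, 130), tolerance = 1e-12)
  expect_equal(imp_by$gMEG$status, "MEG_strong")
  expect_equal(imp_by$gNULL$status, "biparental")
  # q-values adjusted over the two genes tested (gONE is estimable in one
  # direction only and excluded from testing)
  expect_equal(sort(imp$q_value[!is.na(imp$q_value)]),
               sort(bh_step_up_oracle(imp$p_value[!is.na(imp$p_value)])),
               tolerance = 1e-12)
  expect_equal(imp_by$gONE$status, "undetermined")
  expect_equal(imp_by$gONE$theta_dir1, 0.7)
  expect_true(is.na(imp_by$gONE$theta_dir2))

  expect_error(call_imprinting(gase[gase$direction_id == dirs[1], ]),
               "exactly two")
})

test_that("imprintome summaries add strong and moderate members into class totals", {
  imp <- tibble::tibble(
    gene_id = paste0("g", 1:8),
    theta_dir1 = c(0.95, 0.92, 0.85, 0.80, 0.05, 0.5, 0.5, NA),
    theta_dir2 = c(0.96, 0.91, 0.82, 0.78, 0.03, 0.5, 0.5, NA),
    M_pooled = 1, P_pooled = 1, chi2 = 1, p_value = 0.5, q_value = 0.5,
    status = c("MEG_strong", "MEG_strong", "MEG_strong", "MEG_moderate",
               "PEG_strong", "biparental", "biparental", "undetermined"))
  s <- summarize_imprintome(imp)
  expect_equal(s$meg_total, 4)
  expect_equal(s$peg_total, 1)
  expect_equal(s$imprinted_total, 5)
  expect_equal(s$n_assayable, 7)
  expect_equal(s$status_counts[["PEG_moderate"]], 0)
  expect_equal(s$mean_theta_dir1, mean(imp$theta_dir1[1:7]))

  empty <- summarize_imprintome(imp[0, ])
  expect_equal(empty$imprinted_total, 0)
  expect_equal(unname(empty$status_counts), rep(0L, 6))
})

test_that("a well-powered null simulation yields essentially no imprinted calls", {
  cfg <- sim_config(n_genes = 300, frac_meg = 0, frac_peg = 0,
                    overdispersion = 0, depth_mean = 100, seed = 77)
  for (s in c(77, 78)) {
    cfg$seed <- s
    sim <- simulate_imprintome_data(cfg)
    merged <- merge_replicate_counts(sim$counts, sim$design)
    gase <- gene_maternal_proportion(
      site_parental_counts(merged, sim$sites, sim$design))
    imp <- call_imprinting(gase, directions = cfg$direction_ids)
    n_imprinted <- sum(imp$status %in% c("MEG_strong", "MEG_moderate",
                                         "PEG_strong", "PEG_moderate"))
    expect_lte(n_imprinted, 1)
  }
})
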