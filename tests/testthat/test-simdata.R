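test_that("ground truth plants exact class counts, deterministically per seed", {
  cfg <- sim_config(n_genes = 200, frac_meg = 0.05, frac_peg = 0.05, seed = 4)
  truth <- simulate_truth(cfg)
  expect_equal(sum(truth$true_status == "MEG"), 10)
  expect_equal(sum(truth$true_status == "PEG"), 10)
  expect_equal(truth$true_theta[truth$true_status == "MEG"][1], 0.95)
  expect_equal(simulate_truth(cfg), truth)
  expect_false(identical(simulate_truth(sim_config(n_genes = 200, seed = 5)),
                         truth))

  none <- simulate_truth(sim_config(n_genes = 50, frac_meg = 0, frac_peg = 0.1,
                                    seed = 4))
  expect_equal(sum(none$true_status == "MEG"), 0)
  expect_equal(sum(none$true_status == "PEG"), 5)
  expect_error(sim_config(frac_meg = 0.7, frac_peg = 0.4))
})

test_that("simulated genotypes are consistent with their drawn categories", {
  cfg <- sim_config(n_genes = 60, seed = 21)
  parents <- simulate_parental_sites(cfg)
  sites <- parents$sites
  expect_equal(classify_site(sites$gt_P1, sites$gt_P2), sites$category_dir1)
  expect_equal(classify_site(sites$gt_P2, sites$gt_P1), sites$category_dir2)
  # annotation intervals contain their genes' sites
  j <- dplyr::inner_join(sites, parents$annotation,
                         by = c("chrom", "gene_id"))
  expect_true(all(j$pos >= j$start & j$pos <= j$end))
  # uninformative sites never reach the transformation
  sim <- simulate_imprintome_data(cfg)
  merged <- merge_replicate_counts(sim$counts, sim$design)
  ase <- site_parental_counts(merged, sim$sites, sim$design)
  expect_false(any(ase$category == "uninformative"))
})

test_that("deep simulated counts recover the planted maternal proportion", {
  # reciprocal-homozygous sites only: theta-hat is the plain binomial MLE
  cfg <- sim_config(n_genes = 30, frac_meg = 0, frac_peg = 0,
                    category_mix = c(reciprocal_hom = 1, mother_het = 0,
                                     father_het = 0, uninformative = 0),
                    depth_mean = 3333, overdispersion = 0, seed = 8)
  sim <- simulate_imprintome_data(cfg)
  merged <- merge_replicate_counts(sim$counts, sim$design)
  gase <- gene_maternal_proportion(
    site_parental_counts(merged, sim$sites, sim$design))
  expect_true(all(abs(gase$theta - 0.5) < 0.02))
  expect_lt(abs(mean(gase$theta) - 0.5), 0.005)

  # mixed categories: heterozygous sites double the sampling noise but not
  # the expectation
  cfg_mix <- sim_config(n_genes = 30, frac_meg = 0, frac_peg = 0,
                        depth_mean = 3333, overdispersion = 0, seed = 9)
  sim <- simulate_imprintome_data(cfg_mix)
  merged <- merge_replicate_counts(sim$counts, sim$design)
  gase <- gene_maternal_proportion(
    site_parental_counts(merged, sim$sites, sim$design))
  expect_true(all(abs(gase$theta - 0.5) < 0.04))
  expect_lt(abs(mean(gase$theta) - 0.5), 0.005)
})

test_that("maternal sporophytic contamination inflates theta as (1-rho_c)*theta + rho_c", {
  cfg <- sim_config(n_genes = 40, frac_meg = 0, frac_peg = 0,
                    depth_mean = 1000, overdispersion = 0,
                    contamination = 0.2, seed = 15)
  sim <- simulate_imprintome_data(cfg)
  merged <- merge_replicate_counts(sim$counts, sim$design)
  gase <- gene_maternal_proportion(
    site_parental_counts(merged, sim$sites, sim$design))
  expect_equal(mean(gase$theta), 0.8 * 0.5 + 0.2, tolerance = 0.01)

  # the documented diagnostic signature: at rho_c = 0.3 the null mean
  # maternal proportion exceeds 0.6
  cfg$contamination <- 0.3
  sim <- simulate_imprintome_data(cfg)
  merged <- merge_replicate_counts(sim$counts, sim$design)
  gase <- gene_maternal_proportion(
    site_parental_counts(merged, sim$sites, sim$design))
  expect_gt(mean(gase$theta), 0.6)
})

test_that("mother-specific allele frequency at heterozygous sites is theta/2", {
  cfg <- sim_config(n_genes = 40, frac_meg = 0, frac_peg = 0,
                    category_mix = c(reciprocal_hom = 0, mother_het = 1,
                                     father_het = 0, uninformative = 0),
                    depth_mean = 2000, overdispersion = 0, seed = 23)
  sim <- simulate_imprintome_data(cfg)
  merged <- merge_replicate_counts(sim$counts, sim$design)
  dir1 <- merged[merged$direction_id == cfg$direction_ids[1], ]
  j <- dplyr::inner_join(dir1, sim$sites, by = c("chrom", "pos"))
  # mother P1 is 0/1; the mother-specific allele is whichever the father lacks
  spec_count <- ifelse(j$gt_P2 == "0/0", j$count_alt, j$count_ref)
  expect_equal(mean(spec_count / j$total),
               transmission_freq_oracle(0.5), tolerance = 0.005)
})

test_that("fixtures are byte-stable per seed and round-trip through the parsers", {
  cfg <- sim_config(n_genes = 15, seed = 33)
  sim <- simulate_imprintome_data(cfg)
  d1 <- file.path(tempfile(), "a")
  d2 <- file.path(tempfile(), "b")
  p1 <- write_fixtures(sim, d1)
  p2 <- write_fixtures(sim, d2)
  for (f in names(p1)) {
    expect_identical(unname(tools::md5sum(p1[[f]])),
                     unname(tools::md5sum(p2[[f]])), label = f)
  }
  other <- write_fixtures(
    simulate_imprintome_data(sim_config(n_genes = 15, seed = 34)),
    file.path(tempfile(), "c"))
  expect_false(identical(unname(tools::md5sum(p1[["counts"]])),
                         unname(tools::md5sum(other[["counts"]]))))

  reparsed <- parse_parental_genotypes(p1[["variants"]], "P1", "P2",
                                       filter_config(min_minor_allele_count = 1))
  reparsed <- assign_sites_to_genes(reparsed, read_gene_annotation(p1[["annotation"]]))
  cols <- c("chrom", "pos", "ref", "alt", "qual", "gt_P1", "gt_P2",
            "pass", "category_dir1", "category_dir2", "gene_id")
  expect_equal(as.data.frame(reparsed[cols]), as.data.frame(sim$sites[cols]),
               ignore_attr = TRUE)
  expect_equal(reparsed$depth, as.numeric(as.integer(sim$sites$depth)))

  design <- read_design(p1[["design"]])
  expect_equal(as.data.frame(design), as.data.frame(sim$design))
  counts <- extract_allele_depths(p1[["counts"]], reparsed)
  expect_equal(sum(counts$count_alt), sum(sim$counts$count_alt))
})
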