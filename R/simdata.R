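# Seeded generator of synthetic parental genotypes, reciprocal-cross
# endosperm allele counts and ground truth, so every pipeline stage can be
# validated without external sequencing data.

#' Simulation configuration
#'
#' Describes a reciprocal cross of two polymorphic diploid parents with a
#' diploid (1 maternal : 1 paternal) endosperm read out by several replicate
#' RNA libraries per direction. Per-gene informative-site counts follow a
#' negative binomial, per-site per-library sequencing depth follows a
#' negative binomial, and discriminant-allele counts follow a beta-binomial
#' with intraclass correlation `overdispersion` (0 degenerates to binomial).
#' `contamination` is the fraction of reads drawn from the maternal
#' sporophytic genotype (e.g. perisperm/seed-coat carry-over in endosperm
#' dissections); such reads carry the mother's alleles, so at a
#' mother-heterozygous site they contribute the mother-specific allele at
#' rate `contamination / 2`.
#'
#' @param n_genes Number of genes. Default 1000.
#' @param frac_meg,frac_peg Fractions of genes planted as MEGs / PEGs
#'   (defaults 0.05 each); planted counts are exact: `round(frac * n_genes)`.
#' @param theta_meg,theta_peg,theta_null True maternal expression
#'   proportions of planted MEGs, PEGs and null genes. Defaults 0.95, 0.05,
#'   0.5 (diploid endosperm).
#' @param sites_per_gene_mean,sites_per_gene_dispersion Negative-binomial
#'   mean and size of informative-SNP counts per gene. Defaults 5, 8.
#' @param category_mix Named probabilities over site categories
#'   `reciprocal_hom`, `mother_het`, `father_het`, `uninformative`
#'   (heterozygous categories named for direction 1, where `plant_ids[1]`
#'   is the mother). Default c(0.40, 0.225, 0.225, 0.15).
#' @param depth_mean,depth_dispersion Negative-binomial mean and size of
#'   per-site per-library read depth. Defaults 50, 10.
#' @param overdispersion Beta-binomial intraclass correlation rho in
#'   \[0, 1). Default 0.01.
#' @param contamination Maternal sporophytic contamination fraction rho_c in
#'   \[0, 1). Default 0.
#' @param n_replicates Replicate libraries per cross direction. Default 3.
#' @param plant_ids Length-2 parent identifiers. Default `c("P1", "P2")`.
#' @param seed Integer seed driving all randomness. Default 1.
#' @return A `sim_config` list, with `direction_ids` derived as
#'   `"<mother>x<father>"`.
#' @export
sim_config <- function(n_genes = 1000, frac_meg = 0.05, frac_peg = 0.05,
                       theta_meg = 0.95, theta_peg = 0.05, theta_null = 0.5,
                       sites_per_gene_mean = 5, sites_per_gene_dispersion = 8,
                       category_mix = c(reciprocal_hom = 0.40,
                                        mother_het = 0.225,
                                        father_het = 0.225,
                                        uninformative = 0.15),
                       depth_mean = 50, depth_dispersion = 10,
                       overdispersion = 0.01, contamination = 0,
                       n_replicates = 3, plant_ids = c("P1", "P2"),
                       seed = 1L) {
  stopifnot(n_genes >= 1, frac_meg >= 0, frac_peg >= 0,
            frac_meg + frac_peg <= 1,
            theta_meg >= 0, theta_meg <= 1, theta_peg >= 0, theta_peg <= 1,
            theta_null > 0, theta_null < 1,
            sites_per_gene_mean > 0, sites_per_gene_dispersion > 0,
            depth_mean > 0, depth_dispersion > 0,
            overdispersion >= 0, overdispersion < 1,
            contamination >= 0, contamination < 1,
            n_replicates >= 1, length(plant_ids) == 2,
            plant_ids[1] != plant_ids[2],
            abs(seed) < 2^31 - 3)
  if (!setequal(names(category_mix), SITE_CATEGORIES)) {
    stop("category_mix must be named over: ", paste(SITE_CATEGORIES, collapse = ", "))
  }
  category_mix <- category_mix[SITE_CATEGORIES]
  if (any(category_mix < 0) || abs(sum(category_mix) - 1) > 1e-8) {
    stop("category_mix must be non-negative probabilities summing to 1")
  }
  structure(list(n_genes = n_genes, frac_meg = frac_meg, frac_peg = frac_peg,
                 theta_meg = theta_meg, theta_peg = theta_peg,
                 theta_null = theta_null,
                 sites_per_gene_mean = sites_per_gene_mean,
                 sites_per_gene_dispersion = sites_per_gene_dispersion,
                 category_mix = category_mix,
                 depth_mean = depth_mean, depth_dispersion = depth_dispersion,
                 overdispersion = overdispersion, contamination = contamination,
                 n_replicates = n_replicates, plant_ids = plant_ids,
                 direction_ids = c(paste0(plant_ids[1], "x", plant_ids[2]),
                                   paste0(plant_ids[2], "x", plant_ids[1])),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate the ground-truth imprinting status of each gene
#'
#' Exactly `round(frac_meg * n_genes)` genes are planted as MEGs and
#' `round(frac_peg * n_genes)` as PEGs (the first genes of a seeded
#' shuffle); the rest are biparental nulls. Deterministic given the
#' configuration seed.
#'
#' @param cfg A [sim_config()].
#' @return Tibble with `gene_id`, `true_status` (`"MEG"`, `"PEG"`,
#'   `"biparental"`), `true_theta`.
#' @export
simulate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  k_meg <- round(cfg$frac_meg * cfg$n_genes)
  k_peg <- round(cfg$frac_peg * cfg$n_genes)
  gene_id <- sprintf("gene%05d", seq_len(cfg$n_genes))
  withr::with_seed(cfg$seed, {
    order <- sample.int(cfg$n_genes)
  })
  status <- rep("biparental", cfg$n_genes)
  status[order[seq_len(k_meg)]] <- "MEG"
  if (k_peg > 0) status[order[k_meg + seq_len(k_peg)]] <- "PEG"
  theta <- c(MEG = cfg$theta_meg, PEG = cfg$theta_peg,
             biparental = cfg$theta_null)[status]
  tibble::tibble(gene_id = gene_id, true_status = status,
                 true_theta = unname(theta))
}

#' Simulate parental genotypes at SNP sites
#'
#' Lays genes out on two chromosomes, draws an informative-site count per
#' gene and a category per site, and emits genotypes consistent with the
#' category (heterozygous categories are named for direction 1, where
#' `plant_ids[1]` is the mother). Quality and DNA depth are drawn high
#' enough that category, not the variant filter, decides informativeness.
#'
#' @param cfg A [sim_config()].
#' @param filter_cfg Filter used to populate the `pass` column. The default
#'   relaxes the minor-allele-count floor to 1 because at the parental
#'   genotype level a single-parent heterozygous site always carries exactly
#'   one copy of its discriminant allele; keeping the floor at 2 would
#'   exclude the heterozygous categories the reciprocal-cross design is
#'   built to exploit (the original read-level filter counts endosperm
#'   reads, which informative heterozygous sites clear easily).
#' @return List with `sites` (same schema as [parse_parental_genotypes()],
#'   with `gene_id` filled and `plant_ids` attribute set) and `annotation`
#'   (tibble `chrom`, `start`, `end`, `gene_id`).
#' @export
simulate_parental_sites <- function(cfg,
                                    filter_cfg = filter_config(min_minor_allele_count = 1)) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_genes
  gene_id <- sprintf("gene%05d", seq_len(n))
  half <- ceiling(n / 2)
  chrom <- ifelse(seq_len(n) <= half, "chr1", "chr2")
  idx_on_chrom <- ifelse(seq_len(n) <= half, seq_len(n), seq_len(n) - half)
  start <- (idx_on_chrom - 1L) * 2000L + 1L
  end <- start + 1499L
  annotation <- tibble::tibble(chrom = chrom, start = start, end = end,
                               gene_id = gene_id)
  withr::with_seed(cfg$seed + 1L, {
    n_sites <- rnbinom(n, mu = cfg$sites_per_gene_mean,
                       size = cfg$sites_per_gene_dispersion)
    total_sites <- sum(n_sites)
    g <- rep.int(seq_len(n), n_sites)
    pos <- start[g] + unlist(lapply(n_sites[n_sites > 0], function(k) {
      sort(sample.int(1500L, k))
    })) - 1L
    category <- sample(SITE_CATEGORIES, total_sites, replace = TRUE,
                       prob = cfg$category_mix)
    flip <- runif(total_sites) < 0.5   # orientation of the genotype pair
    uninf_het <- runif(total_sites) < 0.5
    alleles <- t(vapply(seq_len(total_sites),
                        function(i) sample(c("A", "C", "G", "T"), 2),
                        character(2)))
    qual <- round(runif(total_sites, 30, 90), 1)
    depth <- rpois(total_sites, 30) + 10L
  })
  gt1 <- gt2 <- character(total_sites)
  rh <- category == "reciprocal_hom"
  gt1[rh] <- ifelse(flip[rh], "1/1", "0/0")
  gt2[rh] <- ifelse(flip[rh], "0/0", "1/1")
  mh <- category == "mother_het"
  gt1[mh] <- "0/1"
  gt2[mh] <- ifelse(flip[mh], "1/1", "0/0")
  fh <- category == "father_het"
  gt2[fh] <- "0/1"
  gt1[fh] <- ifelse(flip[fh], "1/1", "0/0")
  un <- category == "uninformative"
  gt1[un] <- ifelse(uninf_het[un], "0/1", ifelse(flip[un], "1/1", "0/0"))
  gt2[un] <- gt1[un]

  sites <- tibble::tibble(chrom = chrom[g], pos = pos,
                          ref = alleles[, 1], alt = alleles[, 2],
                          qual = qual, depth = as.numeric(depth))
  sites[[paste0("gt_", cfg$plant_ids[1])]] <- gt1
  sites[[paste0("gt_", cfg$plant_ids[2])]] <- gt2
  sites$pass <- site_passes_filters(sites, filter_cfg)
  d1 <- alt_dose(gt1)
  d2 <- alt_dose(gt2)
  sites$category_dir1 <- classify_dose_pair(d1, d2)
  sites$category_dir2 <- classify_dose_pair(d2, d1)
  sites$gene_id <- gene_id[g]
  attr(sites, "plant_ids") <- cfg$plant_ids
  list(sites = sites, annotation = annotation)
}

# Beta-binomial draws with intraclass correlation rho; rho = 0 is binomial.
rbetabinom <- function(n, size, prob, rho) {
  if (rho == 0) return(rbinom(n, size, prob))
  p <- prob
  edge <- p <= 0 | p >= 1
  shape_scale <- (1 - rho) / rho
  draw_p <- p
  if (any(!edge)) {
    draw_p[!edge] <- rbeta(sum(!edge), p[!edge] * shape_scale,
                           (1 - p[!edge]) * shape_scale)
  }
  rbinom(n, size, draw_p)
}

#' Simulate per-library allelic count tables for a reciprocal cross
#'
#' For each site, direction and replicate library, sequencing depth is
#' negative-binomial and the alternate-allele count beta-binomial around its
#' expected frequency. Under the pooled-transmission model the expected
#' alternate-allele frequency at a site is
#' `(1 - rho_c) * (theta * a_m + (1 - theta) * a_p) + rho_c * a_c`, where
#' `a_m`, `a_p` are the probabilities that a transmitted maternal/paternal
#' allele is the alternate (half the parent's alternate dose) and
#' `a_c = a_m` is the alternate fraction of maternal sporophytic
#' contamination reads. The reciprocal direction swaps the parental roles of
#' the same two genotype columns.
#'
#' @param cfg A [sim_config()].
#' @param truth Output of [simulate_truth()].
#' @param sites `sites` element of [simulate_parental_sites()].
#' @return List with `counts` (tibble `chrom`, `pos`, `library_id`,
#'   `count_ref`, `count_alt`) and `design` (see [reciprocal_design()];
#'   library ids are `"<direction>_rep<i>"`).
#' @export
simulate_count_tables <- function(cfg, truth, sites) {
  stopifnot(inherits(cfg, "sim_config"))
  design <- reciprocal_design(
    cfg$plant_ids[1], cfg$plant_ids[2],
    paste0(cfg$direction_ids[1], "_rep", seq_len(cfg$n_replicates)),
    paste0(cfg$direction_ids[2], "_rep", seq_len(cfg$n_replicates)),
    direction_ids = cfg$direction_ids)

  theta <- truth$true_theta[match(sites$gene_id, truth$gene_id)]
  d1 <- alt_dose(sites[[paste0("gt_", cfg$plant_ids[1])]])
  d2 <- alt_dose(sites[[paste0("gt_", cfg$plant_ids[2])]])

  per_lib <- lapply(seq_len(nrow(design)), function(i) {
    mother_dose <- if (design$mother[i] == cfg$plant_ids[1]) d1 else d2
    father_dose <- if (design$father[i] == cfg$plant_ids[1]) d1 else d2
    a_m <- mother_dose / 2
    a_p <- father_dose / 2
    f_alt <- (1 - cfg$contamination) * (theta * a_m + (1 - theta) * a_p) +
      cfg$contamination * a_m
    tibble::tibble(chrom = sites$chrom, pos = sites$pos,
                   library_id = design$library_id[i], f_alt = f_alt)
  })
  long <- dplyr::bind_rows(per_lib)
  withr::with_seed(cfg$seed + 2L, {
    depth <- rnbinom(nrow(long), mu = cfg$depth_mean,
                     size = cfg$depth_dispersion)
    count_alt <- rbetabinom(nrow(long), depth, long$f_alt, cfg$overdispersion)
  })
  counts <- tibble::tibble(chrom = long$chrom, pos = long$pos,
                           library_id = long$library_id,
                           count_ref = as.integer(depth - count_alt),
                           count_alt = as.integer(count_alt))
  list(counts = counts, design = design)
}

#' Generate a complete synthetic reciprocal-cross dataset
#'
#' Convenience wrapper running [simulate_truth()],
#' [simulate_parental_sites()] and [simulate_count_tables()] in sequence.
#'
#' @param cfg A [sim_config()].
#' @return List with `truth`, `sites`, `annotation`, `counts`, `design`,
#'   `cfg`.
#' @export
simulate_imprintome_data <- function(cfg = sim_config()) {
  truth <- simulate_truth(cfg)
  parents <- simulate_parental_sites(cfg)
  tabs <- simulate_count_tables(cfg, truth, parents$sites)
  list(truth = truth, sites = parents$sites, annotation = parents$annotation,
       counts = tabs$counts, design = tabs$design, cfg = cfg)
}

#' Write a simulated dataset to plain-text fixture files
#'
#' Emits a two-sample VCF of the parental genotypes (GT calls; QUAL and
#' INFO/DP populated), a GFF3 gene annotation, a per-library TSV count
#' table, the design TSV and the ground-truth TSV. Files are byte-stable
#' given the seed (which is recorded in the VCF header) and round-trip
#' through the package's own readers.
#'
#' @param sim Output of [simulate_imprintome_data()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the file paths
#'   (`variants`, `annotation`, `counts`, `design`, `truth`).
#' @export
write_fixtures <- function(sim, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  paths <- c(variants = file.path(out_dir, "parents.vcf"),
             annotation = file.path(out_dir, "genes.gff3"),
             counts = file.path(out_dir, "counts.tsv"),
             design = file.path(out_dir, "design.tsv"),
             truth = file.path(out_dir, "truth.tsv"))
  sites <- sim$sites
  plant_ids <- sim$cfg$plant_ids
  contigs <- unique(sites$chrom)
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=imprintr simulate (seed=", sim$cfg$seed, ")"),
    paste0("##contig=<ID=", contigs, ">"),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", plant_ids), collapse = "\t"))
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt,
                format(sites$qual, trim = TRUE, scientific = FALSE),
                "PASS", paste0("DP=", as.integer(sites$depth)), "GT",
                sites[[paste0("gt_", plant_ids[1])]],
                sites[[paste0("gt_", plant_ids[2])]],
                sep = "\t")
  writeLines(c(header, body), paths["variants"])

  gff <- paste(sim$annotation$chrom, "imprintr", "gene",
               sim$annotation$start, sim$annotation$end, ".", "+", ".",
               paste0("ID=", sim$annotation$gene_id), sep = "\t")
  writeLines(c("##gff-version 3", gff), paths["annotation"])

  readr::write_tsv(sim$counts, paths["counts"])
  readr::write_tsv(sim$design, paths["design"])
  readr::write_tsv(sim$truth, paths["truth"])
  invisible(paths)
}
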