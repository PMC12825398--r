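# End-to-end orchestration: sites -> counts -> ase -> caller, recovery
# experiments against simulated ground truth, and overlap convenience entry.

#' Run the imprintome inference pipeline
#'
#' Parses and filters parental genotypes, assigns sites to genes, extracts
#' and merges per-library allelic counts, transforms them into per-gene
#' maternal proportions for both cross directions, and calls the
#' imprintome. Every excluded site is accounted for: the attrition tally
#' satisfies `sites_in = failing_filters + uninformative + unassigned +
#' used`.
#'
#' @param variant_file Path to the two-parent genotype VCF.
#' @param counts Per-library count table, TSV path or AD-carrying VCF path
#'   (see [extract_allele_depths()]).
#' @param annotation Gene annotation tibble or file path (see
#'   [read_gene_annotation()]).
#' @param design Design tibble or TSV path (see [read_design()]).
#' @param filter_cfg A [filter_config()].
#' @param caller_cfg A [caller_config()].
#' @param min_reads Minimum transformed reads per gene and direction for an
#'   estimable maternal proportion. Default 10.
#' @param out_dir Optional directory; when given, writes `sites.tsv`,
#'   `gene_ase.tsv`, `imprintome.tsv` and `summary.json` there.
#' @return List with `sites`, `site_ase`, `gene_ase`, `imprintome`,
#'   `summary` (class counts, per-parent mean theta, assayable-gene count
#'   and the attrition tally).
#' @export
run_pipeline <- function(variant_file, counts, annotation, design,
                         filter_cfg = filter_config(),
                         caller_cfg = caller_config(),
                         min_reads = 10, out_dir = NULL) {
  if (is.character(design)) {
    if (!file.exists(design)) stop("design file not found: ", design)
    design <- read_design(design)
  }
  validate_design(design)
  plants <- unique(c(design$mother, design$father))
  if (length(plants) != 2) {
    stop("design must involve exactly two plants; got: ",
         paste(plants, collapse = ", "))
  }
  if (is.character(annotation)) annotation <- read_gene_annotation(annotation)

  sites <- parse_parental_genotypes(variant_file, plants[1], plants[2], filter_cfg)
  sites <- assign_sites_to_genes(sites, annotation)
  count_tab <- extract_allele_depths(counts, sites)
  merged <- merge_replicate_counts(count_tab, design)
  site_ase <- site_parental_counts(merged, sites, design)

  attrition <- pipeline_attrition(sites)
  usable <- !is.na(site_ase$gene_id)
  if (!any(usable)) {
    warning("no informative gene-assigned sites; imprintome is empty")
    imprintome <- tibble::tibble(gene_id = character(0),
                                 theta_dir1 = numeric(0), theta_dir2 = numeric(0),
                                 M_pooled = numeric(0), P_pooled = numeric(0),
                                 chi2 = numeric(0), p_value = numeric(0),
                                 q_value = numeric(0), status = character(0))
    attr(imprintome, "directions") <- unique(design$direction_id)
    gene_ase <- tibble::tibble(gene_id = character(0), direction_id = character(0),
                               M = numeric(0), P = numeric(0), theta = numeric(0),
                               n_sites = integer(0), n_reads = numeric(0),
                               estimable = logical(0))
  } else {
    gene_ase <- gene_maternal_proportion(site_ase, min_reads = min_reads)
    imprintome <- call_imprinting(gene_ase, caller_cfg)
  }
  summary <- summarize_imprintome(imprintome)
  summary$attrition <- attrition
  summary$mean_theta_by_mother <- mean_theta_by_mother(gene_ase, design)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_tsv(sites, file.path(out_dir, "sites.tsv"))
    readr::write_tsv(gene_ase, file.path(out_dir, "gene_ase.tsv"))
    readr::write_tsv(imprintome, file.path(out_dir, "imprintome.tsv"))
    jsonlite::write_json(summary_to_json(summary),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(sites = sites, site_ase = site_ase, gene_ase = gene_ase,
       imprintome = imprintome, summary = summary)
}

# Site attrition tally; conservation (in = fail + uninformative + unassigned
# + used) holds by construction and is asserted here.
pipeline_attrition <- function(sites) {
  informative <- !is.na(sites$category_dir1) & sites$category_dir1 != "uninformative"
  tally <- c(
    sites_in = nrow(sites),
    sites_failing_filters = sum(!sites$pass),
    sites_uninformative = sum(sites$pass & !informative),
    sites_unassigned = sum(sites$pass & informative & is.na(sites$gene_id)),
    sites_used = sum(sites$pass & informative & !is.na(sites$gene_id)),
    sites_ambiguous_gene = attr(sites, "n_ambiguous") %||% NA_integer_
  )
  stopifnot(tally[["sites_in"]] == tally[["sites_failing_filters"]] +
              tally[["sites_uninformative"]] + tally[["sites_unassigned"]] +
              tally[["sites_used"]])
  tally
}

mean_theta_by_mother <- function(gene_ase, design) {
  plants <- unique(design$mother)
  vapply(plants, function(p) {
    tryCatch(dataset_mean_maternal_proportion(gene_ase, design, p),
             error = function(e) NA_real_)
  }, numeric(1))
}

summary_to_json <- function(summary) {
  summary$status_counts <- as.list(summary$status_counts)
  summary$attrition <- as.list(summary$attrition)
  summary$mean_theta_by_mother <- as.list(summary$mean_theta_by_mother)
  summary
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Recovery experiment on simulated data
#'
#' Simulates reciprocal-cross datasets with known ground truth over several
#' seeds, runs the in-memory analysis chain (merge, transform, aggregate,
#' call) and scores the calls against the planted truth: sensitivity per
#' imprinted class (a planted MEG counts as recovered when called
#' `MEG_strong` or `MEG_moderate`, symmetrically for PEGs), false imprinted
#' calls among null genes, and the mean pooled maternal-proportion estimate
#' per class.
#'
#' @param sim_cfg A [sim_config()]; seed `i - 1` offsets are applied per
#'   replicate run.
#' @param caller_cfg A [caller_config()].
#' @param n_seeds Number of simulated replicates. Default 10.
#' @param min_reads Passed to [gene_maternal_proportion()]. Default 10.
#' @return Tibble with one row per seed: `seed`, `n_assayable`,
#'   `meg_sensitivity`, `peg_sensitivity`, `false_imprinted`,
#'   `mean_theta_meg`, `mean_theta_peg`, `mean_theta_null`,
#'   `mean_theta_null_dir1`, `mean_theta_null_dir2`.
#' @export
run_recovery_experiment <- function(sim_cfg = sim_config(),
                                    caller_cfg = caller_config(),
                                    n_seeds = 10, min_reads = 10) {
  stopifnot(inherits(sim_cfg, "sim_config"), n_seeds >= 1)
  rows <- lapply(seq_len(n_seeds), function(i) {
    cfg_i <- sim_cfg
    cfg_i$seed <- sim_cfg$seed + (i - 1L) * 7L
    sim <- simulate_imprintome_data(cfg_i)
    merged <- merge_replicate_counts(sim$counts, sim$design)
    site_ase <- site_parental_counts(merged, sim$sites, sim$design)
    gene_ase <- gene_maternal_proportion(site_ase, min_reads = min_reads)
    imp <- call_imprinting(gene_ase, caller_cfg,
                           directions = cfg_i$direction_ids)
    scored <- dplyr::left_join(sim$truth, imp, by = "gene_id")
    scored$status[is.na(scored$status)] <- "undetermined"
    called_meg <- scored$status %in% c("MEG_strong", "MEG_moderate")
    called_peg <- scored$status %in% c("PEG_strong", "PEG_moderate")
    theta_pooled <- scored$M_pooled / (scored$M_pooled + scored$P_pooled)
    null_ase <- gene_ase[gene_ase$estimable &
                           gene_ase$gene_id %in%
                           scored$gene_id[scored$true_status == "biparental"], ]
    class_mean <- function(class) {
      sel <- scored$true_status == class & !is.na(theta_pooled) &
        !is.na(scored$theta_dir1) & !is.na(scored$theta_dir2)
      if (any(sel)) mean(theta_pooled[sel]) else NA_real_
    }
    dir_mean <- function(d) {
      th <- null_ase$theta[null_ase$direction_id == d]
      if (length(th)) mean(th) else NA_real_
    }
    tibble::tibble(
      seed = cfg_i$seed,
      n_assayable = sum(!is.na(scored$theta_dir1) & !is.na(scored$theta_dir2)),
      meg_sensitivity = mean(called_meg[scored$true_status == "MEG"]),
      peg_sensitivity = mean(called_peg[scored$true_status == "PEG"]),
      false_imprinted = sum((called_meg | called_peg) &
                              scored$true_status == "biparental"),
      mean_theta_meg = class_mean("MEG"),
      mean_theta_peg = class_mean("PEG"),
      mean_theta_null = class_mean("biparental"),
      mean_theta_null_dir1 = dir_mean(cfg_i$direction_ids[1]),
      mean_theta_null_dir2 = dir_mean(cfg_i$direction_ids[2]))
  })
  dplyr::bind_rows(rows)
}

#' Gene-set overlap entry point
#'
#' Reads newline-delimited gene lists (or takes character vectors), builds
#' the contingency table against a universe and runs the exact overlap
#' test.
#'
#' @param set_a,set_b,universe Character vectors of gene ids, or paths to
#'   newline-delimited list files.
#' @param ... Passed to [exact_overlap_test()] (`alternative`, `or_method`).
#' @return The [exact_overlap_test()] result.
#' @export
run_overlap <- function(set_a, set_b, universe, ...) {
  read_list <- function(x) {
    if (is.character(x) && length(x) == 1 && file.exists(x)) {
      x <- readLines(x)
      x[nzchar(x)]
    } else x
  }
  tab <- contingency_from_sets(read_list(set_a), read_list(set_b),
                               read_list(universe))
  exact_overlap_test(tab, ...)
}
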