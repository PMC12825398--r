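# Transformation of discriminant-allele counts into maternal/paternal read
# equivalents per site, and aggregation to per-gene maternal proportions.

#' Transform merged site counts into parental read equivalents
#'
#' For each cross direction, every informative site's reference/alternate
#' counts are converted into maternal (`m_hat`) and paternal (`p_hat`) read
#' equivalents according to its category:
#'
#' * `reciprocal_hom` — the mother's allele is fully discriminant:
#'   `m_hat` is the count of the maternal allele, `p_hat` the rest.
#' * `mother_het` — the father is homozygous for one allele; the mother
#'   carries the other (mother-specific) allele on one chromosome. The
#'   captured tissue pools endosperms from many seeds and the mother
#'   transmits each allele to half of them, so the mother-specific allele is
#'   expected at frequency theta/2 where theta is the maternal expression
#'   proportion. Hence `m_hat = min(2 * count(mother-specific), total)`,
#'   `p_hat = total - m_hat`; `truncated` flags sites where the doubling
#'   exceeded the site total and was capped.
#' * `father_het` — symmetric on the paternal side:
#'   `p_hat = min(2 * count(father-specific), total)`.
#'
#' Uninformative sites and sites with a merged total of zero in a direction
#' are excluded (they carry no parent-of-origin information); exclusion
#' counts are attached as attributes.
#'
#' @param merged Merged counts per direction from [merge_replicate_counts()].
#' @param sites Site tibble with genotypes, `pass` and `gene_id` columns
#'   (from [parse_parental_genotypes()] + [assign_sites_to_genes()], or the
#'   simulator).
#' @param design Design tibble declaring each direction's mother and father.
#' @return Tibble with `direction_id`, `chrom`, `pos`, `gene_id`,
#'   `category`, `m_hat`, `p_hat`, `total`, `truncated`.
#' @export
site_parental_counts <- function(merged, sites, design) {
  validate_design(design)
  gt_cols <- grep("^gt_", names(sites), value = TRUE)
  if (length(gt_cols) != 2) stop("site table must carry exactly two gt_<plant> columns")
  plant_ids <- sub("^gt_", "", gt_cols)
  roles <- dplyr::distinct(design[, c("direction_id", "mother", "father")])
  if (!all(c(roles$mother, roles$father) %in% plant_ids)) {
    stop("design plants (", paste(unique(c(roles$mother, roles$father)), collapse = ", "),
         ") do not match site genotype columns (", paste(plant_ids, collapse = ", "), ")")
  }

  use <- c("chrom", "pos", "gene_id", "pass", gt_cols)
  joined <- dplyr::inner_join(merged, sites[, use], by = c("chrom", "pos"))
  joined <- dplyr::left_join(joined, roles, by = "direction_id")
  joined <- joined[joined$pass, , drop = FALSE]

  mother_gt <- ifelse(joined$mother == plant_ids[1],
                      joined[[gt_cols[1]]], joined[[gt_cols[2]]])
  father_gt <- ifelse(joined$father == plant_ids[1],
                      joined[[gt_cols[1]]], joined[[gt_cols[2]]])
  dm <- alt_dose(mother_gt)
  df <- alt_dose(father_gt)
  joined$category <- classify_dose_pair(dm, df)

  n_uninf <- sum(joined$category == "uninformative", na.rm = TRUE)
  n_zero <- sum(joined$total == 0 & !is.na(joined$category) &
                  joined$category != "uninformative")
  keep <- !is.na(joined$category) & joined$category != "uninformative" &
    joined$total > 0
  joined <- joined[keep, , drop = FALSE]
  dm <- dm[keep]
  df <- df[keep]

  m_hat <- p_hat <- rep(NA_real_, nrow(joined))
  truncated <- rep(FALSE, nrow(joined))

  rh <- joined$category == "reciprocal_hom"
  # maternal allele is alt when the mother is the alt-homozygote
  m_hat[rh] <- ifelse(dm[rh] == 2, joined$count_alt[rh], joined$count_ref[rh])
  p_hat[rh] <- joined$total[rh] - m_hat[rh]

  mh <- joined$category == "mother_het"
  # mother-specific allele = the allele the homozygous father lacks
  y_count <- ifelse(df[mh] == 0, joined$count_alt[mh], joined$count_ref[mh])
  m_raw <- 2 * y_count
  m_hat[mh] <- pmin(m_raw, joined$total[mh])
  p_hat[mh] <- joined$total[mh] - m_hat[mh]
  truncated[mh] <- m_raw > joined$total[mh]

  fh <- joined$category == "father_het"
  y_count <- ifelse(dm[fh] == 0, joined$count_alt[fh], joined$count_ref[fh])
  p_raw <- 2 * y_count
  p_hat[fh] <- pmin(p_raw, joined$total[fh])
  m_hat[fh] <- joined$total[fh] - p_hat[fh]
  truncated[fh] <- p_raw > joined$total[fh]

  out <- tibble::tibble(direction_id = joined$direction_id,
                        chrom = joined$chrom, pos = joined$pos,
                        gene_id = joined$gene_id,
                        category = joined$category,
                        m_hat = m_hat, p_hat = p_hat,
                        total = joined$total, truncated = truncated)
  attr(out, "n_uninformative") <- n_uninf
  attr(out, "n_zero_total") <- n_zero
  out
}

#' Aggregate site-level parental counts to per-gene maternal proportions
#'
#' Transformed counts are summed over a gene's informative sites within each
#' direction (depth-weighting sites, consistent with count-based testing
#' downstream): `M = sum(m_hat)`, `P = sum(p_hat)`, and the maternal
#' proportion `theta = M / (M + P)`. Genes with fewer than `min_reads`
#' transformed reads in a direction are flagged `estimable = FALSE` and get
#' no theta there; such genes are excluded from imprinting calling in that
#' direction.
#'
#' @param site_ase Output of [site_parental_counts()]. Sites without a gene
#'   assignment are dropped.
#' @param min_reads Minimum `M + P` per gene and direction for a reported
#'   theta. Default 10.
#' @return Tibble with `gene_id`, `direction_id`, `M`, `P`, `theta`,
#'   `n_sites`, `n_reads`, `estimable`.
#' @export
gene_maternal_proportion <- function(site_ase, min_reads = 10) {
  stopifnot(is.numeric(min_reads), min_reads >= 0)
  site_ase <- site_ase[!is.na(site_ase$gene_id), , drop = FALSE]
  if (nrow(site_ase) == 0) stop("no gene-assigned informative sites to aggregate")
  out <- site_ase |>
    dplyr::group_by(.data$gene_id, .data$direction_id) |>
    dplyr::summarise(M = sum(.data$m_hat), P = sum(.data$p_hat),
                     n_sites = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(n_reads = .data$M + .data$P,
                  estimable = .data$n_reads >= min_reads,
                  theta = ifelse(.data$estimable, .data$M / .data$n_reads, NA_real_))
  out[, c("gene_id", "direction_id", "M", "P", "theta",
          "n_sites", "n_reads", "estimable")]
}

#' Mean maternal proportion for one parent in the mother role
#'
#' Unweighted mean of per-gene maternal proportions over the direction(s) in
#' which the given plant was the mother. In a well-behaved diploid endosperm
#' dataset this sits near 0.5.
#'
#' @param gene_ase Output of [gene_maternal_proportion()].
#' @param design Design tibble.
#' @param maternal_plant_id Plant whose mother-role directions to average.
#' @return A single numeric mean theta.
#' @export
dataset_mean_maternal_proportion <- function(gene_ase, design, maternal_plant_id) {
  dirs <- unique(design$direction_id[design$mother == maternal_plant_id])
  if (length(dirs) == 0) stop("plant ", maternal_plant_id, " is never the mother in this design")
  theta <- gene_ase$theta[gene_ase$direction_id %in% dirs & gene_ase$estimable]
  if (length(theta) == 0) stop("no genes with an estimable maternal proportion for ",
                               maternal_plant_id)
  mean(theta)
}
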