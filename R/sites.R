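# Parental genotype ingestion, variant filtering, informative-site
# classification and site-to-gene assignment.

#' Variant filter configuration
#'
#' Thresholds applied to candidate SNPs before they enter the imprinting
#' analysis: only biallelic SNPs with sufficient variant quality, read depth
#' and minor-allele support are retained. Defaults retain biallelic sites
#' with a minor allele count >= 2 (counted over the four parental allele
#' copies), quality >= 20 and depth >= 5.
#'
#' @param min_qual Minimum variant quality score (QUAL). Default 20.
#' @param min_depth Minimum total read depth at the site (INFO/DP). Default 5.
#' @param min_minor_allele_count Minimum number of copies of the rarer allele
#'   among the four parental allele copies. Default 2.
#' @param require_biallelic Keep only biallelic SNPs. Default `TRUE`.
#' @return A `filter_config` list.
#' @export
#' @examples
#' filter_config()
#' filter_config(min_depth = 10)
filter_config <- function(min_qual = 20, min_depth = 5,
                          min_minor_allele_count = 2,
                          require_biallelic = TRUE) {
  stopifnot(is.numeric(min_qual), min_qual >= 0,
            is.numeric(min_depth), min_depth >= 0,
            is.numeric(min_minor_allele_count), min_minor_allele_count >= 0,
            is.logical(require_biallelic), length(require_biallelic) == 1)
  structure(list(min_qual = min_qual,
                 min_depth = min_depth,
                 min_minor_allele_count = min_minor_allele_count,
                 require_biallelic = require_biallelic),
            class = "filter_config")
}

# Normalise diploid GT strings: phased -> unphased, allele order sorted,
# missing calls -> NA.
normalize_gt <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  gt[gt %in% c(".", "./.", ".", "./", "/.") | is.na(gt)] <- NA_character_
  gt[grepl("\\.", gt)] <- NA_character_
  swap <- !is.na(gt) & gt == "1/0"
  gt[swap] <- "0/1"
  gt
}

# Number of alternate-allele copies in a normalised genotype (0, 1, 2 or NA).
alt_dose <- function(gt) {
  unname(c("0/0" = 0, "0/1" = 1, "1/1" = 2)[gt])
}

# Vectorised category from allele doses; NA when either dose is missing.
classify_dose_pair <- function(mother_dose, father_dose) {
  out <- rep(NA_character_, length(mother_dose))
  ok <- !is.na(mother_dose) & !is.na(father_dose)
  m <- mother_dose
  f <- father_dose
  hom_m <- m %in% c(0, 2)
  hom_f <- f %in% c(0, 2)
  out[ok & hom_m & hom_f & m != f] <- "reciprocal_hom"
  out[ok & m == 1 & hom_f] <- "mother_het"
  out[ok & f == 1 & hom_m] <- "father_het"
  out[ok & ((hom_m & hom_f & m == f) | (m == 1 & f == 1))] <- "uninformative"
  out
}

#' Classify a SNP as imprinting-informative or not
#'
#' A site lets reads be assigned a parent of origin when the two parents are
#' homozygous for different alleles (`reciprocal_hom`) or when exactly one
#' parent is heterozygous (`mother_het` / `father_het`, named for the
#' heterozygous parent's role in the given cross direction). Sites where both
#' parents are heterozygous, or homozygous for the same allele, carry no
#' discriminant allele and are `uninformative`. Swapping the two arguments
#' (i.e. swapping the cross direction) maps `mother_het` to `father_het` and
#' leaves the other categories fixed.
#'
#' @param mother_gt,father_gt Diploid genotypes of the mother and father at
#'   the site, as `"0/0"`, `"0/1"` or `"1/1"` (phased separators accepted).
#'   Vectorised.
#' @return Character vector of categories: one of `"reciprocal_hom"`,
#'   `"mother_het"`, `"father_het"`, `"uninformative"`.
#' @export
#' @examples
#' classify_site("0/0", "1/1")   # reciprocal_hom
#' classify_site("0/1", "0/0")   # mother_het
#' classify_site("0/1", "0/1")   # uninformative
classify_site <- function(mother_gt, father_gt) {
  m <- alt_dose(normalize_gt(mother_gt))
  f <- alt_dose(normalize_gt(father_gt))
  if (anyNA(m) || anyNA(f)) {
    stop("classify_site() requires both genotypes to be called at every site")
  }
  classify_dose_pair(m, f)
}

#' Parse parental genotypes from a VCF
#'
#' Reads a two-sample (or larger) VCF of the two parental plants and returns
#' one row per biallelic SNP with both genotypes, variant quality, site depth
#' (INFO/DP), filter status and the informative-site category for each
#' direction of the reciprocal cross. Direction 1 takes `plant1_id` as
#' mother, direction 2 takes `plant2_id` as mother. Rows with a missing
#' genotype in either plant are retained with `pass = FALSE`; multiallelic
#' rows and non-SNP variants are excluded and counted.
#'
#' @param vcf_path Path to a VCF (v4.x) file with GT calls for both plants.
#' @param plant1_id,plant2_id Sample names of the two parents as they appear
#'   in the VCF header.
#' @param cfg A [filter_config()].
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `depth`, `gt_<plant1_id>`, `gt_<plant2_id>`, `pass`, `category_dir1`,
#'   `category_dir2` and `gene_id` (`NA` until [assign_sites_to_genes()]).
#'   Attributes: `plant_ids` (the two sample names) and `attrition` (counts
#'   of excluded/failed rows).
#' @export
parse_parental_genotypes <- function(vcf_path, plant1_id, plant2_id,
                                     cfg = filter_config()) {
  if (!file.exists(vcf_path)) stop("variant file not found: ", vcf_path)
  vcf <- tryCatch(vcfR::read.vcfR(vcf_path, verbose = FALSE),
                  error = function(e) stop("malformed variant file '", vcf_path,
                                           "': ", conditionMessage(e)))
  samples <- colnames(vcf@gt)[-1]
  missing_samples <- setdiff(c(plant1_id, plant2_id), samples)
  if (length(missing_samples) > 0) {
    stop("sample(s) not present in VCF: ", paste(missing_samples, collapse = ", "))
  }
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dp <- suppressWarnings(vcfR::extract.info(vcf, element = "DP", as.numeric = TRUE))
  if (is.null(dp)) dp <- rep(NA_real_, nrow(fix))

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_snp <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L & ref != alt
  n_multi <- sum(!is.na(alt) & grepl(",", alt, fixed = TRUE))
  n_nonsnp <- sum(!is_snp) - n_multi

  out <- tibble::tibble(
    chrom = fix[is_snp, "CHROM"],
    pos = as.integer(fix[is_snp, "POS"]),
    ref = ref[is_snp],
    alt = alt[is_snp],
    qual = suppressWarnings(as.numeric(fix[is_snp, "QUAL"])),
    depth = dp[is_snp],
    gt1 = normalize_gt(gt[is_snp, plant1_id]),
    gt2 = normalize_gt(gt[is_snp, plant2_id])
  )
  names(out)[names(out) == "gt1"] <- paste0("gt_", plant1_id)
  names(out)[names(out) == "gt2"] <- paste0("gt_", plant2_id)

  out$pass <- site_passes_filters(out, cfg)
  d1 <- alt_dose(out[[paste0("gt_", plant1_id)]])
  d2 <- alt_dose(out[[paste0("gt_", plant2_id)]])
  out$category_dir1 <- classify_dose_pair(d1, d2)
  out$category_dir2 <- classify_dose_pair(d2, d1)
  out$gene_id <- NA_character_

  n_missing_gt <- sum(is.na(d1) | is.na(d2))
  attr(out, "plant_ids") <- c(plant1_id, plant2_id)
  attr(out, "attrition") <- c(n_vcf_rows = nrow(fix),
                              n_multiallelic = n_multi,
                              n_non_snp = n_nonsnp,
                              n_missing_genotype = n_missing_gt,
                              n_fail_filters = sum(!out$pass))
  out
}

#' Apply variant filters to a site table
#'
#' A site passes when its quality and depth meet the configured floors, both
#' parental genotypes are called, the site is a biallelic SNP, and the rarer
#' allele across the four parental allele copies occurs at least
#' `min_minor_allele_count` times. Filtering is monotone: relaxing any
#' threshold never removes a passing site.
#'
#' @param sites Site tibble as from [parse_parental_genotypes()] (needs
#'   `qual`, `depth` and the two `gt_*` columns).
#' @param cfg A [filter_config()].
#' @return Logical vector, one element per site.
#' @export
site_passes_filters <- function(sites, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  gt_cols <- grep("^gt_", names(sites), value = TRUE)
  if (length(gt_cols) != 2) {
    stop("site table must carry exactly two gt_<plant> columns")
  }
  d1 <- alt_dose(sites[[gt_cols[1]]])
  d2 <- alt_dose(sites[[gt_cols[2]]])
  both_called <- !is.na(d1) & !is.na(d2)
  alt_copies <- d1 + d2
  minor <- pmin(alt_copies, 4 - alt_copies)
  qual_ok <- !is.na(sites$qual) & sites$qual >= cfg$min_qual
  depth_ok <- !is.na(sites$depth) & sites$depth >= cfg$min_depth
  if (cfg$min_qual == 0) qual_ok <- qual_ok | is.na(sites$qual)
  if (cfg$min_depth == 0) depth_ok <- depth_ok | is.na(sites$depth)
  biallelic_ok <- if (cfg$require_biallelic) {
    nchar(sites$ref) == 1L & nchar(sites$alt) == 1L & sites$ref != sites$alt
  } else rep(TRUE, nrow(sites))
  pass <- qual_ok & depth_ok & both_called & biallelic_ok
  pass & dplyr::coalesce(minor >= cfg$min_minor_allele_count, FALSE)
}

#' Read a gene annotation as 1-based inclusive intervals
#'
#' Accepts GFF3 (rows of type `gene`; `ID` attribute used as the gene
#' identifier) or a 4-column tab-separated table (`chrom`, `start`, `end`,
#' `gene_id`). Tabular input must declare its coordinate convention via
#' `zero_based_half_open`; GFF3 is 1-based inclusive by definition.
#'
#' @param path Annotation file path.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @param zero_based_half_open For tabular input only: intervals are BED-style
#'   0-based half-open and are converted. Default `FALSE` (1-based inclusive).
#' @return Tibble with `chrom`, `start`, `end`, `gene_id`.
#' @export
read_gene_annotation <- function(path, format = c("auto", "gff3", "tsv"),
                                 zero_based_half_open = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "gene"]
    tibble::tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   gene_id = as.character(gr$ID))
  } else {
    ann <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             chrom = readr::col_character(),
                             start = readr::col_integer(),
                             end = readr::col_integer(),
                             gene_id = readr::col_character()))
    if (zero_based_half_open) ann$start <- ann$start + 1L
    ann
  }
}

#' Assign SNP sites to genes
#'
#' Each site falling inside exactly one gene interval receives that gene's
#' identifier. Sites overlapping two or more genes are left unassigned (to
#' avoid double-counting their reads in two genes' maternal proportions) and
#' tallied in the `n_ambiguous` attribute; intergenic sites stay unassigned.
#'
#' @param sites Site tibble with `chrom` and `pos`.
#' @param annotation Tibble with `chrom`, `start`, `end`, `gene_id`
#'   (1-based inclusive intervals), e.g. from [read_gene_annotation()].
#' @return `sites` with `gene_id` filled in; attributes `n_ambiguous`
#'   (sites dropped for overlapping >= 2 genes) and `n_intergenic`.
#' @export
assign_sites_to_genes <- function(sites, annotation) {
  stopifnot(all(c("chrom", "pos") %in% names(sites)),
            all(c("chrom", "start", "end", "gene_id") %in% names(annotation)))
  keep_attrs <- attributes(sites)[c("plant_ids", "attrition")]
  if (nrow(sites) == 0) {
    sites$gene_id <- character(0)
    attr(sites, "n_ambiguous") <- 0L
    attr(sites, "n_intergenic") <- 0L
    return(sites)
  }
  if (length(intersect(unique(sites$chrom), unique(annotation$chrom))) == 0) {
    warning("annotation and variant sequence names are disjoint; no sites assigned")
  }
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos, width = 1))
  gene_gr <- GenomicRanges::GRanges(annotation$chrom,
                                    IRanges::IRanges(annotation$start, annotation$end))
  # suppress the benign seqlevel-mismatch warning; disjointness is reported
  # through the explicit warning above
  hits <- suppressWarnings(GenomicRanges::findOverlaps(site_gr, gene_gr))
  n_hits <- tabulate(S4Vectors::queryHits(hits), nbins = nrow(sites))
  gene_id <- rep(NA_character_, nrow(sites))
  uniq <- S4Vectors::queryHits(hits)[n_hits[S4Vectors::queryHits(hits)] == 1L]
  uniq_gene <- S4Vectors::subjectHits(hits)[n_hits[S4Vectors::queryHits(hits)] == 1L]
  gene_id[uniq] <- annotation$gene_id[uniq_gene]
  sites$gene_id <- gene_id
  for (a in names(keep_attrs)) if (!is.null(keep_attrs[[a]])) attr(sites, a) <- keep_attrs[[a]]
  attr(sites, "n_ambiguous") <- sum(n_hits > 1L)
  attr(sites, "n_intergenic") <- sum(n_hits == 0L)
  sites
}
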