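# Per-library allelic read counts at informative sites and replicate merging.

#' Build the design table of a reciprocal cross
#'
#' One row per sequencing library, declaring which cross direction it belongs
#' to and which plant acted as mother and father in that direction. The two
#' directions of a reciprocal pair swap the mother/father roles of the same
#' two plants.
#'
#' @param plant1,plant2 Identifiers of the two parental plants.
#' @param libraries_dir1 Library ids of the replicates where `plant1` is the
#'   mother.
#' @param libraries_dir2 Library ids of the replicates where `plant2` is the
#'   mother.
#' @param direction_ids Length-2 character vector naming the two directions
#'   (mother listed first by convention). Default `"<p1>x<p2>"`, `"<p2>x<p1>"`.
#' @return Tibble with columns `direction_id`, `mother`, `father`,
#'   `library_id`.
#' @export
#' @examples
#' reciprocal_design("P1", "P2",
#'                   paste0("P1xP2_rep", 1:3),
#'                   paste0("P2xP1_rep", 1:3))
reciprocal_design <- function(plant1, plant2, libraries_dir1, libraries_dir2,
                              direction_ids = c(paste0(plant1, "x", plant2),
                                                paste0(plant2, "x", plant1))) {
  stopifnot(length(direction_ids) == 2, plant1 != plant2,
            length(libraries_dir1) >= 1, length(libraries_dir2) >= 1,
            !anyDuplicated(c(libraries_dir1, libraries_dir2)))
  dplyr::bind_rows(
    tibble::tibble(direction_id = direction_ids[1], mother = plant1,
                   father = plant2, library_id = libraries_dir1),
    tibble::tibble(direction_id = direction_ids[2], mother = plant2,
                   father = plant1, library_id = libraries_dir2))
}

#' Read a cross-design file
#'
#' Tab-separated with columns `direction_id`, `mother`, `father`,
#' `library_id`, one row per library.
#'
#' @param path Design file path.
#' @return Design tibble, validated (mother differs from father, at least one
#'   replicate per direction).
#' @export
read_design <- function(path) {
  design <- readr::read_tsv(path, show_col_types = FALSE,
                            col_types = readr::cols(.default = readr::col_character()))
  required <- c("direction_id", "mother", "father", "library_id")
  if (!all(required %in% names(design))) {
    stop("design file must have columns: ", paste(required, collapse = ", "))
  }
  validate_design(design)
  design[required]
}

validate_design <- function(design) {
  if (any(design$mother == design$father)) {
    stop("design invalid: mother and father must differ")
  }
  n_rep <- table(design$direction_id)
  if (any(n_rep < 1) || nrow(design) == 0) {
    stop("design invalid: every direction needs at least one replicate library")
  }
  if (anyDuplicated(design$library_id)) {
    stop("design invalid: duplicated library_id")
  }
  invisible(design)
}

#' Extract per-library allelic read counts at known sites
#'
#' Accepts either a plain count table (tibble or TSV path with columns
#' `chrom`, `pos`, `library_id`, `count_ref`, `count_alt`) or a VCF whose
#' sample columns are libraries carrying an `AD` (allele depth) FORMAT field.
#' Counts are returned for every (site, library) combination: sites absent
#' from a library get `(0, 0)`. For VCF input, REF/ALT must match the site
#' table's alleles; a mismatch is an error naming the site, as is an `AD`
#' field with more than two values at a supposedly biallelic site.
#'
#' @param x Count table, TSV path, or VCF path.
#' @param sites Site tibble (from [parse_parental_genotypes()] or the
#'   simulator) restricting and ordering the extraction.
#' @return Tibble with `chrom`, `pos`, `library_id`, `count_ref`,
#'   `count_alt`, `total`.
#' @export
extract_allele_depths <- function(x, sites) {
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  if (is.character(x) && length(x) == 1) {
    counts <- if (grepl("\\.vcf(\\.gz)?$", x, ignore.case = TRUE)) {
      ad_counts_from_vcf(x, sites)
    } else {
      readr::read_tsv(x, show_col_types = FALSE,
                      col_types = readr::cols(chrom = readr::col_character(),
                                              pos = readr::col_integer(),
                                              library_id = readr::col_character(),
                                              count_ref = readr::col_integer(),
                                              count_alt = readr::col_integer()))
    }
  } else {
    counts <- tibble::as_tibble(x)
  }
  required <- c("chrom", "pos", "library_id", "count_ref", "count_alt")
  if (!all(required %in% names(counts))) {
    stop("count input must have columns: ", paste(required, collapse = ", "))
  }
  if (any(counts$count_ref < 0 | counts$count_alt < 0, na.rm = TRUE)) {
    stop("negative allele counts in input")
  }
  libs <- sort(unique(counts$library_id))
  grid <- tidyr::crossing(dplyr::distinct(sites[, c("chrom", "pos")]),
                          library_id = libs)
  out <- dplyr::left_join(grid, counts[required],
                          by = c("chrom", "pos", "library_id"))
  out$count_ref <- dplyr::coalesce(out$count_ref, 0L)
  out$count_alt <- dplyr::coalesce(out$count_alt, 0L)
  out$total <- out$count_ref + out$count_alt
  out
}

# AD-field extraction from a per-library VCF (samples = libraries).
ad_counts_from_vcf <- function(path, sites) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ad <- vcfR::extract.gt(vcf, element = "AD")
  key <- tibble::tibble(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                        ref = fix[, "REF"], alt = fix[, "ALT"])
  ref_alt <- dplyr::inner_join(key,
                               sites[, c("chrom", "pos", "ref", "alt")],
                               by = c("chrom", "pos"), suffix = c("", ".site"))
  bad <- ref_alt$ref != ref_alt$ref.site | ref_alt$alt != ref_alt$alt.site
  if (any(bad)) {
    stop("allele order mismatch between count VCF and site table at ",
         ref_alt$chrom[bad][1], ":", ref_alt$pos[bad][1])
  }
  long <- tibble::tibble(
    chrom = rep(key$chrom, ncol(ad)),
    pos = rep(key$pos, ncol(ad)),
    library_id = rep(colnames(ad), each = nrow(ad)),
    ad = as.vector(ad))
  long <- long[!is.na(long$ad), ]
  parts <- strsplit(long$ad, ",", fixed = TRUE)
  n_alleles <- lengths(parts)
  if (any(n_alleles > 2)) {
    i <- which(n_alleles > 2)[1]
    stop("AD field with ", n_alleles[i], " values at biallelic site ",
         long$chrom[i], ":", long$pos[i])
  }
  long$count_ref <- as.integer(vapply(parts, `[`, "", 1))
  long$count_alt <- as.integer(vapply(parts, function(p) if (length(p) > 1) p[2] else "0", ""))
  long[, c("chrom", "pos", "library_id", "count_ref", "count_alt")]
}

#' Merge replicate libraries within each cross direction
#'
#' Allelic counts are pooled by summation across a direction's replicate
#' libraries before estimation, mirroring a merge of the replicate alignments
#' ahead of variant evaluation. Per-replicate counts remain available in the
#' unmerged table for diagnostics.
#'
#' @param counts Per-library count tibble from [extract_allele_depths()].
#' @param design Design tibble from [reciprocal_design()] / [read_design()].
#' @return Tibble with `direction_id`, `chrom`, `pos`, `count_ref`,
#'   `count_alt`, `total`, `n_libraries`.
#' @export
merge_replicate_counts <- function(counts, design) {
  validate_design(design)
  unknown <- setdiff(unique(counts$library_id), design$library_id)
  if (length(unknown) > 0) {
    stop("library id(s) absent from design: ", paste(unknown, collapse = ", "))
  }
  dplyr::inner_join(counts, design[, c("direction_id", "library_id")],
                    by = "library_id") |>
    dplyr::group_by(.data$direction_id, .data$chrom, .data$pos) |>
    dplyr::summarise(count_ref = sum(.data$count_ref),
                     count_alt = sum(.data$count_alt),
                     n_libraries = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(total = .data$count_ref + .data$count_alt)
}
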