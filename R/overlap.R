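# Exact contingency-table enrichment statistics for gene-set overlaps and
# cross-species imprinted-gene comparisons through ortholog maps.

#' Build a 2x2 contingency table from two gene sets and a universe
#'
#' Cells: `a = |A intersect B|`, `b = |A \ B|`, `c = |B \ A|`,
#' `d = |U \ (A union B)|`. Both sets must be subsets of the universe;
#' offenders are reported. Duplicated identifiers are collapsed.
#'
#' @param set_a,set_b Character vectors of gene identifiers.
#' @param universe Character vector: the background gene universe.
#' @return A `contingency_table` list with fields `a`, `b`, `c`, `d`.
#' @export
contingency_from_sets <- function(set_a, set_b, universe) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  universe <- unique(universe)
  outside <- setdiff(union(set_a, set_b), universe)
  if (length(outside) > 0) {
    stop("gene(s) outside the universe: ",
         paste(head(outside, 10), collapse = ", "),
         if (length(outside) > 10) " ..." else "")
  }
  a <- length(intersect(set_a, set_b))
  contingency_table(a = a,
                    b = length(set_a) - a,
                    c = length(set_b) - a,
                    d = length(universe) - length(set_a) - length(set_b) + a)
}

#' Construct a 2x2 contingency table from its cells
#'
#' @param a,b,c,d Non-negative integer cell counts: overlap, A-only, B-only,
#'   neither.
#' @return A `contingency_table` list.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  structure(as.list(cells), class = "contingency_table")
}

#' Exact test of gene-set overlap
#'
#' The association measure is the sample cross-product odds ratio
#' `a*d / (b*c)` (`Inf` when `b*c = 0` with `a*d > 0`); the conditional
#' maximum-likelihood estimate is also available. Significance is the exact
#' hypergeometric probability: two-sided by summation of point masses no
#' larger than the observed one (the usual exact-test convention), or the
#' one-sided upper tail (`alternative = "greater"`, a hypergeometric
#' enrichment test). P-values are computed in log space internally, so
#' magnitudes like 1e-35 are exact rather than underflowed. Degenerate
#' margins give p = 1.
#'
#' @param table A `contingency_table`.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @param or_method `"cross_product"` (default) or `"conditional_mle"`.
#' @return List with `table`, `odds_ratio`, `p_value`, `alternative`.
#' @export
#' @examples
#' tab <- contingency_table(129, 587, 968, 18643)
#' exact_overlap_test(tab)   # OR 4.23, p ~ 7.5e-35
exact_overlap_test <- function(table, alternative = c("two.sided", "greater"),
                               or_method = c("cross_product", "conditional_mle")) {
  stopifnot(inherits(table, "contingency_table"))
  alternative <- match.arg(alternative)
  or_method <- match.arg(or_method)
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  odds_ratio <- if (or_method == "conditional_mle") {
    unname(fisher.test(m)$estimate)
  } else if (b * c == 0) {
    if (a * d > 0) Inf else NaN
  } else {
    (a * d) / (b * c)
  }
  p_value <- if (alternative == "greater") {
    # upper tail of Hypergeometric(|A| successes, |U|-|A| failures, |B| draws)
    phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
  } else {
    fisher.test(m, alternative = "two.sided")$p.value
  }
  list(table = table, odds_ratio = odds_ratio,
       p_value = min(p_value, 1), alternative = alternative)
}

#' Cross-species shared-imprinted-gene counts through ortholog maps
#'
#' For each ordered species pair (focal, other), counts how many of the
#' focal species' imprinted genes have at least one ortholog imprinted in
#' the other species. Counting is in the focal species' gene namespace: a
#' focal gene counts once per species pair regardless of how many of its
#' orthologs are imprinted there. Pairs without an ortholog map are reported
#' as not assessable (`NA`), never as zero.
#'
#' @param imprinted_lists Named list of character vectors: imprinted gene
#'   ids per species, in each species' own namespace.
#' @param ortholog_maps Named list of two-column data frames mapping gene
#'   ids between a species pair; names are `"spA:spB"` with column 1 in
#'   spA's namespace and column 2 in spB's. A map is used in either
#'   orientation.
#' @return List with `overlap_matrix` (focal species in rows), per-species
#'   `shared_with_any` (focal genes imprinted in >= 1 assessable other
#'   species), `mean_pairwise_overlap` (mean of assessable off-diagonal
#'   counts) and `not_assessable` (character vector of "focal:other" pairs
#'   lacking a map).
#' @export
pairwise_species_overlap <- function(imprinted_lists, ortholog_maps) {
  stopifnot(is.list(imprinted_lists), !is.null(names(imprinted_lists)))
  species <- names(imprinted_lists)
  n <- length(species)
  mat <- matrix(NA_real_, n, n, dimnames = list(focal = species, other = species))
  shared_any <- setNames(integer(n), species)
  not_assessable <- character(0)

  orthologs_of <- function(focal, other, genes) {
    key_fo <- paste0(focal, ":", other)
    key_of <- paste0(other, ":", focal)
    if (key_fo %in% names(ortholog_maps)) {
      map <- ortholog_maps[[key_fo]]
      split(map[[2]], map[[1]])[as.character(genes)]
    } else if (key_of %in% names(ortholog_maps)) {
      map <- ortholog_maps[[key_of]]
      split(map[[1]], map[[2]])[as.character(genes)]
    } else {
      NULL
    }
  }

  for (f in species) {
    focal_genes <- unique(imprinted_lists[[f]])
    shared_genes <- character(0)
    for (o in setdiff(species, f)) {
      orth <- orthologs_of(f, o, focal_genes)
      if (is.null(orth)) {
        not_assessable <- c(not_assessable, paste0(f, ":", o))
        next
      }
      hit <- vapply(orth, function(g) {
        !is.null(g) && length(intersect(g, imprinted_lists[[o]])) > 0
      }, logical(1))
      mat[f, o] <- sum(hit)
      shared_genes <- union(shared_genes, focal_genes[hit])
    }
    mat[f, f] <- length(focal_genes)
    shared_any[[f]] <- length(shared_genes)
  }
  off_diag <- mat[row(mat) != col(mat)]
  list(overlap_matrix = mat,
       shared_with_any = shared_any,
       mean_pairwise_overlap = if (all(is.na(off_diag))) NA_real_ else
         mean(off_diag, na.rm = TRUE),
       not_assessable = not_assessable)
}
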