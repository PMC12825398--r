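# Chi-squared departure testing, FDR adjustment and reciprocal-threshold
# MEG/PEG calling.

#' Imprinting caller configuration
#'
#' Reciprocal maternal-proportion thresholds and significance settings used
#' to call imprinted genes. Defaults: moderate MEGs > 0.75 and strong
#' MEGs > 0.9 maternal proportion, moderate PEGs < 0.25 and strong
#' PEGs < 0.1, all required in both directions of the cross; thresholds are
#' symmetric around the null expectation of 0.5 for a diploid (1m:1p)
#' endosperm. For a typical triploid (2m:1p) endosperm, set
#' `null_maternal_proportion = 2/3` (and thresholds to taste).
#'
#' @param meg_moderate,meg_strong Lower theta bounds (exclusive) for moderate
#'   and strong MEGs. Defaults 0.75, 0.9.
#' @param peg_moderate,peg_strong Upper theta bounds (exclusive) for moderate
#'   and strong PEGs. Defaults 0.25, 0.1.
#' @param q_cut FDR level for the chi-squared departure test. Default 0.05.
#' @param null_maternal_proportion Expected theta under biparental
#'   expression. Default 0.5 (diploid endosperm).
#' @param require_significance If `TRUE` (default) a MEG/PEG call also
#'   requires `q <= q_cut`; if `FALSE`, calling is thresholds-only.
#' @return A `caller_config` list.
#' @export
caller_config <- function(meg_moderate = 0.75, meg_strong = 0.9,
                          peg_moderate = 0.25, peg_strong = 0.1,
                          q_cut = 0.05, null_maternal_proportion = 0.5,
                          require_significance = TRUE) {
  ok <- 0 <= peg_strong && peg_strong < peg_moderate &&
    peg_moderate < null_maternal_proportion &&
    null_maternal_proportion < meg_moderate &&
    meg_moderate < meg_strong && meg_strong <= 1
  if (!ok) {
    stop("thresholds must satisfy 0 <= peg_strong < peg_moderate < null < ",
         "meg_moderate < meg_strong <= 1")
  }
  stopifnot(q_cut > 0, q_cut <= 1, is.logical(require_significance))
  structure(list(meg_moderate = meg_moderate, meg_strong = meg_strong,
                 peg_moderate = peg_moderate, peg_strong = peg_strong,
                 q_cut = q_cut,
                 null_maternal_proportion = null_maternal_proportion,
                 require_significance = require_significance),
            class = "caller_config")
}

#' Chi-squared goodness-of-fit test of an allelic ratio
#'
#' One-degree-of-freedom test of observed maternal/paternal read counts
#' `(M, P)` against the expectation `(n * theta0, n * (1 - theta0))` under
#' biparental expression, with `n = M + P`. The statistic is the closed form
#' `(M - n*theta0)^2 / (n*theta0) + (P - n*(1-theta0))^2 / (n*(1-theta0))`
#' and the p-value comes from the upper tail of the chi-squared distribution
#' with 1 df. Vectorised over `M` and `P`.
#'
#' @param M,P Maternal and paternal read-equivalent counts (each site or gene).
#' @param null_theta Expected maternal proportion under the null. Default 0.5.
#' @return Tibble with `chi2` and `p_value`.
#' @export
#' @examples
#' chi_squared_departure(75, 25)         # chi2 = 25
#' chi_squared_departure(10, 20, 2/3)    # chi2 = 15, triploid null
chi_squared_departure <- function(M, P, null_theta = 0.5) {
  stopifnot(length(M) == length(P), null_theta > 0, null_theta < 1)
  n <- M + P
  if (any(n <= 0)) stop("chi-squared departure needs M + P > 0")
  exp_m <- n * null_theta
  exp_p <- n * (1 - null_theta)
  chi2 <- (M - exp_m)^2 / exp_m + (P - exp_p)^2 / exp_p
  tibble::tibble(chi2 = chi2, p_value = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjusted p-values (monotone non-decreasing in p, capped
#' at 1; ties share the rank-minimum).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order as the input.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must all lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Reciprocal-threshold imprinting status
#'
#' A gene is called a MEG when its maternal proportion exceeds the MEG
#' threshold in BOTH directions of the cross (strict inequality; a theta of
#' exactly 0.75 is not a MEG), and a PEG symmetrically below the PEG
#' threshold in both directions. The strongest satisfied class is reported
#' (strong subsumes moderate). With `require_significance`, any MEG/PEG call
#' additionally needs `q <= q_cut`, otherwise the gene is `biparental`.
#' Vectorised; `NA` theta in either direction yields `undetermined`.
#'
#' @param theta_dir1,theta_dir2 Maternal proportions in the two directions.
#' @param q_value FDR-adjusted p of the pooled departure test (recycled).
#' @param cfg A [caller_config()].
#' @return Character vector of statuses.
#' @export
#' @examples
#' call_status(0.95, 0.92, 1e-6)   # MEG_strong
#' call_status(0.80, 0.70, 1e-4)   # biparental: fails the both-directions rule
call_status <- function(theta_dir1, theta_dir2, q_value,
                        cfg = caller_config()) {
  stopifnot(inherits(cfg, "caller_config"))
  n <- max(length(theta_dir1), length(theta_dir2))
  t1 <- rep_len(theta_dir1, n)
  t2 <- rep_len(theta_dir2, n)
  q <- rep_len(q_value, n)
  status <- rep("biparental", n)
  status[t1 > cfg$meg_moderate & t2 > cfg$meg_moderate] <- "MEG_moderate"
  status[t1 > cfg$meg_strong & t2 > cfg$meg_strong] <- "MEG_strong"
  status[t1 < cfg$peg_moderate & t2 < cfg$peg_moderate] <- "PEG_moderate"
  status[t1 < cfg$peg_strong & t2 < cfg$peg_strong] <- "PEG_strong"
  if (cfg$require_significance) {
    status[status != "biparental" & (is.na(q) | q > cfg$q_cut)] <- "biparental"
  }
  status[is.na(t1) | is.na(t2)] <- "undetermined"
  status
}

#' Call the imprintome from per-gene maternal proportions
#'
#' Combines the two cross directions per gene: counts are pooled across
#' directions for one chi-squared departure test per gene, q-values come
#' from Benjamini-Hochberg adjustment over all genes estimable in both
#' directions, and the reciprocal threshold rule of [call_status()] is
#' applied per direction. Genes estimable in only one (or neither) direction
#' are reported as `undetermined` and excluded from testing.
#'
#' @param gene_ase Output of [gene_maternal_proportion()], covering exactly
#'   two directions.
#' @param cfg A [caller_config()].
#' @param directions Optional length-2 character vector fixing which
#'   direction is reported as `theta_dir1` vs `theta_dir2`; defaults to the
#'   sorted unique direction ids.
#' @return Imprintome tibble: `gene_id`, `theta_dir1`, `theta_dir2`,
#'   `M_pooled`, `P_pooled`, `chi2`, `p_value`, `q_value`, `status`, with a
#'   `directions` attribute naming the two directions.
#' @export
call_imprinting <- function(gene_ase, cfg = caller_config(), directions = NULL) {
  stopifnot(inherits(cfg, "caller_config"))
  if (is.null(directions)) directions <- sort(unique(gene_ase$direction_id))
  if (length(directions) != 2) {
    stop("imprinting calling needs exactly two cross directions; got: ",
         paste(directions, collapse = ", "))
  }
  g1 <- gene_ase[gene_ase$direction_id == directions[1], ]
  g2 <- gene_ase[gene_ase$direction_id == directions[2], ]
  wide <- dplyr::full_join(
    g1[, c("gene_id", "M", "P", "theta", "estimable")],
    g2[, c("gene_id", "M", "P", "theta", "estimable")],
    by = "gene_id", suffix = c("_1", "_2"))
  wide$estimable_1 <- dplyr::coalesce(wide$estimable_1, FALSE)
  wide$estimable_2 <- dplyr::coalesce(wide$estimable_2, FALSE)
  both <- wide$estimable_1 & wide$estimable_2

  out <- tibble::tibble(
    gene_id = wide$gene_id,
    theta_dir1 = ifelse(wide$estimable_1, wide$theta_1, NA_real_),
    theta_dir2 = ifelse(wide$estimable_2, wide$theta_2, NA_real_),
    M_pooled = dplyr::coalesce(wide$M_1, 0) + dplyr::coalesce(wide$M_2, 0),
    P_pooled = dplyr::coalesce(wide$P_1, 0) + dplyr::coalesce(wide$P_2, 0),
    chi2 = NA_real_, p_value = NA_real_, q_value = NA_real_,
    status = "undetermined")
  if (any(both)) {
    test <- chi_squared_departure(out$M_pooled[both], out$P_pooled[both],
                                  cfg$null_maternal_proportion)
    out$chi2[both] <- test$chi2
    out$p_value[both] <- test$p_value
    out$q_value[both] <- benjamini_hochberg(test$p_value)
    out$status[both] <- call_status(out$theta_dir1[both], out$theta_dir2[both],
                                    out$q_value[both], cfg)
  }
  out <- dplyr::arrange(out, .data$gene_id)
  attr(out, "directions") <- directions
  out
}

#' Summarise an imprintome table
#'
#' Class counts (MEG/PEG totals add strong and moderate members), the number
#' of genes assayable in both directions, and the mean maternal proportion
#' per direction over assayable genes.
#'
#' @param imprintome Output of [call_imprinting()].
#' @return List with `status_counts` (named integer vector over the six
#'   statuses), `n_genes`, `n_assayable`, `meg_total`, `peg_total`,
#'   `imprinted_total`, `mean_theta_dir1`, `mean_theta_dir2` and
#'   `directions`.
#' @export
summarize_imprintome <- function(imprintome) {
  counts <- table(factor(imprintome$status, levels = IMPRINT_STATUSES))
  counts <- setNames(as.integer(counts), IMPRINT_STATUSES)
  assayable <- !is.na(imprintome$theta_dir1) & !is.na(imprintome$theta_dir2)
  list(
    status_counts = counts,
    n_genes = nrow(imprintome),
    n_assayable = sum(assayable),
    meg_total = counts[["MEG_strong"]] + counts[["MEG_moderate"]],
    peg_total = counts[["PEG_strong"]] + counts[["PEG_moderate"]],
    imprinted_total = counts[["MEG_strong"]] + counts[["MEG_moderate"]] +
      counts[["PEG_strong"]] + counts[["PEG_moderate"]],
    mean_theta_dir1 = if (any(assayable)) mean(imprintome$theta_dir1[assayable]) else NA_real_,
    mean_theta_dir2 = if (any(assayable)) mean(imprintome$theta_dir2[assayable]) else NA_real_,
    directions = attr(imprintome, "directions")
  )
}
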