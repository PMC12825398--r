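# Independent oracles and small fixture builders used across the suite.

# Literal Benjamini-Hochberg step-up procedure: sort, scale by m/rank, take
# the running minimum from the largest p down, map back, cap at 1.
bh_step_up_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- numeric(m)
  running <- 1
  for (j in rev(seq_len(m))) {
    running <- min(running, scaled[j])
    adj[j] <- running
  }
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Brute-force exact test by enumerating every 2x2 table with the observed
# margins; point masses from binomial coefficients (exact for |U| <= 200).
hypergeom_enum_oracle <- function(a, b, c, d, alternative = "two.sided") {
  k <- a + c            # draws (size of set B)
  w <- a + b            # white balls (size of set A)
  n_total <- a + b + c + d
  lo <- max(0, k - (n_total - w))
  hi <- min(w, k)
  xs <- lo:hi
  mass <- choose(w, xs) * choose(n_total - w, k - xs) / choose(n_total, k)
  obs <- mass[xs == a]
  if (alternative == "greater") {
    sum(mass[xs >= a])
  } else {
    sum(mass[mass <= obs * (1 + 1e-7)])
  }
}

# Pooled-seed transmission enumeration for a heterozygous parent: the parent
# transmits its two alleles to equal halves of the pooled seeds; in the half
# receiving the parent-specific allele that allele makes up the parent's
# expression share, in the other half it is absent.
transmission_freq_oracle <- function(parent_share) {
  states <- c(parent_share, 0)
  mean(states)
}

# Closed-form 1-df goodness-of-fit statistic.
chi2_closed_form <- function(M, P, theta0 = 0.5) {
  n <- M + P
  (M - n * theta0)^2 / (n * theta0) + (P - n * (1 - theta0))^2 / (n * (1 - theta0))
}

# Minimal two-sample VCF writer for parser tests.
write_mini_vcf <- function(body_lines, samples = c("P1", "P2"),
                           path = tempfile(fileext = ".vcf"),
                           format_fields = "GT") {
  fmt_defs <- c(
    GT = "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    AD = "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">")
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##contig=<ID=chr2>",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    unname(fmt_defs[format_fields]),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, body_lines), path)
  path
}

# Hand-built site table in the schema of parse_parental_genotypes().
make_sites <- function(pos, gt_P1, gt_P2, ref = "A", alt = "G",
                       gene_id = NA_character_, chrom = "chr1",
                       qual = 50, depth = 40, pass = TRUE) {
  n <- length(pos)
  tibble::tibble(chrom = rep_len(chrom, n), pos = pos,
                 ref = rep_len(ref, n), alt = rep_len(alt, n),
                 qual = rep_len(qual, n), depth = rep_len(depth, n),
                 gt_P1 = gt_P1, gt_P2 = gt_P2,
                 pass = rep_len(pass, n),
                 category_dir1 = classify_site(gt_P1, gt_P2),
                 category_dir2 = classify_site(gt_P2, gt_P1),
                 gene_id = rep_len(gene_id, n))
}

# Merged-count rows matching make_sites() keys.
make_merged <- function(direction_id, pos, count_ref, count_alt,
                        chrom = "chr1") {
  tibble::tibble(direction_id = direction_id, chrom = rep_len(chrom, length(pos)),
                 pos = pos, count_ref = count_ref, count_alt = count_alt,
                 n_libraries = 1L, total = count_ref + count_alt)
}

# Two-direction design over plants P1/P2 with one library each.
tiny_design <- function() {
  reciprocal_design("P1", "P2", "P1xP2_rep1", "P2xP1_rep1")
}
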