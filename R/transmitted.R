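#' Expected rare-allele count for a gene under the length-proportional null
#'
#' Under the null, rare damaging alleles land in genes in proportion to
#' coding length; the expectation for a gene is the cohort-wide allele total
#' times the gene's fraction of the coding exome.
#'
#' @param gene gene symbol (must appear in `lengths`).
#' @param lengths a `"gene_length_table"`.
#' @param total_alleles total rare alleles of the class observed in cases.
#' @return Expected allele count (real).
#' @export
expected_gene_count <- function(gene, lengths, total_alleles) {
  if (total_alleles < 0) stop("expected_gene_count: total_alleles must be >= 0")
  i <- match(gene, lengths$gene)
  if (is.na(i)) stop("expected_gene_count: unknown gene '", gene, "'")
  total_alleles * lengths$coding_bp[i] / sum(lengths$coding_bp)
}

#' Exact binomial burden test for one gene
#'
#' Upper-tail exact binomial probability that a gene receives `observed` or
#' more of the cohort's `total_alleles` rare alleles when each allele hits
#' the gene with probability `gene_fraction` (its share of the coding
#' exome). Enrichment is observed over expected
#' (\eqn{n \cdot p}).
#'
#' @param observed rare alleles observed in the gene.
#' @param total_alleles cohort-wide rare allele total (binomial n).
#' @param gene_fraction the gene's coding fraction of the exome (binomial p).
#' @param label optional gene label.
#' @return A `"burden_test"` object (upper tail).
#' @export
binomial_burden_test <- function(observed, total_alleles, gene_fraction,
                                 label = NA_character_) {
  if (gene_fraction < 0 || gene_fraction > 1)
    stop("binomial_burden_test: gene_fraction must lie in [0, 1]")
  if (observed > total_alleles)
    stop("binomial_burden_test: observed exceeds total_alleles")
  if (observed < 0 || observed != round(observed))
    stop("binomial_burden_test: observed must be a non-negative integer")
  expected <- total_alleles * gene_fraction
  p <- if (observed == 0) 1
       else stats::pbinom(observed - 1, total_alleles, gene_fraction,
                          lower.tail = FALSE)
  burden_result(label = label, observed = observed, expected = expected,
                enrichment = if (expected > 0) observed / expected else NA_real_,
                p.value = p, tail = "upper",
                method = "Exact binomial gene burden test")
}

#' Quantile-quantile points for per-gene burden p-values
#'
#' Pairs the ordered observed p-values with uniform order-statistic
#' expectations on the -log10 scale; the i-th expected quantile is
#' \eqn{(i - 0.5)/m}.
#'
#' @param per_gene_p named numeric vector of per-gene p-values.
#' @return Data frame with columns `gene`, `observed_p`, `expected`
#'   and `observed` (-log10 expected / observed p), ordered by increasing
#'   observed p.
#' @export
qq_points <- function(per_gene_p) {
  p <- as.numeric(per_gene_p)
  if (!length(p)) stop("qq_points: need at least one gene")
  ord <- order(p)
  m <- length(p)
  data.frame(gene = if (is.null(names(per_gene_p))) as.character(ord)
                    else names(per_gene_p)[ord],
             observed_p = p[ord],
             expected = -log10((seq_len(m) - 0.5) / m),
             observed = -log10(p[ord]),
             stringsAsFactors = FALSE)
}

#' Case-control carrier burden by Fisher's exact test
#'
#' Two-sided Fisher exact test on the 2x2 table of variant carriers versus
#' non-carriers in cases and controls (two-sidedness by summing all tables
#' with point probability at most that observed). The odds ratio is the
#' sample cross-product; when a cell is zero the Haldane-Anscombe 0.5
#' correction is applied and flagged.
#'
#' @param case_carriers,case_n carriers and total among cases.
#' @param control_carriers,control_n carriers and total among controls.
#' @return List with `odds_ratio`, `p.value`, `table` and `haldane`
#'   (logical; TRUE when the 0.5 correction was used).
#' @export
case_control_fisher <- function(case_carriers, case_n, control_carriers, control_n) {
  if (case_carriers > case_n || control_carriers > control_n)
    stop("case_control_fisher: carriers exceed group size")
  tab <- matrix(c(case_carriers, case_n - case_carriers,
                  control_carriers, control_n - control_carriers),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("case", "control"), c("carrier", "noncarrier")))
  p <- stats::fisher.test(tab)$p.value
  haldane <- any(tab == 0)
  t2 <- if (haldane) tab + 0.5 else tab
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  list(odds_ratio = or, p.value = p, table = tab, haldane = haldane)
}

#' Combine de novo and transmitted burden evidence
#'
#' Fisher's-method combination (chi-square with 4 df) of the de novo and
#' transmitted burden p-values for one gene.
#'
#' @param p_denovo,p_transmitted the two component p-values.
#' @return Combined p-value.
#' @export
combine_denovo_transmitted <- function(p_denovo, p_transmitted) {
  fishers_method(c(p_denovo, p_transmitted))
}

#' Per-gene binomial burden scan
#'
#' Runs [binomial_burden_test()] for every gene in a length table against
#' observed per-gene allele counts (genes without observations count 0),
#' optionally excluding listed genes (e.g. capture-mask exclusions).
#'
#' @param counts named integer vector of observed rare alleles per gene.
#' @param lengths a `"gene_length_table"`.
#' @param total_alleles cohort-wide total (default `sum(counts)`).
#' @param exclude character vector of genes to drop from the scan.
#' @return Data frame: `gene`, `observed`, `expected`, `enrichment`, `p.value`.
#' @export
burden_scan <- function(counts, lengths, total_alleles = sum(counts),
                        exclude = character()) {
  lengths <- lengths[!lengths$gene %in% exclude, , drop = FALSE]
  frac <- lengths$coding_bp / sum(lengths$coding_bp)
  obs <- counts[match(lengths$gene, names(counts))]
  obs[is.na(obs)] <- 0L
  res <- lapply(seq_along(frac), function(i)
    binomial_burden_test(obs[i], total_alleles, frac[i], label = lengths$gene[i]))
  data.frame(gene = lengths$gene,
             observed = as.integer(obs),
             expected = vapply(res, `[[`, numeric(1), "expected"),
             enrichment = vapply(res, `[[`, numeric(1), "enrichment"),
             p.value = vapply(res, `[[`, numeric(1), "p.value"),
             stringsAsFactors = FALSE)
}
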