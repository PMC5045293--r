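## deterministic substream seed: one root seed fans out to named streams so
## pedigrees / variants / transmissions can be regenerated independently
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

#' Synthetic per-gene de novo mutation-rate table
#'
#' Builds a rate table whose class totals match study-scale expectations for
#' a trio exome cohort (defaults: 12.7 LOF, 89.7 missense, 40.4 synonymous
#' de novo mutations expected in 132 trios), distributing the totals over
#' genes with gamma-distributed relative mutabilities.
#'
#' @param n_genes number of genes.
#' @param cohort_size number of trios the lambdas refer to.
#' @param total_lof,total_mis,total_syn cohort-wide expected counts per class.
#' @param seed integer seed (mandatory; the table is deterministic given it).
#' @return A `"rate_table"`.
#' @export
synthetic_rate_table <- function(n_genes = 500, cohort_size = 132,
                                 total_lof = 12.7, total_mis = 89.7,
                                 total_syn = 40.4, seed) {
  set.seed(substream_seed(seed, "rate_table"))
  w <- stats::rgamma(n_genes, shape = 1.2)   # long-tailed gene mutabilities
  w <- w / sum(w)
  rate_table(data.frame(gene = sprintf("GENE%04d", seq_len(n_genes)),
                        lambda_lof = total_lof * w,
                        lambda_mis = total_mis * w,
                        lambda_syn = total_syn * w,
                        stringsAsFactors = FALSE),
             cohort_size = cohort_size)
}

#' Synthetic per-gene coding-length table
#'
#' Gamma-distributed coding lengths (mean ~1.7 kb) over the same gene
#' symbols used by [synthetic_rate_table()].
#'
#' @param n_genes number of genes.
#' @param seed integer seed.
#' @return A `"gene_length_table"`.
#' @export
synthetic_gene_lengths <- function(n_genes = 500, seed) {
  set.seed(substream_seed(seed, "gene_lengths"))
  bp <- pmax(150L, as.integer(round(stats::rgamma(n_genes, shape = 2, scale = 850))))
  gene_length_table(data.frame(gene = sprintf("GENE%04d", seq_len(n_genes)),
                               coding_bp = bp, stringsAsFactors = FALSE))
}

#' Simulate a de novo variant table for a trio cohort
#'
#' Cohort-wide de novo counts per gene and class are Poisson with the rate
#' table's lambdas (so per-trio totals are Poisson with mean
#' \eqn{\sum\lambda / n}); missense events are split into damaging and
#' tolerated calls; events land in trios uniformly. An optional spike gene
#' receives extra damaging events, emulating a true disease gene.
#'
#' @param n_trios number of trios.
#' @param rates a `"rate_table"` (lambdas for this cohort size).
#' @param dmis_fraction fraction of missense de novo events called damaging
#'   under the null (default 0.162, the study-scale expected D-mis share of
#'   all missense).
#' @param spike optional list `(gene, extra_lof, extra_dmis)` of additional
#'   expected damaging de novo counts for one gene.
#' @param seed integer seed (mandatory).
#' @return List: `variants` (a `"variant_table"` of de novo calls), `rates`
#'   (the null rate table), `n_trios`.
#' @export
simulate_denovo_cohort <- function(n_trios, rates, dmis_fraction = 0.162,
                                   spike = NULL, seed) {
  set.seed(substream_seed(seed, "denovo"))
  lam <- as.matrix(rates[, c("lambda_lof", "lambda_mis", "lambda_syn")])
  if (!is.na(attr(rates, "cohort_size")) && attr(rates, "cohort_size") != n_trios)
    lam <- lam * n_trios / attr(rates, "cohort_size")
  counts <- matrix(stats::rpois(length(lam), lam), ncol = 3,
                   dimnames = list(NULL, c("lof", "mis", "syn")))
  rows <- list()
  emit <- function(gene, consequence, call, n) {
    if (n <= 0) return(NULL)
    data.frame(sample_id = sprintf("trio%04d", sample.int(n_trios, n, replace = TRUE)),
               gene = gene,
               consequence = consequence,
               damaging_call = call,
               damaging_score = NA_real_,
               pop_af = 0,
               origin = "de_novo",
               zygosity = "het",
               stringsAsFactors = FALSE)
  }
  lof_types <- c("nonsense", "frameshift", "splice_site")
  for (g in seq_len(nrow(rates))) {
    gene <- rates$gene[g]
    if (counts[g, "lof"] > 0)
      rows[[length(rows) + 1L]] <-
        emit(gene, sample(lof_types, counts[g, "lof"], replace = TRUE),
             NA_character_, counts[g, "lof"])
    if (counts[g, "mis"] > 0) {
      nd <- stats::rbinom(1, counts[g, "mis"], dmis_fraction)
      calls <- sample(c(rep("D", nd), rep("T", counts[g, "mis"] - nd)))
      rows[[length(rows) + 1L]] <- emit(gene, "missense", calls, counts[g, "mis"])
    }
    if (counts[g, "syn"] > 0)
      rows[[length(rows) + 1L]] <- emit(gene, "synonymous", NA_character_,
                                        counts[g, "syn"])
  }
  if (!is.null(spike)) {
    n_lof <- stats::rpois(1, spike$extra_lof %||% 0)
    n_dmis <- stats::rpois(1, spike$extra_dmis %||% 0)
    if (n_lof > 0)
      rows[[length(rows) + 1L]] <-
        emit(spike$gene, sample(lof_types, n_lof, replace = TRUE), NA_character_, n_lof)
    if (n_dmis > 0)
      rows[[length(rows) + 1L]] <- emit(spike$gene, "missense", "D", n_dmis)
  }
  variants <- if (length(rows)) do.call(rbind, rows)
              else emit("none", "synonymous", NA_character_, 0)
  if (is.null(variants))
    variants <- data.frame(sample_id = character(), gene = character(),
                           consequence = character(), damaging_call = character(),
                           damaging_score = numeric(), pop_af = numeric(),
                           origin = character(), zygosity = character(),
                           stringsAsFactors = FALSE)
  list(variants = variant_table(variants), rates = rates, n_trios = n_trios)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate per-gene transmitted rare-allele counts
#'
#' Throws `n_alleles` rare alleles at genes with probability proportional to
#' coding length (the null of the binomial burden test), optionally adding a
#' fixed spike of extra alleles in one gene.
#'
#' @param n_alleles total rare alleles in the cohort.
#' @param lengths a `"gene_length_table"`.
#' @param spike_gene,spike_count optional gene receiving `spike_count` extra
#'   alleles.
#' @param seed integer seed.
#' @return Named integer vector of per-gene counts.
#' @export
simulate_transmitted_alleles <- function(n_alleles, lengths, spike_gene = NULL,
                                         spike_count = 0, seed) {
  set.seed(substream_seed(seed, "transmitted"))
  pr <- lengths$coding_bp / sum(lengths$coding_bp)
  counts <- as.vector(stats::rmultinom(1, n_alleles, pr))
  names(counts) <- lengths$gene
  if (!is.null(spike_gene)) counts[spike_gene] <- counts[spike_gene] + spike_count
  counts
}

.ped_template <- function(kind, fam) {
  base <- function(id, father, mother, sex, proband)
    data.frame(fam = fam, id = id, father = father, mother = mother, sex = sex,
               affected = FALSE, proband = proband, smad6 = NA_character_,
               bmp2 = NA_integer_, stringsAsFactors = FALSE)
  switch(kind,
    trio = base(c("fa", "mo", "ch1"), c(NA, NA, "fa"), c(NA, NA, "mo"),
                c(1L, 2L, 1L), c(FALSE, FALSE, TRUE)),
    quartet = base(c("fa", "mo", "ch1", "ch2"), c(NA, NA, "fa", "fa"),
                   c(NA, NA, "mo", "mo"), c(1L, 2L, 1L, 2L),
                   c(FALSE, FALSE, TRUE, FALSE)),
    threegen = base(c("gf", "gm", "fa", "mo", "ch1", "ch2"),
                    c(NA, NA, "gf", NA, "fa", "fa"),
                    c(NA, NA, "gm", NA, "mo", "mo"),
                    c(1L, 2L, 1L, 2L, 2L, 1L),
                    c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)),
    multiplex = base(c("gf", "gm", "fa", "mo", "ch1", "ch2", "ch3", "ch4"),
                     c(NA, NA, "gf", NA, "fa", "fa", "fa", "fa"),
                     c(NA, NA, "gm", NA, "mo", "mo", "mo", "mo"),
                     c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L),
                     c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)),
    stop("unknown template '", kind, "'"))
}

## founder who seeds the rare damaging allele in each template
.carrier_founder <- c(trio = "fa", quartet = "fa", threegen = "gf",
                      multiplex = "gf")

#' Simulate two-locus pedigrees under a penetrance model
#'
#' Founders draw SNP genotypes from Hardy-Weinberg proportions at the risk
#' allele frequency `model$q_B` and rare-allele carrier states from
#' `model$q_S` (or are seeded as carriers when `seed_carrier`, emulating
#' kindreds ascertained to segregate the rare allele). Alleles drop through
#' the pedigree by Mendelian transmission; affection is sampled from the
#' genotype-specific penetrance. Ascertainment retains only families whose
#' proband meets the rule, by rejection sampling with an iteration cap.
#'
#' @param n_families number of kindreds to generate.
#' @param model a [two_locus_model()] (defaults to the maximum-likelihood
#'   craniosynostosis model).
#' @param templates pedigree structure kinds cycled over families: any of
#'   `"trio"` (3 members), `"quartet"` (4), `"threegen"` (6) or
#'   `"multiplex"` (8, three generations with four grandchildren). The
#'   default mix reproduces the composition of the published 13-kindred
#'   panel (about 30 rare-allele carriers and 50 classified members per
#'   panel of 13).
#' @param seed_carrier force one founder per kindred to carry the rare
#'   damaging allele (default TRUE).
#' @param ascertain `"affected_carrier"` (proband affected and a carrier —
#'   kindreds enter the study through a diagnosed carrier proband),
#'   `"affected"` (proband affected), or `"none"`.
#' @param max_tries rejection-sampling cap per family.
#' @param seed integer seed (mandatory for reproducibility).
#' @return List of `"pedigree"` objects.
#' @export
simulate_pedigrees <- function(n_families = 13, model = two_locus_model(),
                               templates = c("quartet", "threegen", "multiplex"),
                               seed_carrier = TRUE,
                               ascertain = c("affected_carrier", "affected", "none"),
                               max_tries = 10000, seed = NULL) {
  ascertain <- match.arg(ascertain)
  if (!is.null(seed)) set.seed(substream_seed(seed, "pedigrees"))
  hwe <- c((1 - model$q_B)^2, 2 * model$q_B * (1 - model$q_B), model$q_B^2)
  out <- vector("list", n_families)
  for (k in seq_len(n_families)) {
    kind <- templates[((k - 1L) %% length(templates)) + 1L]
    skel <- .ped_template(kind, sprintf("K%03d", k))
    drawn <- NULL
    for (try in seq_len(max_tries)) {
      p <- skel
      fo <- is_founder(p)
      p$bmp2[fo] <- sample(0:2, sum(fo), replace = TRUE, prob = hwe)
      carrier <- logical(nrow(p))
      carrier[fo] <- stats::runif(sum(fo)) < model$q_S
      if (seed_carrier) carrier[p$id == .carrier_founder[[kind]]] <- TRUE
      ## drop alleles in pedigree order (templates list parents before children)
      for (i in which(!fo)) {
        fi <- match(p$father[i], p$id); mi <- match(p$mother[i], p$id)
        p$bmp2[i] <- stats::rbinom(1, 1, p$bmp2[fi] / 2) +
                     stats::rbinom(1, 1, p$bmp2[mi] / 2)
        carrier[i] <- (carrier[fi] && stats::runif(1) < 0.5) ||
                      (carrier[mi] && stats::runif(1) < 0.5)
      }
      p$smad6 <- ifelse(carrier, "D", "N")
      p$affected <- stats::runif(nrow(p)) < penetrance_of(carrier, p$bmp2, model)
      pro <- which(p$proband)
      ok <- switch(ascertain,
                   none = TRUE,
                   affected = all(p$affected[pro]),
                   affected_carrier = all(p$affected[pro] & carrier[pro]))
      if (ok) { drawn <- p; break }
    }
    if (is.null(drawn))
      stop("simulate_pedigrees: ascertainment rule '", ascertain,
           "' not met within ", max_tries, " tries for family ", k,
           " (is the model's penetrance compatible with the rule?)")
    out[[k]] <- pedigree(drawn)
  }
  out
}

#' Simulate null transmission counts for the TDT
#'
#' Fair-coin transmissions from heterozygous parents to affected offspring:
#' used to verify the transmission disequilibrium test's type-I error.
#'
#' @param n_transmissions informative transmissions per replicate.
#' @param n_replicates number of replicates.
#' @param seed integer seed.
#' @return Data frame with columns `transmitted`, `untransmitted`, one row
#'   per replicate (zero rows when `n_transmissions` is 0).
#' @export
simulate_null_tdt <- function(n_transmissions, n_replicates = 1, seed) {
  set.seed(substream_seed(seed, "tdt"))
  if (n_transmissions == 0)
    return(data.frame(transmitted = integer(), untransmitted = integer()))
  t <- stats::rbinom(n_replicates, n_transmissions, 0.5)
  data.frame(transmitted = t, untransmitted = n_transmissions - t)
}

#' Extract SNP transmission counts from pedigrees
#'
#' Counts risk-allele transmissions and non-transmissions from heterozygous
#' parents to affected offspring, for the TDT. A transmission is counted
#' only when it is unambiguous from the trio's genotypes (when both parents
#' are heterozygous and the child too, which parent transmitted the risk
#' allele cannot be resolved; such parent-child pairs are skipped).
#'
#' @param peds list of `"pedigree"` objects.
#' @return List with `transmitted`, `untransmitted`, `ambiguous`.
#' @export
extract_tdt_counts <- function(peds) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  t <- u <- amb <- 0L
  for (p in peds) {
    fa <- match(p$father, p$id); mo <- match(p$mother, p$id)
    for (i in seq_len(nrow(p))) {
      if (!p$affected[i] || is.na(fa[i]) || is.na(p$bmp2[i])) next
      for (par in c(fa[i], mo[i])) {
        if (is.na(p$bmp2[par]) || p$bmp2[par] != 1L) next
        other <- if (par == fa[i]) mo[i] else fa[i]
        od <- p$bmp2[other]
        cd <- p$bmp2[i]
        if (is.na(od)) { amb <- amb + 1L; next }
        ## allele contributed by the non-focal parent, when determinate
        from_other <- if (od == 0) 0L else if (od == 2) 1L
                      else if (cd == 0) 0L else if (cd == 2) 1L else NA_integer_
        if (is.na(from_other)) { amb <- amb + 1L; next }
        if (cd - from_other == 1L) t <- t + 1L else u <- u + 1L
      }
    }
  }
  list(transmitted = t, untransmitted = u, ambiguous = amb)
}
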