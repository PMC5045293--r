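#' Poisson burden test for a de novo mutation class
#'
#' Compares the observed number of de novo mutations of a class (all
#' protein-altering, damaging missense, loss-of-function, ...) in a trio
#' cohort to the Poisson expectation built from per-gene mutation rates.
#' When the class is enriched (observed > expected) the p-value is the upper
#' tail \eqn{P(X \ge obs)}; when depleted, the reported lower tail is the
#' complement \eqn{P(X < obs)}, the convention under which the published
#' depletion p-values for synonymous mutations reproduce exactly. Set
#' `lower_tail = "inclusive"` for the conservative \eqn{P(X \le obs)}.
#'
#' @param observed non-negative integer count of de novo mutations.
#' @param expected Poisson expectation (lambda) for the class in the cohort.
#' @param label optional class label carried into the result.
#' @param lower_tail `"exclusive"` (default, \eqn{P(X < obs)}) or
#'   `"inclusive"` (\eqn{P(X \le obs)}) for depleted classes.
#' @return A `"burden_test"` object: `observed`, `expected`, `enrichment`
#'   (observed/expected), `p.value`, `tail` ("upper"/"lower").
#' @export
class_poisson_test <- function(observed, expected, label = NA_character_,
                               lower_tail = c("exclusive", "inclusive")) {
  lower_tail <- match.arg(lower_tail)
  if (!is.finite(observed) || observed < 0 || observed != round(observed))
    stop("class_poisson_test: observed must be a non-negative integer")
  if (!is.finite(expected) || expected < 0)
    stop("class_poisson_test: expected must be non-negative")
  if (expected == 0 && observed > 0)
    stop("class_poisson_test: expected = 0 with observed > 0 (infinite enrichment); ",
         "use gene_poisson_test for boundary flagging")
  if (observed >= expected) {
    tail <- "upper"
    p <- if (expected == 0) 1 else stats::ppois(observed - 1, expected, lower.tail = FALSE)
  } else {
    tail <- "lower"
    p <- if (lower_tail == "exclusive") stats::ppois(observed - 1, expected)
         else stats::ppois(observed, expected)
  }
  burden_result(label = label, observed = observed, expected = expected,
                enrichment = if (expected > 0) observed / expected else NA_real_,
                p.value = p, tail = tail, method = "Poisson class burden test")
}

burden_result <- function(label, observed, expected, enrichment, p.value, tail,
                          method, flags = character()) {
  structure(list(label = label, observed = observed, expected = expected,
                 enrichment = enrichment, p.value = p.value, tail = tail,
                 method = method, flags = flags),
            class = "burden_test")
}

#' @export
print.burden_test <- function(x, ...) {
  cat(x$method, if (!is.na(x$label)) paste0(" [", x$label, "]"), "\n", sep = "")
  cat(sprintf("  observed %s, expected %.4g, enrichment %.3g, %s-tail p = %.3g\n",
              format(x$observed), x$expected,
              if (is.na(x$enrichment)) NA else x$enrichment, x$tail, x$p.value))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Per-gene Poisson test for recurrent de novo mutations
#'
#' Upper-tail Poisson probabilities \eqn{P(X \ge obs \mid \lambda)} of the
#' observed de novo count per mutation class in one gene (or gene set), with
#' lambdas taken from a pre-computed mutation-rate table scaled to the cohort.
#'
#' @param rate one row of a `"rate_table"` (or a list with `gene`,
#'   `lambda_lof`, `lambda_mis`, `lambda_syn`).
#' @param observed_lof,observed_mis,observed_syn observed de novo counts per
#'   class; classes passed as `NULL` are skipped.
#' @return A data frame of per-class results with columns `gene`, `class`,
#'   `observed`, `expected`, `enrichment`, `p.value`, `flag`. An observed
#'   count against lambda = 0 is flagged `"infinite_enrichment"` with a
#'   boundary p of 0.
#' @export
gene_poisson_test <- function(rate, observed_lof = NULL, observed_mis = NULL,
                              observed_syn = NULL) {
  one <- function(class, obs, lam) {
    if (is.null(obs)) return(NULL)
    if (obs < 0 || obs != round(obs)) stop("gene_poisson_test: negative/non-integer count")
    flag <- ""
    if (lam == 0 && obs > 0) {
      p <- 0
      enr <- Inf
      flag <- "infinite_enrichment"
    } else {
      p <- if (obs == 0) 1 else stats::ppois(obs - 1, lam, lower.tail = FALSE)
      enr <- if (lam > 0) obs / lam else NA_real_
    }
    data.frame(gene = rate$gene, class = class, observed = obs, expected = lam,
               enrichment = enr, p.value = p, flag = flag,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one("LOF", observed_lof, rate$lambda_lof),
               one("missense", observed_mis, rate$lambda_mis),
               one("synonymous", observed_syn, rate$lambda_syn))
  if (is.null(out)) stop("gene_poisson_test: no observed counts supplied")
  rownames(out) <- NULL
  out
}

#' Combine independent p-values by Fisher's method
#'
#' \eqn{\chi^2 = -2 \sum \ln p_i} referred to the chi-square distribution
#' with \eqn{2k} degrees of freedom.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return Combined p-value.
#' @export
fishers_method <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (!length(pvals)) stop("fishers_method: empty input")
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("fishers_method: p-values must lie in (0, 1]; a p of exactly 0 is ",
         "undefined under the log transform — use boundary-safe tails upstream")
  stats::pchisq(-2 * sum(log(pvals)), df = 2 * length(pvals), lower.tail = FALSE)
}

#' Permutation test for recurrently hit genes
#'
#' Given `n_hits` de novo mutations of a class observed cohort-wide,
#' estimates the probability that any single gene receives two or more of
#' them under the null in which each hit lands in gene \eqn{g} with
#' probability proportional to that gene's de novo mutation rate. Each
#' iteration resamples all hits and checks for a multiply-hit gene.
#'
#' @param n_hits number of observed mutations of the class.
#' @param gene_probs named numeric vector of per-gene hit probabilities
#'   (normalized internally).
#' @param n_iter Monte Carlo iterations (default 1e6).
#' @param seed integer seed; required for reproducibility.
#' @return Estimated p-value (fraction of iterations with a gene hit twice),
#'   with attributes `n_iter` and `mc_se` (binomial Monte Carlo standard
#'   error).
#' @export
multihit_permutation <- function(n_hits, gene_probs, n_iter = 1e6, seed = NULL) {
  if (n_iter < 1) stop("multihit_permutation: n_iter must be >= 1")
  gene_probs <- as.numeric(gene_probs) / sum(gene_probs)
  if (any(gene_probs < 0)) stop("multihit_permutation: negative probabilities")
  if (n_hits < 2) {
    warning("multihit_permutation: fewer than 2 hits, no gene can be multiply hit")
    return(structure(0, n_iter = n_iter, mc_se = 0))
  }
  if (!is.null(seed)) set.seed(seed)
  ng <- length(gene_probs)
  hits <- 0L
  remaining <- as.integer(n_iter)
  chunk <- max(1L, min(remaining, as.integer(2e6 %/% n_hits)))
  while (remaining > 0L) {
    b <- min(chunk, remaining)
    g <- matrix(sample.int(ng, n_hits * b, replace = TRUE, prob = gene_probs),
                nrow = n_hits)
    dup <- vapply(seq_len(b), function(j) anyDuplicated(g[, j]) > 0L, logical(1))
    hits <- hits + sum(dup)
    remaining <- remaining - b
  }
  p <- hits / n_iter
  structure(p, n_iter = n_iter, mc_se = sqrt(p * (1 - p) / n_iter))
}

#' Fraction of the cohort attributable to de novo mutation
#'
#' The excess of probands carrying protein-altering de novo mutations over
#' chance expectation, as a fraction of all trios: \eqn{(obs - exp)/n},
#' clipped below at 0.
#'
#' @param observed_pa probands with at least one protein-altering de novo
#'   mutation.
#' @param expected_pa expected number of such probands by chance.
#' @param n_trios cohort size.
#' @return Attributable fraction in [0, 1].
#' @export
attributable_fraction <- function(observed_pa, expected_pa, n_trios) {
  if (n_trios <= 0) stop("attributable_fraction: n_trios must be > 0")
  if (observed_pa < 0 || expected_pa < 0) stop("attributable_fraction: negative counts")
  max(0, (observed_pa - expected_pa) / n_trios)
}

#' Per-offspring de novo mutation rate
#'
#' @param n_mutations de novo mutations called cohort-wide.
#' @param n_trios number of parent-offspring trios.
#' @param callable_bp haploid callable coding target size in bp, if known;
#'   enables the per-base-pair rate \eqn{n / (trios \cdot 2 \cdot bp)}.
#' @return List with `per_offspring` and `per_bp` (NULL when `callable_bp`
#'   is not given).
#' @export
per_offspring_rate <- function(n_mutations, n_trios, callable_bp = NULL) {
  if (n_trios <= 0) stop("per_offspring_rate: n_trios must be > 0")
  list(per_offspring = n_mutations / n_trios,
       per_bp = if (is.null(callable_bp)) NULL
                else n_mutations / (n_trios * 2 * callable_bp))
}
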