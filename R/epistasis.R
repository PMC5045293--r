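## log multivariate hypergeometric probability of an r x c table with fixed margins
.log_table_prob <- function(tab) {
  sum(lfactorial(rowSums(tab))) + sum(lfactorial(colSums(tab))) -
    lfactorial(sum(tab)) - sum(lfactorial(tab))
}

## enumerate all r x c tables with the given margins; returns matrix of
## log-probabilities (one per table) via depth-first composition of rows
.enumerate_tables <- function(row_m, col_m) {
  r <- length(row_m)
  out <- list()
  rec <- function(i, col_rem, acc) {
    if (i == r) {
      if (all(col_rem >= 0)) out[[length(out) + 1L]] <<- rbind(acc, col_rem)
      return(invisible())
    }
    compose(row_m[i], col_rem, integer(0), i, col_rem, acc)
  }
  compose <- function(left, col_rem, cells, i, col_rem0, acc) {
    j <- length(cells) + 1L
    if (j == length(col_rem0)) {
      if (left <= col_rem0[j] - 0) {
        row <- c(cells, left)
        rec(i + 1L, col_rem0 - row, rbind(acc, row))
      }
      return(invisible())
    }
    for (v in 0:min(left, col_rem0[j]))
      compose(left - v, col_rem, c(cells, v), i, col_rem0, acc)
  }
  rec(1L, col_m, NULL)
  out
}

#' Freeman-Halton exact test for an r x c contingency table
#'
#' Two-sided exact p-value for independence in an r x c table of counts:
#' the sum of multivariate-hypergeometric probabilities, over all tables
#' with the observed margins, of every table whose probability does not
#' exceed that of the observed table (ties admitted with relative slack
#' 1e-12). This is the extension of Fisher's exact test to tables larger
#' than 2 x 2 and reduces to it there.
#'
#' Full enumeration is used up to a documented bound (total count and table
#' size); beyond it a seeded Monte Carlo version samples margin-fixed tables
#' from the null (Patefield's algorithm).
#'
#' @param table integer matrix of counts, at least 2 x 2 after dropping
#'   all-zero rows/columns.
#' @param method `"auto"` (enumerate within bounds, otherwise error
#'   advising Monte Carlo), `"exact"`, or `"mc"`.
#' @param n_mc Monte Carlo samples for `method = "mc"`.
#' @param seed integer seed for the Monte Carlo path.
#' @param max_total,max_cells enumeration bounds: total count and number of
#'   cells (defaults 60 and 8 — ample for kindred-scale genotype tables).
#' @return List of class `"fh_test"`: `p.value`, `method`, `table`; exact
#'   results carry `total_prob`, the summed probability of all enumerated
#'   tables (a self-check that should be 1 to near machine precision), and
#'   `n_tables`.
#' @export
freeman_halton_exact <- function(table, method = c("auto", "exact", "mc"),
                                 n_mc = 1e5, seed = NULL,
                                 max_total = 60, max_cells = 8) {
  method <- match.arg(method)
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("freeman_halton_exact: counts must be non-negative integers")
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    ## degenerate margins: only one table possible
    return(structure(list(p.value = 1, method = "degenerate", table = tab,
                          total_prob = 1, n_tables = 1L), class = "fh_test"))
  }
  lp_obs <- .log_table_prob(tab)
  tol <- log1p(1e-12)
  within <- sum(tab) <= max_total && length(tab) <= max_cells
  if (method == "auto") {
    if (!within)
      stop("freeman_halton_exact: table exceeds the enumeration bound (N <= ",
           max_total, ", cells <= ", max_cells,
           "); use method = \"mc\" with a seed for a Monte Carlo p-value")
    method <- "exact"
  }
  if (method == "exact") {
    tables <- .enumerate_tables(rowSums(tab), colSums(tab))
    lp <- vapply(tables, .log_table_prob, numeric(1))
    res <- list(p.value = sum(exp(lp[lp <= lp_obs + tol])),
                method = "exact enumeration", table = tab,
                total_prob = sum(exp(lp)), n_tables = length(lp))
  } else {
    if (!is.null(seed)) set.seed(seed)
    sims <- stats::r2dtable(n_mc, rowSums(tab), colSums(tab))
    lp <- vapply(sims, .log_table_prob, numeric(1))
    res <- list(p.value = mean(lp <= lp_obs + tol),
                method = sprintf("Monte Carlo (%d samples)", n_mc),
                table = tab, total_prob = NA_real_, n_tables = n_mc)
  }
  structure(res, class = "fh_test")
}

#' @export
print.fh_test <- function(x, ...) {
  cat("Freeman-Halton exact test (", x$method, ")\n", sep = "")
  print(x$table)
  cat(sprintf("two-sided p = %.4g\n", x$p.value))
  invisible(x)
}

#' Transmission disequilibrium test
#'
#' Tests for distorted transmission of a risk allele from heterozygous
#' parents to affected offspring: under the null each transmission is a fair
#' coin, and \eqn{\chi^2 = (T - U)^2 / (T + U)} is referred to the
#' chi-square distribution with 1 df.
#'
#' @param transmitted,untransmitted counts of risk-allele transmissions and
#'   non-transmissions from heterozygous parents to affected offspring.
#' @return List with `chi2`, `p.value`, `transmitted`, `untransmitted`.
#' @export
tdt <- function(transmitted, untransmitted) {
  if (transmitted < 0 || untransmitted < 0) stop("tdt: negative counts")
  n <- transmitted + untransmitted
  if (n < 1) stop("tdt: need at least one transmission")
  chi2 <- (transmitted - untransmitted)^2 / n
  list(chi2 = chi2, p.value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       transmitted = transmitted, untransmitted = untransmitted)
}

#' Carrier penetrance with optional proband exclusion
#'
#' Fraction of rare-allele carriers who are affected. Because probands are
#' ascertained for disease, the unbiased estimate excludes them from both
#' numerator and denominator.
#'
#' @param n_carriers carriers observed in the kindreds.
#' @param n_affected_carriers of whom affected.
#' @param n_probands probands among the affected carriers.
#' @param exclude_probands drop probands from both counts (default TRUE).
#' @return Penetrance estimate in [0, 1].
#' @export
penetrance_estimate <- function(n_carriers, n_affected_carriers, n_probands,
                                exclude_probands = TRUE) {
  if (n_affected_carriers > n_carriers)
    stop("penetrance_estimate: affected carriers exceed carriers")
  if (n_probands > n_affected_carriers)
    stop("penetrance_estimate: probands must be a subset of affected carriers")
  if (!exclude_probands) return(n_affected_carriers / n_carriers)
  if (n_carriers == n_probands)
    stop("penetrance_estimate: all carriers are probands; the proband-excluded ",
         "estimate is undefined")
  (n_affected_carriers - n_probands) / (n_carriers - n_probands)
}

#' Two-locus genotype class by affection table
#'
#' Tabulates every member of kindreds segregating a rare damaging allele
#' into the three informative two-locus classes — carrier with risk allele
#' (S+B+), carrier without (S+B-), risk allele only (S-B+) — split by
#' affection. Individuals with neither allele are excluded from the table;
#' members with a missing genotype at either locus are counted and reported
#' in the `n_missing` attribute, never silently dropped.
#'
#' @param peds list of `"pedigree"` objects (or a single pedigree). Only
#'   kindreds containing at least one damaging-allele carrier contribute.
#' @return 3 x 2 integer matrix (`affected` / `unaffected` columns) of class
#'   `"two_locus_class_table"`, with attribute `n_missing`.
#' @export
class_risk_table <- function(peds) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  tab <- matrix(0L, nrow = 3, ncol = 2,
                dimnames = list(c("S+B+", "S+B-", "S-B+"),
                                c("affected", "unaffected")))
  n_missing <- 0L
  for (p in peds) {
    if (!any(p$smad6 %in% c("D", "D*"))) next
    for (i in seq_len(nrow(p))) {
      s <- p$smad6[i]; b <- p$bmp2[i]
      if (is.na(s) || is.na(b)) { n_missing <- n_missing + 1L; next }
      carrier <- s %in% c("D", "D*")
      risk <- b >= 1
      row <- if (carrier && risk) 1L else if (carrier) 2L
             else if (risk) 3L else NA_integer_
      if (is.na(row)) next
      col <- if (p$affected[i]) 1L else 2L
      tab[row, col] <- tab[row, col] + 1L
    }
  }
  structure(tab, n_missing = n_missing, class = c("two_locus_class_table", "matrix"))
}

#' @export
print.two_locus_class_table <- function(x, ...) {
  cat("Two-locus class by affection (carrier kindred members):\n")
  print(unclass(structure(x, n_missing = NULL)))
  nm <- attr(x, "n_missing")
  if (nm > 0) cat(nm, "member(s) with missing genotypes not tabulated\n")
  invisible(x)
}
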