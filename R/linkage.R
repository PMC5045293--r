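#' Two-locus penetrance model
#'
#' Parametric penetrance model for digenic inheritance of a rare damaging
#' allele at a haploinsufficient gene together with a common risk SNP:
#' five penetrance classes (both loci; rare allele only; one or two SNP risk
#' alleles only; neither = phenocopy rate), plus founder allele frequencies
#' for the two loci. Recombination between each marker and its trait locus
#' is fixed at zero. Defaults are the maximum-likelihood estimates for
#' midline craniosynostosis: 100% penetrance with risk alleles at both loci,
#' 9% with the rare damaging allele alone, 0.08% / 0.32% with one / two SNP
#' risk alleles alone, 0.02% phenocopy rate, SNP risk-allele frequency 0.34.
#'
#' @param f_both penetrance with the rare allele plus >= 1 SNP risk allele.
#' @param f_S penetrance with the rare damaging allele only.
#' @param f_B1,f_B2 penetrance with one / two SNP risk alleles only.
#' @param f_0 phenocopy rate (neither risk genotype).
#' @param q_B SNP risk-allele frequency in founders.
#' @param q_S rare damaging-allele carrier frequency in founders.
#' @return An object of class `"two_locus_model"`.
#' @export
two_locus_model <- function(f_both = 1.0, f_S = 0.09, f_B1 = 0.0008,
                            f_B2 = 0.0032, f_0 = 0.0002,
                            q_B = 0.34, q_S = 1e-4) {
  f <- c(f_both = f_both, f_S = f_S, f_B1 = f_B1, f_B2 = f_B2, f_0 = f_0)
  if (any(f < 0 | f > 1)) stop("two_locus_model: penetrances must lie in [0, 1]")
  if (q_B <= 0 || q_B >= 1) stop("two_locus_model: q_B must lie in (0, 1)")
  if (q_S <= 0 || q_S >= 1) stop("two_locus_model: q_S must lie in (0, 1)")
  structure(list(f_both = f_both, f_S = f_S, f_B1 = f_B1, f_B2 = f_B2,
                 f_0 = f_0, q_B = q_B, q_S = q_S, theta = 0),
            class = "two_locus_model")
}

#' @export
print.two_locus_model <- function(x, ...) {
  cat("Two-locus penetrance model (theta = 0):\n")
  cat(sprintf("  f(both loci)        = %g\n", x$f_both))
  cat(sprintf("  f(rare allele only) = %g\n", x$f_S))
  cat(sprintf("  f(1 SNP risk)       = %g\n", x$f_B1))
  cat(sprintf("  f(2 SNP risk)       = %g\n", x$f_B2))
  cat(sprintf("  f(neither)          = %g (phenocopy)\n", x$f_0))
  cat(sprintf("  q_B = %g, q_S = %g\n", x$q_B, x$q_S))
  invisible(x)
}

.penvec <- function(m) c(m$f_both, m$f_S, m$f_B1, m$f_B2, m$f_0)

## penetrance class index: 1 S+B+, 2 S+B-, 3 S-B1, 4 S-B2, 5 S-B0
.class_index <- function(carrier, dose) {
  ifelse(carrier, ifelse(dose >= 1, 1L, 2L),
         ifelse(dose == 1, 3L, ifelse(dose == 2, 4L, 5L)))
}

#' Genotype-specific penetrance
#'
#' @param carrier logical: carries the rare damaging allele.
#' @param dose SNP risk-allele dose (0, 1 or 2). Vectorized with `carrier`.
#' @param m a [two_locus_model()].
#' @return Numeric vector of penetrances.
#' @export
penetrance_of <- function(carrier, dose, m) {
  if (any(is.na(carrier)) || any(is.na(dose)) || any(!dose %in% 0:2))
    stop("penetrance_of: need non-missing carrier state and dose in 0:2")
  .penvec(m)[.class_index(carrier, dose)]
}

## SNP transmission: P(child dose | father dose, mother dose)
.snp_trans_prob <- function(child, df, dm) {
  tf <- df / 2; tm <- dm / 2
  switch(as.character(child),
         "0" = (1 - tf) * (1 - tm),
         "1" = tf * (1 - tm) + (1 - tf) * tm,
         "2" = tf * tm,
         stop("invalid dose"))
}

## rare-allele transmission: carriers treated as heterozygous
.smad6_trans_prob <- function(child_code, f_carrier, m_carrier) {
  pc <- 1 - (1 - 0.5 * f_carrier) * (1 - 0.5 * m_carrier)
  if (identical(child_code, "D*")) return(1)   # de novo: uninformative about parents
  if (identical(child_code, "D")) pc else 1 - pc
}

## Reduce a pedigree to sufficient statistics for the penetrance likelihood:
## either per-class affected/unaffected counts (fully genotyped), or a
## mixture over genotype completions of missing founders with
## genotype-only weights (prior x Mendelian transmission), normalized.
.family_summary <- function(ped, q_B, q_S, max_missing = 2) {
  carrier <- ped$smad6 %in% c("D", "D*")
  carrier[is.na(ped$smad6)] <- NA
  miss <- is.na(carrier) | is.na(ped$bmp2)
  count_classes <- function(cl) {
    a <- u <- numeric(5)
    for (k in 1:5) {
      a[k] <- sum(ped$affected & cl == k)
      u[k] <- sum(!ped$affected & cl == k)
    }
    list(a = a, u = u)
  }
  pro_counts <- local({
    i <- which(ped$proband)
    if (!length(i) || any(miss[i])) return(NULL)
    tabulate(.class_index(carrier[i], ped$bmp2[i]), 5)
  })
  if (!any(miss)) {
    cl <- .class_index(carrier, ped$bmp2)
    return(c(list(type = "counts", pro = pro_counts), count_classes(cl)))
  }
  if (any(miss & !is_founder(ped)))
    stop("family likelihood: missing genotypes are marginalized for founders only; ",
         "non-founder '", ped$id[which(miss & !is_founder(ped))[1]], "' is missing")
  widx <- which(miss)
  if (length(widx) > max_missing)
    stop("family likelihood: ", length(widx), " missing founders exceeds max_missing = ",
         max_missing)
  hwe <- c((1 - q_B)^2, 2 * q_B * (1 - q_B), q_B^2)
  states <- expand.grid(carrier = c(TRUE, FALSE), dose = 0:2)
  states$prior <- ifelse(states$carrier, q_S, 1 - q_S) * hwe[states$dose + 1]
  grids <- rep(list(seq_len(nrow(states))), length(widx))
  combos <- as.matrix(expand.grid(grids))
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  w <- numeric(nrow(combos))
  comps <- vector("list", nrow(combos))
  for (j in seq_len(nrow(combos))) {
    car_j <- carrier; dose_j <- ped$bmp2
    st <- combos[j, ]
    car_j[widx] <- states$carrier[st]
    dose_j[widx] <- states$dose[st]
    wt <- prod(states$prior[st])
    for (i in seq_len(nrow(ped))) {
      if (is.na(fa[i])) next
      if (!is.na(ped$bmp2[i]))
        wt <- wt * .snp_trans_prob(ped$bmp2[i], dose_j[fa[i]], dose_j[mo[i]])
      if (!is.na(ped$smad6[i]))
        wt <- wt * .smad6_trans_prob(ped$smad6[i], car_j[fa[i]], car_j[mo[i]])
    }
    w[j] <- wt
    comps[[j]] <- count_classes(.class_index(car_j, dose_j))
  }
  if (sum(w) <= 0)
    stop("family likelihood: no Mendelian-consistent completion of missing ",
         "founder genotypes in kindred '", ped$fam[1], "'")
  keep <- w > 0
  list(type = "mixture", pro = pro_counts, w = w[keep] / sum(w[keep]),
       components = comps[keep])
}

.pen_prod <- function(f, a, u) {
  s <- 0
  ia <- a > 0; iu <- u > 0
  if (any(ia)) s <- s + sum(a[ia] * log(f[ia]))
  if (any(iu)) s <- s + sum(u[iu] * log1p(-f[iu]))
  exp(s)
}

.summary_likelihood <- function(smry, f) {
  if (smry$type == "counts") return(.pen_prod(f, smry$a, smry$u))
  sum(smry$w * vapply(smry$components, function(cc) .pen_prod(f, cc$a, cc$u),
                      numeric(1)))
}

#' Pedigree likelihood under the two-locus penetrance model
#'
#' With fully observed genotypes and zero recombination the likelihood,
#' conditional on the genotypes, is the product over members of
#' \eqn{f(g)} for affected and \eqn{1 - f(g)} for unaffected members.
#' Founders with missing genotypes are marginalized: the likelihood is
#' summed over all genotype completions, weighted by the Hardy-Weinberg
#' SNP genotype prior (from `q_B`), the carrier prior `q_S`, and Mendelian
#' transmission consistency with the observed offspring genotypes.
#'
#' @param ped a `"pedigree"`.
#' @param m a [two_locus_model()].
#' @param max_missing maximum number of genotype-missing founders to
#'   marginalize (default 2).
#' @return Likelihood (real in [0, 1]).
#' @export
family_likelihood <- function(ped, m, max_missing = 2) {
  smry <- .family_summary(ped, m$q_B, m$q_S, max_missing)
  .summary_likelihood(smry, .penvec(m))
}

#' @rdname family_likelihood
#' @details `marginalize_missing_parent()` is the explicit entry point for
#'   pedigrees containing genotype-missing founders; it errors if none are
#'   missing.
#' @export
marginalize_missing_parent <- function(ped, m, max_missing = 2) {
  carrier_na <- is.na(ped$smad6) | is.na(ped$bmp2)
  if (!any(carrier_na))
    stop("marginalize_missing_parent: no missing genotypes in this pedigree")
  family_likelihood(ped, m, max_missing)
}

#' Null likelihood: phenotypes independent of genotypes
#'
#' Under the chance alternative every member is affected with probability
#' `prevalence` regardless of genotype.
#'
#' @param ped a `"pedigree"`.
#' @param prevalence population disease prevalence in (0, 1).
#' @return Null likelihood.
#' @export
null_likelihood <- function(ped, prevalence) {
  if (prevalence <= 0 || prevalence >= 1)
    stop("null_likelihood: prevalence must lie in (0, 1)")
  na <- sum(ped$affected)
  prevalence^na * (1 - prevalence)^(nrow(ped) - na)
}

#' Per-family and total lod scores
#'
#' The family lod is \eqn{\log_{10}} of the two-locus model likelihood over
#' the null (genotype-independent) likelihood; independent families add on
#' the lod scale. A zero model likelihood (an unaffected member in a
#' fully-penetrant class) yields `-Inf`, surfaced as-is and flagged.
#'
#' @param ped,peds one pedigree / a list of pedigrees.
#' @param m a [two_locus_model()].
#' @param prevalence null prevalence (default 5e-4).
#' @param condition_proband correct for ascertainment by conditioning both
#'   numerator and denominator on the probands' (ascertained) affection:
#'   the model likelihood is divided by the probands' genotype-specific
#'   penetrance, the null likelihood by the prevalence. Default FALSE.
#' @return `family_lod`: a single lod. `total_lod`: a `"linkage_result"`
#'   list with `per_family_lod`, `total_lod`, `model`, `null_spec`.
#' @export
family_lod <- function(ped, m, prevalence = 5e-4, condition_proband = FALSE) {
  l1 <- family_likelihood(ped, m)
  l0 <- null_likelihood(ped, prevalence)
  if (condition_proband) {
    pro <- which(ped$proband)
    if (!length(pro)) stop("family_lod: condition_proband with no flagged proband")
    if (any(is.na(ped$smad6[pro]) | is.na(ped$bmp2[pro])))
      stop("family_lod: proband genotype missing; cannot condition")
    f <- penetrance_of(ped$smad6[pro] %in% c("D", "D*"), ped$bmp2[pro], m)
    l1 <- l1 / prod(f)
    l0 <- l0 / prevalence^length(pro)
  }
  log10(l1) - log10(l0)
}

#' @rdname family_lod
#' @export
total_lod <- function(peds, m, prevalence = 5e-4, condition_proband = FALSE) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  lods <- vapply(peds, family_lod, numeric(1), m = m, prevalence = prevalence,
                 condition_proband = condition_proband)
  names(lods) <- vapply(peds, function(p) p$fam[1], character(1))
  structure(list(per_family_lod = lods, total_lod = sum(lods), model = m,
                 null_spec = sprintf("phenotypes independent of genotype, prevalence %g",
                                     prevalence),
                 flagged = names(lods)[!is.finite(lods)]),
            class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, ...) {
  cat("Two-locus linkage (", length(x$per_family_lod), " kindreds)\n", sep = "")
  cat(sprintf("  total lod = %.4g (odds %.3g:1)\n", x$total_lod,
              lod_to_odds(x$total_lod)))
  if (length(x$flagged)) cat("  -Inf lod in:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Convert between lod scores and likelihood odds
#'
#' @param lod lod score; `odds` likelihood ratio.
#' @return `lod_to_odds` returns \eqn{10^{lod}}; `odds_to_lod` its inverse.
#' @export
lod_to_odds <- function(lod) 10^lod

#' @rdname lod_to_odds
#' @param odds likelihood ratio.
#' @export
odds_to_lod <- function(odds) log10(odds)

#' Default log2-spaced penetrance grid
#'
#' `0.0001, 0.0002, 0.0004, ..., 0.4096`, with `1.0` appended when
#' `include_one` (used for the both-loci penetrance, which may be complete).
#'
#' @param include_one append exact 1.0.
#' @return Numeric vector of grid values.
#' @export
penetrance_grid <- function(include_one = FALSE) {
  g <- 1e-4 * 2^(0:12)
  if (include_one) c(g, 1.0) else g
}

## Vectorized total log10-likelihood of all grid models over family summaries.
## F: M x 5 matrix of penetrance vectors. Returns length-M vector. With
## condition = TRUE, each family's likelihood is divided by the probands'
## genotype-specific penetrance (ascertainment correction, numerator side).
.grid_log10_lik <- function(F, summaries, condition = FALSE) {
  LF <- log10(F); L1F <- log10(1 - F)
  LF[!is.finite(LF)] <- -1e10
  L1F[!is.finite(L1F)] <- -1e10
  tot <- numeric(nrow(F))
  for (smry in summaries) {
    if (condition) {
      if (is.null(smry$pro))
        stop("ascertainment correction needs a genotyped, flagged proband in every kindred")
      tot <- tot - as.vector(LF %*% smry$pro)
    }
    if (smry$type == "counts") {
      tot <- tot + as.vector(LF %*% smry$a + L1F %*% smry$u)
    } else {
      J <- length(smry$w)
      X <- matrix(0, nrow(F), J)
      for (j in seq_len(J))
        X[, j] <- LF %*% smry$components[[j]]$a + L1F %*% smry$components[[j]]$u
      xmax <- apply(X, 1, max)
      contrib <- xmax + log10(rowSums(sweep(10^(X - xmax), 2, smry$w, "*")))
      contrib[!is.finite(xmax)] <- -1e10
      tot <- tot + contrib
    }
  }
  tot
}

#' Fit the two-locus penetrance model by exhaustive grid maximization
#'
#' Maximizes the total lod score over a per-parameter grid of penetrance
#' values (the search is exhaustive and deterministic; ties resolve to the
#' first grid point in column-major order). Allele frequencies `q_B`, `q_S`
#' enter only through the marginalization of missing founder genotypes and
#' are not searched.
#'
#' @param peds list of `"pedigree"` objects.
#' @param grid named list of candidate values for any of `f_both`, `f_S`,
#'   `f_B1`, `f_B2`, `f_0`; a singleton fixes the parameter. Defaults:
#'   [penetrance_grid()] per parameter, with 1.0 allowed for `f_both`.
#' @param prevalence null-model disease prevalence (default 5e-4).
#' @param q_B,q_S founder allele frequencies for missing-genotype
#'   marginalization.
#' @param condition_proband correct for ascertainment: condition each
#'   kindred's likelihood on the proband's affection (model likelihood
#'   divided by the proband's genotype-specific penetrance, null by the
#'   prevalence). Recommended when kindreds were collected through affected
#'   probands and the penetrances themselves are of interest.
#' @return An object of class `"twolocus_fit"`.
#' @export
fit_twolocus <- function(peds, grid = list(), prevalence = 5e-4,
                         q_B = 0.34, q_S = 1e-4, condition_proband = FALSE) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  if (!length(peds)) stop("fit_twolocus: no pedigrees")
  defaults <- list(f_both = penetrance_grid(include_one = TRUE),
                   f_S = penetrance_grid(), f_B1 = penetrance_grid(),
                   f_B2 = penetrance_grid(), f_0 = penetrance_grid())
  unknown <- setdiff(names(grid), names(defaults))
  if (length(unknown)) stop("fit_twolocus: unknown grid parameter(s): ",
                            paste(unknown, collapse = ", "))
  for (nm in names(grid)) defaults[[nm]] <- grid[[nm]]
  grid <- defaults
  if (any(!lengths(grid))) stop("fit_twolocus: empty grid")
  summaries <- lapply(peds, .family_summary, q_B = q_B, q_S = q_S)
  G <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  F <- as.matrix(G[, c("f_both", "f_S", "f_B1", "f_B2", "f_0")])
  ll <- .grid_log10_lik(F, summaries, condition = condition_proband)
  ll0 <- sum(vapply(peds, function(p) log10(null_likelihood(p, prevalence)),
                    numeric(1)))
  if (condition_proband)
    ll0 <- ll0 - log10(prevalence) *
      sum(vapply(peds, function(p) sum(p$proband), numeric(1)))
  lods <- ll - ll0
  best <- which.max(lods)
  fb <- unname(F[best, ])
  m <- two_locus_model(fb[1], fb[2], fb[3], fb[4], fb[5], q_B = q_B, q_S = q_S)
  res <- total_lod(peds, m, prevalence, condition_proband = condition_proband)
  profile <- lapply(names(grid), function(nm) {
    vals <- sort(unique(G[[nm]]))
    data.frame(value = vals,
               lod = vapply(vals, function(v) max(lods[G[[nm]] == v]), numeric(1)))
  })
  names(profile) <- names(grid)
  structure(list(model = m, total_lod = res$total_lod,
                 per_family_lod = res$per_family_lod,
                 log10_lik = ll[best], null_log10_lik = ll0,
                 grid = grid, profile = profile, prevalence = prevalence,
                 n_families = length(peds), n_models = nrow(F),
                 call = match.call()),
            class = "twolocus_fit")
}

#' @export
print.twolocus_fit <- function(x, ...) {
  cat("Two-locus penetrance model fit (exhaustive grid, ",
      x$n_models, " models, ", x$n_families, " kindreds)\n", sep = "")
  cat(sprintf("  total lod = %.4g (odds %.3g:1 vs prevalence %g null)\n",
              x$total_lod, lod_to_odds(x$total_lod), x$prevalence))
  cat("  penetrances:", paste(sprintf("%s=%g", names(coef(x)), coef(x)),
                              collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.twolocus_fit <- function(object, ...) {
  print(object)
  cat("\nPer-family lod scores:\n")
  print(round(object$per_family_lod, 4))
  invisible(object)
}

#' @export
coef.twolocus_fit <- function(object, ...) {
  m <- object$model
  c(f_both = m$f_both, f_S = m$f_S, f_B1 = m$f_B1, f_B2 = m$f_B2, f_0 = m$f_0)
}

#' @export
logLik.twolocus_fit <- function(object, ...) {
  structure(object$log10_lik * log(10),
            df = sum(lengths(object$grid) > 1),
            nobs = object$n_families, class = "logLik")
}

#' @export
predict.twolocus_fit <- function(object, newdata, ...) {
  if (missing(newdata))
    newdata <- expand.grid(carrier = c(TRUE, FALSE), dose = 0:2)
  newdata$penetrance <- penetrance_of(newdata$carrier, newdata$dose, object$model)
  newdata
}

#' @export
simulate.twolocus_fit <- function(object, nsim = 1, seed = NULL, n_families = 13,
                                  ...) {
  lapply(seq_len(nsim), function(i)
    simulate_pedigrees(n_families = n_families, model = object$model,
                       seed = if (is.null(seed)) NULL else seed + i - 1L, ...))
}

#' @export
plot.twolocus_fit <- function(x, parameter = "f_S", ...) {
  pr <- x$profile[[parameter]]
  if (is.null(pr)) stop("no profile for parameter ", parameter)
  graphics::plot(pr$value, pr$lod, log = "x", type = "b",
                 xlab = parameter, ylab = "profile lod", ...)
  graphics::abline(v = coef(x)[parameter], lty = 2)
  invisible(x)
}

#' Compare the two-locus model with the best single-locus model
#'
#' Maximizes a single-locus penetrance model — risk depends only on the rare
#' damaging allele, the SNP is ignored — over a grid, and returns the
#' likelihood ratio \eqn{10^{lod_2 - lod_1}} of the supplied two-locus model
#' over that best single-locus competitor.
#'
#' @param peds list of pedigrees.
#' @param m2 the two-locus model (e.g. from [fit_twolocus()]).
#' @param m1_grid named list with `f_carrier` and `f_noncarrier` candidate
#'   vectors (defaults: [penetrance_grid()] with 1.0 for carriers; for
#'   noncarriers the grid plus the null prevalence).
#' @param prevalence null prevalence shared by both comparisons.
#' @return List: `ratio` (two-locus : single-locus), `lod_two_locus`,
#'   `lod_single_locus`, `best_single` (named vector).
#' @export
single_locus_comparison <- function(peds, m2, m1_grid = list(),
                                    prevalence = 5e-4) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  defaults <- list(f_carrier = penetrance_grid(include_one = TRUE),
                   f_noncarrier = sort(unique(c(penetrance_grid(), prevalence))))
  for (nm in names(m1_grid)) defaults[[nm]] <- m1_grid[[nm]]
  summaries <- lapply(peds, .family_summary, q_B = m2$q_B, q_S = m2$q_S)
  G <- expand.grid(defaults, KEEP.OUT.ATTRS = FALSE)
  ## single-locus model as a constrained penetrance vector
  F <- cbind(G$f_carrier, G$f_carrier, G$f_noncarrier, G$f_noncarrier,
             G$f_noncarrier)
  ll <- .grid_log10_lik(F, summaries)
  ll0 <- sum(vapply(peds, function(p) log10(null_likelihood(p, prevalence)),
                    numeric(1)))
  lod1 <- max(ll - ll0)
  best <- which.max(ll - ll0)
  lod2 <- total_lod(peds, m2, prevalence)$total_lod
  list(ratio = 10^(lod2 - lod1), lod_two_locus = lod2, lod_single_locus = lod1,
       best_single = c(f_carrier = G$f_carrier[best],
                       f_noncarrier = G$f_noncarrier[best]))
}
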