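#' Rarity and damaging-call policy
#'
#' Thresholds used to declare a variant "rare" and a missense call "damaging".
#' Defaults follow the prospective criteria used in trio exome studies of
#' midline craniosynostosis: population allele frequency below 2e-5 for
#' dominant analyses, below 1e-3 for recessive genotypes, and an ensemble
#' (MetaSVM-style) rank score above 0.83357 for a damaging-missense call when
#' only a score (no categorical call) is available.
#'
#' @param dominant_af_max strict upper bound on population allele frequency
#'   for dominant-model rarity (default `2e-5`).
#' @param recessive_af_max strict upper bound for recessive-model rarity
#'   (default `1e-3`).
#' @param damaging_score_min score strictly above which a missense variant is
#'   called damaging when no categorical call is present (default `0.83357`).
#' @return An object of class `"rarity_policy"`.
#' @export
rarity_policy <- function(dominant_af_max = 2e-5,
                          recessive_af_max = 1e-3,
                          damaging_score_min = 0.83357) {
  stopifnot(is.numeric(dominant_af_max), is.numeric(recessive_af_max),
            is.numeric(damaging_score_min))
  if (!(dominant_af_max > 0 && dominant_af_max <= recessive_af_max))
    stop("rarity_policy: need 0 < dominant_af_max <= recessive_af_max")
  if (damaging_score_min < 0 || damaging_score_min > 1)
    stop("rarity_policy: damaging_score_min must lie in [0, 1]")
  structure(list(dominant_af_max = dominant_af_max,
                 recessive_af_max = recessive_af_max,
                 damaging_score_min = damaging_score_min),
            class = "rarity_policy")
}

#' @export
print.rarity_policy <- function(x, ...) {
  cat("Rarity policy:\n")
  cat("  dominant AF <", format(x$dominant_af_max), "\n")
  cat("  recessive AF <", format(x$recessive_af_max), "\n")
  cat("  damaging score >", format(x$damaging_score_min), "\n")
  invisible(x)
}

#' Read a rarity policy from a YAML config file
#'
#' The file may define any subset of `dominant_af_max`, `recessive_af_max`,
#' `damaging_score_min`; unspecified fields keep their defaults.
#'
#' @param path path to a YAML file.
#' @return A `"rarity_policy"`.
#' @export
read_rarity_policy <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- rarity_policy()
  for (nm in names(defaults)) if (!is.null(cfg[[nm]])) defaults[[nm]] <- cfg[[nm]]
  rarity_policy(defaults$dominant_af_max, defaults$recessive_af_max,
                defaults$damaging_score_min)
}

.consequences <- c("synonymous", "missense", "nonsense", "frameshift", "splice_site")
.lof_consequences <- c("nonsense", "frameshift", "splice_site")

#' Construct / validate an annotated variant table
#'
#' A variant table is a data frame with one row per called coding variant in
#' one individual. Required columns: `sample_id`, `gene`, `consequence`
#' (one of synonymous / missense / nonsense / frameshift / splice_site),
#' `damaging_call` ("D", "T" or NA; meaningful for missense only),
#' `damaging_score` (numeric in [0,1] or NA), `pop_af` (population allele
#' frequency in [0,1]; variants absent from the reference database carry 0),
#' `origin` (de_novo / transmitted / unknown) and `zygosity` (het / hom).
#'
#' @param df a data frame with the columns above.
#' @return The validated data frame with class `"variant_table"` prepended.
#' @export
variant_table <- function(df) {
  need <- c("sample_id", "gene", "consequence", "damaging_call",
            "damaging_score", "pop_af", "origin", "zygosity")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("variant_table: missing columns: ", paste(miss, collapse = ", "))
  df$consequence <- as.character(df$consequence)
  bad <- !df$consequence %in% .consequences
  if (any(bad)) stop("variant_table: unknown consequence: ",
                     paste(unique(df$consequence[bad]), collapse = ", "))
  if (any(is.na(df$pop_af))) stop("variant_table: pop_af must be present (use 0 for absent-from-database)")
  if (any(df$pop_af < 0 | df$pop_af > 1)) stop("variant_table: pop_af outside [0, 1]")
  if (!all(df$origin %in% c("de_novo", "transmitted", "unknown")))
    stop("variant_table: origin must be de_novo / transmitted / unknown")
  if (!all(df$zygosity %in% c("het", "hom")))
    stop("variant_table: zygosity must be het / hom")
  dc <- df$damaging_call
  if (any(!is.na(dc) & !dc %in% c("D", "T")))
    stop("variant_table: damaging_call must be D, T or NA")
  if (any(!is.na(dc) & df$consequence != "missense"))
    stop("variant_table: damaging_call defined only for missense variants")
  sc <- df$damaging_score
  if (any(!is.na(sc) & (sc < 0 | sc > 1)))
    stop("variant_table: damaging_score outside [0, 1]")
  class(df) <- unique(c("variant_table", class(df)))
  df
}

#' Read / write a tab-separated variant table
#'
#' @param path file path; the file is TSV with the fixed header documented in
#'   [variant_table()]. Missing values are written as `NA`.
#' @return `read_variant_table` returns a validated `"variant_table"`.
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", "."),
                          colClasses = c(damaging_call = "character"))
  df$damaging_score <- as.numeric(df$damaging_score)
  variant_table(df)
}

#' @rdname read_variant_table
#' @param df a `"variant_table"` (or coercible data frame).
#' @export
write_variant_table <- function(df, path) {
  df <- variant_table(as.data.frame(df))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify variants into burden classes
#'
#' Maps annotated variants onto the four classes used throughout the burden
#' analyses: `LOF` (nonsense, frameshift or splice-site — loss of function),
#' `D_mis` (damaging missense: categorical call "D", or score strictly above
#' the policy threshold when only a score is available), `T_mis` (tolerated
#' missense) and `synonymous`.
#'
#' @param x a `"variant_table"` data frame, or a single-row list/data frame.
#' @param policy a [rarity_policy()]; supplies the damaging-score threshold.
#' @return Character vector of classes, one per row of `x`.
#' @details A missense variant carrying neither a categorical call nor a
#'   score is an error ("unclassifiable"), never silently tolerated.
#' @export
classify_variants <- function(x, policy = rarity_policy()) {
  x <- as.data.frame(x)
  cons <- as.character(x$consequence)
  out <- character(nrow(x))
  out[cons %in% .lof_consequences] <- "LOF"
  out[cons == "synonymous"] <- "synonymous"
  mis <- which(cons == "missense")
  if (length(mis)) {
    call <- x$damaging_call[mis]
    score <- x$damaging_score[mis]
    unclass <- is.na(call) & is.na(score)
    if (any(unclass))
      stop("classify_variants: unclassifiable missense (no damaging call and no score) at row(s) ",
           paste(mis[unclass], collapse = ", "))
    dam <- ifelse(!is.na(call), call == "D", score > policy$damaging_score_min)
    out[mis] <- ifelse(dam, "D_mis", "T_mis")
  }
  bad <- !cons %in% c(.lof_consequences, "synonymous", "missense")
  if (any(bad)) stop("classify_variants: unknown consequence ", unique(cons[bad]))
  out
}

#' @rdname classify_variants
#' @param consequence,damaging_call,damaging_score scalar fields of a single
#'   variant, for the one-record convenience form.
#' @export
classify_variant <- function(consequence, damaging_call = NA, damaging_score = NA,
                             policy = rarity_policy()) {
  classify_variants(data.frame(consequence = consequence,
                               damaging_call = as.character(damaging_call),
                               damaging_score = as.numeric(damaging_score),
                               stringsAsFactors = FALSE), policy)
}

#' Filter a variant table down to rare variants
#'
#' Keeps rows whose population allele frequency is strictly below the policy
#' threshold for the chosen inheritance mode (the comparison is strict `<`;
#' absent-from-database variants, coded `pop_af = 0`, always pass). Row order
#' is preserved.
#'
#' @param records a `"variant_table"`.
#' @param policy a [rarity_policy()].
#' @param mode `"dominant"` (AF < `dominant_af_max`) or `"recessive"`
#'   (AF < `recessive_af_max`).
#' @return The filtered variant table.
#' @export
filter_rare <- function(records, policy = rarity_policy(),
                        mode = c("dominant", "recessive")) {
  mode <- match.arg(mode)
  records <- as.data.frame(records)
  if (any(is.na(records$pop_af)) || any(records$pop_af < 0))
    stop("filter_rare: pop_af must be non-negative and present")
  thr <- if (mode == "dominant") policy$dominant_af_max else policy$recessive_af_max
  out <- records[records$pop_af < thr, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- unique(c("variant_table", class(out)))
  out
}

#' Read a per-gene de novo mutation-rate table
#'
#' A rate table gives, per gene, the expected number of de novo mutations in
#' the whole cohort for each mutation class (the Poisson lambda of the
#' class-specific burden test). Columns: `gene`, `lambda_lof`, `lambda_mis`,
#' `lambda_syn`. Lambdas scale linearly with cohort size; `cohort_size`
#' records the number of trios the lambdas refer to.
#'
#' @param path TSV file path.
#' @param cohort_size number of trios the table's lambdas were computed for.
#' @return Data frame with class `"rate_table"` and attribute `cohort_size`.
#' @export
read_rate_table <- function(path, cohort_size = NA_integer_) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  rate_table(df, cohort_size)
}

#' @rdname read_rate_table
#' @param df data frame with columns `gene`, `lambda_lof`, `lambda_mis`,
#'   `lambda_syn`.
#' @export
rate_table <- function(df, cohort_size = NA_integer_) {
  need <- c("gene", "lambda_lof", "lambda_mis", "lambda_syn")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("rate_table: missing columns: ", paste(miss, collapse = ", "))
  lam <- as.matrix(df[, c("lambda_lof", "lambda_mis", "lambda_syn")])
  if (any(lam < 0, na.rm = TRUE)) stop("rate_table: lambdas must be >= 0")
  attr(df, "cohort_size") <- cohort_size
  class(df) <- unique(c("rate_table", class(df)))
  df
}

#' Rescale a rate table to a different cohort size
#'
#' Expected de novo counts are per-cohort quantities and scale linearly with
#' the number of sequenced trios.
#'
#' @param rates a `"rate_table"` with a known `cohort_size`.
#' @param new_size target number of trios.
#' @return Rescaled `"rate_table"`.
#' @export
rescale_rate_table <- function(rates, new_size) {
  old <- attr(rates, "cohort_size")
  if (is.na(old)) stop("rescale_rate_table: source cohort_size unknown")
  fac <- new_size / old
  for (cl in c("lambda_lof", "lambda_mis", "lambda_syn")) rates[[cl]] <- rates[[cl]] * fac
  attr(rates, "cohort_size") <- new_size
  rates
}

#' Read a per-gene coding-length table
#'
#' Two columns: `gene` and `coding_bp` (positive integers). The sum of
#' `coding_bp` over all genes defines the exome denominator for the
#' length-weighted binomial burden test.
#'
#' @param path TSV file path.
#' @return Data frame with class `"gene_length_table"`.
#' @export
read_gene_lengths <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  gene_length_table(df)
}

#' @rdname read_gene_lengths
#' @param df data frame with columns `gene`, `coding_bp`.
#' @export
gene_length_table <- function(df) {
  if (!all(c("gene", "coding_bp") %in% names(df)))
    stop("gene_length_table: need columns gene, coding_bp")
  if (any(df$coding_bp <= 0)) stop("gene_length_table: coding_bp must be > 0")
  if (anyDuplicated(df$gene)) stop("gene_length_table: duplicated gene symbols")
  class(df) <- unique(c("gene_length_table", class(df)))
  df
}
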