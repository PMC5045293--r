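#' Simulation / pipeline configuration
#'
#' Bundles the parameters of a full synthetic-cohort run. Defaults are the
#' study conditions the analyses were designed around: 132 trios, a 13-
#' kindred two-locus linkage panel, SNP risk-allele frequency 0.34, the
#' maximum-likelihood penetrance vector, and rare damaging spike rates small
#' enough to emulate a single true disease gene.
#'
#' @param n_trios trio cohort size for the de novo stage.
#' @param n_genes genes in the synthetic rate / length tables.
#' @param n_families kindreds for the linkage stage.
#' @param n_transmitted_alleles cohort-wide rare damaging allele count for
#'   the transmitted-burden stage.
#' @param model a [two_locus_model()].
#' @param spike_gene gene receiving excess damaging variation.
#' @param spike_denovo_lof,spike_denovo_dmis extra expected de novo counts
#'   in the spike gene.
#' @param spike_transmitted extra transmitted alleles in the spike gene.
#' @param templates pedigree templates (see [simulate_pedigrees()]).
#' @param seed root RNG seed; all stage substreams derive from it.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(n_trios = 132, n_genes = 500, n_families = 13,
                       n_transmitted_alleles = 1135,
                       model = two_locus_model(),
                       spike_gene = "GENE0001",
                       spike_denovo_lof = 2, spike_denovo_dmis = 1,
                       spike_transmitted = 8,
                       templates = c("quartet", "threegen", "multiplex"),
                       seed = 1L) {
  structure(list(n_trios = n_trios, n_genes = n_genes, n_families = n_families,
                 n_transmitted_alleles = n_transmitted_alleles, model = model,
                 spike_gene = spike_gene, spike_denovo_lof = spike_denovo_lof,
                 spike_denovo_dmis = spike_denovo_dmis,
                 spike_transmitted = spike_transmitted,
                 templates = templates, seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields override [sim_config()] defaults; penetrance-model fields
#' may be given under a `model:` block (`f_both`, `f_S`, `f_B1`, `f_B2`,
#' `f_0`, `q_B`, `q_S`).
#'
#' @param path YAML file path.
#' @return A `"sim_config"`.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- cfg[setdiff(names(cfg), "model")]
  if (!is.null(cfg$model)) args$model <- do.call(two_locus_model, cfg$model)
  do.call(sim_config, args)
}

.stage <- function(name, log, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  log(sprintf("stage %-18s %.2fs", name, proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' simulate -> de novo burden -> transmitted burden -> epistasis -> linkage,
#' writing every stage's inputs and outputs plus a run manifest (seed,
#' config, input digests, package version) into `out_dir`. Deterministic:
#' identical configs and seeds reproduce byte-identical TSV/JSON outputs.
#'
#' @param config a `"sim_config"`, or path to a YAML config file.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the main results of each stage and
#'   `manifest`.
#' @export
run_all <- function(config = sim_config(), out_dir, quiet = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("run_all: config file not found: ", config)
    config <- read_sim_config(config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out_dir, "run.log")
  cat("", file = logfile)
  log <- function(msg) {
    cat(msg, "\n", file = logfile, append = TRUE)
    if (!quiet) message(msg)
  }
  path <- function(f) file.path(out_dir, f)
  seed <- config$seed
  wtsv <- function(df, f) {
    utils::write.table(df, path(f), sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }

  sim <- .stage("simulate", log, {
    rates <- synthetic_rate_table(config$n_genes, cohort_size = config$n_trios,
                                  seed = seed)
    lengths <- synthetic_gene_lengths(config$n_genes, seed = seed)
    dn <- simulate_denovo_cohort(config$n_trios, rates,
                                 spike = list(gene = config$spike_gene,
                                              extra_lof = config$spike_denovo_lof,
                                              extra_dmis = config$spike_denovo_dmis),
                                 seed = seed)
    tr <- simulate_transmitted_alleles(config$n_transmitted_alleles, lengths,
                                       spike_gene = config$spike_gene,
                                       spike_count = config$spike_transmitted,
                                       seed = seed)
    peds <- simulate_pedigrees(config$n_families, model = config$model,
                               templates = config$templates, seed = seed)
    write_variant_table(dn$variants, path("variants.tsv"))
    wtsv(as.data.frame(rates), "rates.tsv")
    wtsv(as.data.frame(lengths), "gene_lengths.tsv")
    wtsv(data.frame(gene = names(tr), alleles = as.integer(tr)),
         "transmitted_counts.tsv")
    write_pedigree(peds, path("pedigrees.ped"))
    list(variants = dn$variants, rates = rates, lengths = lengths,
         transmitted = tr, peds = peds)
  })

  denovo <- .stage("denovo-burden", log, {
    cls <- classify_variants(sim$variants)
    obs <- c(LOF = sum(cls == "LOF"), D_mis = sum(cls == "D_mis"),
             T_mis = sum(cls == "T_mis"), synonymous = sum(cls == "synonymous"))
    lam <- c(LOF = sum(sim$rates$lambda_lof),
             D_mis = sum(sim$rates$lambda_mis) * 0.162,
             T_mis = sum(sim$rates$lambda_mis) * (1 - 0.162),
             synonymous = sum(sim$rates$lambda_syn))
    class_tab <- do.call(rbind, lapply(names(obs), function(cl) {
      b <- class_poisson_test(obs[[cl]], lam[[cl]], label = cl)
      data.frame(class = cl, observed = b$observed,
                 per_subject = b$observed / config$n_trios,
                 expected = b$expected, enrichment = b$enrichment,
                 tail = b$tail, p.value = b$p.value, stringsAsFactors = FALSE)
    }))
    spike_rows <- sim$rates[sim$rates$gene == config$spike_gene, ]
    gene_tab <- gene_poisson_test(
      spike_rows,
      observed_lof = sum(cls == "LOF" & sim$variants$gene == config$spike_gene),
      observed_mis = sum(cls %in% c("D_mis", "T_mis") &
                           sim$variants$gene == config$spike_gene))
    wtsv(class_tab, "denovo_class_burden.tsv")
    wtsv(gene_tab, "denovo_gene_burden.tsv")
    list(class_tab = class_tab, gene_tab = gene_tab)
  })

  transmitted <- .stage("transmitted-burden", log, {
    scan <- burden_scan(sim$transmitted, sim$lengths)
    qq <- qq_points(stats::setNames(scan$p.value, scan$gene))
    wtsv(scan, "transmitted_burden.tsv")
    wtsv(qq, "transmitted_qq.tsv")
    list(scan = scan, qq = qq)
  })

  epi <- .stage("epistasis", log, {
    tab <- class_risk_table(sim$peds)
    fh <- freeman_halton_exact(tab, method = if (sum(tab) <= 60) "auto" else "mc",
                               seed = substream_seed(seed, "fh_mc"))
    cf <- stats::fisher.test(tab[1:2, ])$p.value
    tc <- extract_tdt_counts(sim$peds)
    td <- if (tc$transmitted + tc$untransmitted > 0)
            tdt(tc$transmitted, tc$untransmitted)
          else list(chi2 = NA_real_, p.value = NA_real_)
    carriers <- sum(tab[1:2, ])
    affected_carriers <- sum(tab[1:2, 1])
    n_pro <- sum(vapply(sim$peds, function(p)
      sum(p$proband & p$smad6 %in% c("D", "D*"), na.rm = TRUE), numeric(1)))
    pen <- list(
      include = penetrance_estimate(carriers, affected_carriers, n_pro, FALSE),
      exclude = if (carriers > n_pro && n_pro <= affected_carriers)
                  penetrance_estimate(carriers, affected_carriers, n_pro, TRUE)
                else NA_real_)
    res <- list(class_table = unclass(tab)[, , drop = FALSE],
                freeman_halton_p = fh$p.value, carrier_fisher_p = cf,
                tdt = list(transmitted = tc$transmitted,
                           untransmitted = tc$untransmitted,
                           chi2 = td$chi2, p = td$p.value),
                penetrance = pen)
    jsonlite::write_json(res, path("epistasis.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    res
  })

  linkage <- .stage("linkage", log, {
    fit <- fit_twolocus(sim$peds,
                        grid = list(f_both = c(0.25, 0.5, 1.0),
                                    f_S = penetrance_grid(),
                                    f_B1 = config$model$f_B1,
                                    f_B2 = config$model$f_B2,
                                    f_0 = config$model$f_0))
    out <- list(total_lod = fit$total_lod,
                per_family_lod = as.list(fit$per_family_lod),
                penetrance = as.list(coef(fit)),
                prevalence = fit$prevalence)
    jsonlite::write_json(out, path("linkage.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    wtsv(data.frame(family = names(fit$per_family_lod),
                    lod = as.numeric(fit$per_family_lod)), "family_lods.tsv")
    fit
  })

  inputs <- c("variants.tsv", "rates.tsv", "gene_lengths.tsv",
              "transmitted_counts.tsv", "pedigrees.ped")
  manifest <- list(
    package_version = as.character(utils::packageVersion("craniodigen")),
    seed = seed,
    config = config[setdiff(names(config), "model")],
    model = unclass(config$model),
    input_digests = stats::setNames(as.list(unname(
      tools::md5sum(file.path(out_dir, inputs)))), inputs),
    outputs = c("denovo_class_burden.tsv", "denovo_gene_burden.tsv",
                "transmitted_burden.tsv", "transmitted_qq.tsv",
                "epistasis.json", "linkage.json", "family_lods.tsv"))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log("run complete")
  invisible(list(simulate = sim, denovo = denovo, transmitted = transmitted,
                 epistasis = epi, linkage = linkage, manifest = manifest))
}
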