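# Fixtures built in code: trios, the kindred panel reproducing the published
# two-locus class-by-affection margins, and independent likelihood oracles.

make_trio <- function(fam = "F1", smad6 = c("D", "N", "D"), bmp2 = c(0, 1, 1),
                      affected = c(FALSE, FALSE, TRUE), validate = TRUE) {
  pedigree(data.frame(
    fam = fam, id = c("fa", "mo", "ch"),
    father = c(NA, NA, "fa"), mother = c(NA, NA, "mo"),
    sex = c(1L, 2L, 1L), affected = affected,
    proband = c(FALSE, FALSE, TRUE),
    smad6 = smad6, bmp2 = as.integer(bmp2),
    stringsAsFactors = FALSE), validate = validate)
}

# Kindred panel engineered so class_risk_table() reproduces the published
# 3x2 margins: S+B+ 14/0, S+B- 3/13, S-B+ 0/18.
class_table_pedigrees <- function() {
  peds <- list()
  unit <- function(fam, ids, fathers, mothers, aff, pro, smad6, bmp2) {
    pedigree(data.frame(fam = fam, id = ids, father = fathers, mother = mothers,
                        sex = rep(1L, length(ids)), affected = aff, proband = pro,
                        smad6 = smad6, bmp2 = as.integer(bmp2),
                        stringsAsFactors = FALSE))
  }
  k <- 0
  add <- function(...) peds[[length(peds) + 1L]] <<- unit(...)
  # 4x T1: fa D0 unaff, mo N1 unaff, ch D1 affected proband
  for (i in 1:4) add(sprintf("T1_%d", i), c("fa", "mo", "ch"),
                     c(NA, NA, "fa"), c(NA, NA, "mo"),
                     c(FALSE, FALSE, TRUE), c(FALSE, FALSE, TRUE),
                     c("D", "N", "D"), c(0, 1, 1))
  # 6x T1b: as T1 plus a noncarrier sib with the risk allele
  for (i in 1:6) add(sprintf("T1b_%d", i), c("fa", "mo", "ch", "sib"),
                     c(NA, NA, "fa", "fa"), c(NA, NA, "mo", "mo"),
                     c(FALSE, FALSE, TRUE, FALSE), c(FALSE, FALSE, TRUE, FALSE),
                     c("D", "N", "D", "N"), c(0, 1, 1, 1))
  # 3x T2: carrier child affected without the risk allele
  for (i in 1:3) add(sprintf("T2_%d", i), c("fa", "mo", "ch"),
                     c(NA, NA, "fa"), c(NA, NA, "mo"),
                     c(FALSE, FALSE, TRUE), c(FALSE, FALSE, TRUE),
                     c("D", "N", "D"), c(0, 0, 0))
  # 2x T3: affected carrier parent and child, both with the risk allele
  for (i in 1:2) add(sprintf("T3_%d", i), c("fa", "mo", "ch"),
                     c(NA, NA, "fa"), c(NA, NA, "mo"),
                     c(TRUE, FALSE, TRUE), c(FALSE, FALSE, TRUE),
                     c("D", "N", "D"), c(1, 1, 1))
  peds
}

# Independent brute-force likelihood oracle: enumerates every genotype
# completion of genotype-missing members, weighting by founder priors
# (Hardy-Weinberg at q_B; carrier frequency q_S) and explicit Mendelian
# transmission probabilities, then averages the penetrance product.
# Written from first principles; shares no code with the package internals.
oracle_likelihood <- function(ped, m) {
  n <- nrow(ped)
  carrier_obs <- ifelse(is.na(ped$smad6), NA, ped$smad6 %in% c("D", "D*"))
  denovo <- !is.na(ped$smad6) & ped$smad6 == "D*"
  miss <- which(is.na(carrier_obs) | is.na(ped$bmp2))
  states <- expand.grid(car = c(TRUE, FALSE), dose = 0:2)
  combos <- if (length(miss)) expand.grid(rep(list(seq_len(nrow(states))), length(miss)))
            else data.frame(dummy = 1)
  hwe <- function(d) c((1 - m$q_B)^2, 2 * m$q_B * (1 - m$q_B), m$q_B^2)[d + 1]
  fa <- match(ped$father, ped$id); mo <- match(ped$mother, ped$id)
  num <- den <- 0
  for (j in seq_len(nrow(combos))) {
    car <- carrier_obs; dose <- ped$bmp2
    if (length(miss)) {
      st <- as.integer(combos[j, ])
      car[miss] <- states$car[st]
      dose[miss] <- states$dose[st]
    }
    w <- 1
    for (i in seq_len(n)) {
      if (is.na(fa[i])) {            # founder prior only for completed members
        if (i %in% miss) w <- w * (if (car[i]) m$q_S else 1 - m$q_S) * hwe(dose[i])
      } else {
        tf <- dose[fa[i]] / 2; tm <- dose[mo[i]] / 2
        pd <- c((1 - tf) * (1 - tm), tf * (1 - tm) + (1 - tf) * tm, tf * tm)
        if (!is.na(ped$bmp2[i])) w <- w * pd[ped$bmp2[i] + 1]
        if (!is.na(ped$smad6[i]) && !denovo[i]) {
          pc <- 1 - (1 - 0.5 * car[fa[i]]) * (1 - 0.5 * car[mo[i]])
          w <- w * (if (car[i]) pc else 1 - pc)
        }
      }
    }
    f <- ifelse(car, ifelse(dose >= 1, m$f_both, m$f_S),
                ifelse(dose == 1, m$f_B1, ifelse(dose == 2, m$f_B2, m$f_0)))
    pen <- prod(ifelse(ped$affected, f, 1 - f))
    num <- num + w * pen
    den <- den + w
  }
  num / den
}

tiny_rate_table <- function() {
  rate_table(data.frame(gene = c("SMAD6", "SPRY_SET", "OTHER"),
                        lambda_lof = c(0.00026, 0.001193, 10),
                        lambda_mis = c(0.0046, 0.01, 70),
                        lambda_syn = c(0.002, 0.004, 35),
                        stringsAsFactors = FALSE),
             cohort_size = 132)
}

tiny_variants <- function() {
  variant_table(data.frame(
    sample_id = c("s1", "s1", "s2", "s3", "s4"),
    gene = c("SMAD6", "SMAD6", "TTN", "SMAD6", "FGFR2"),
    consequence = c("frameshift", "nonsense", "missense", "missense", "synonymous"),
    damaging_call = c(NA, NA, "T", NA, NA),
    damaging_score = c(NA, NA, NA, 0.9, NA),
    pop_af = c(0, 9.0e-6, 3.3e-5, 9.4e-6, 0.002),
    origin = c("de_novo", "transmitted", "transmitted", "transmitted", "transmitted"),
    zygosity = "het",
    stringsAsFactors = FALSE))
}
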