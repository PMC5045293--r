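#' Construct a two-locus pedigree
#'
#' A pedigree holds one kindred: individuals, parent links, sex, affection
#' status, an explicit proband flag, and genotypes at the two loci of the
#' digenic model — the rare damaging-variant carrier state at the candidate
#' gene (coded `"D"` inherited carrier, `"D*"` de novo carrier, `"N"`
#' noncarrier, `NA` missing) and the risk-allele dose at the common SNP
#' (0, 1, 2 or `NA`).
#'
#' @param df data frame with columns `fam`, `id`, `father`, `mother`
#'   (`NA` for founders), `sex` (1 male, 2 female, 0 unknown), `affected`
#'   (logical), `proband` (logical), `smad6` (character as above), `bmp2`
#'   (integer dose or `NA`).
#' @param validate check structural and Mendelian invariants (default TRUE).
#' @return The data frame with class `"pedigree"`.
#' @export
pedigree <- function(df, validate = TRUE) {
  need <- c("fam", "id", "father", "mother", "sex", "affected", "proband",
            "smad6", "bmp2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("pedigree: missing columns: ", paste(miss, collapse = ", "))
  df$id <- as.character(df$id)
  df$father <- as.character(df$father)
  df$mother <- as.character(df$mother)
  df$affected <- as.logical(df$affected)
  df$proband <- as.logical(df$proband)
  df$smad6 <- as.character(df$smad6)
  df$bmp2 <- as.integer(df$bmp2)
  class(df) <- unique(c("pedigree", class(df)))
  if (validate) validate_pedigree(df)
  df
}

#' @rdname pedigree
#' @param x object to test.
#' @export
is_founder <- function(x) is.na(x$father) & is.na(x$mother)

#' Validate pedigree structure and Mendelian consistency
#'
#' Checks: every named parent exists in the family; individuals have either
#' two named parents or none (founders); parent links are acyclic; SNP doses
#' of children are achievable from their parents' doses (a missing parental
#' genotype is compatible with any transmission); a child carrying the rare
#' damaging allele without the de novo flag has at least one carrier (or
#' genotype-missing) parent.
#'
#' @param ped a `"pedigree"`.
#' @param line_offset optional integer vector mapping rows to source-file
#'   line numbers, used in error messages by [read_pedigree()].
#' @return Invisibly `TRUE`; stops with a structured message otherwise.
#' @export
validate_pedigree <- function(ped, line_offset = NULL) {
  where <- function(i) {
    if (is.null(line_offset)) sprintf("individual '%s'", ped$id[i])
    else sprintf("individual '%s' (line %d)", ped$id[i], line_offset[i])
  }
  if (anyDuplicated(ped$id))
    stop("pedigree [", ped$fam[1], "]: duplicated individual ids")
  half <- xor(is.na(ped$father), is.na(ped$mother))
  if (any(half))
    stop("pedigree [", ped$fam[1], "]: ", where(which(half)[1]),
         " has exactly one named parent; need both or neither")
  for (col in c("father", "mother")) {
    known <- !is.na(ped[[col]])
    bad <- known & !ped[[col]] %in% ped$id
    if (any(bad))
      stop("pedigree [", ped$fam[1], "]: ", where(which(bad)[1]),
           " names missing ", col, " '", ped[[col]][which(bad)[1]], "'")
  }
  ## acyclicity: iteratively peel individuals whose parents are all peeled
  done <- is_founder(ped)
  repeat {
    newly <- !done & ped$father %in% ped$id[done] & ped$mother %in% ped$id[done]
    if (!any(newly)) break
    done <- done | newly
  }
  if (!all(done))
    stop("pedigree [", ped$fam[1], "]: cyclic parent links involving ",
         paste(ped$id[!done], collapse = ", "))
  ## Mendelian consistency at the SNP
  dose_alleles <- function(d) {
    if (is.na(d)) return(0:1)
    switch(as.character(d), "0" = 0L, "1" = 0:1, "2" = 1L,
           stop("bmp2 dose must be 0, 1, 2 or NA"))
  }
  idx <- match(ped$father, ped$id)
  midx <- match(ped$mother, ped$id)
  for (i in seq_len(nrow(ped))) {
    if (is.na(ped$father[i]) || is.na(ped$bmp2[i])) next
    fa <- dose_alleles(ped$bmp2[idx[i]])
    mo <- dose_alleles(ped$bmp2[midx[i]])
    if (!ped$bmp2[i] %in% outer(fa, mo, "+"))
      stop("pedigree [", ped$fam[1], "]: Mendelian inconsistency at SNP for ",
           where(i), ": child dose ", ped$bmp2[i], " impossible from parents (",
           ped$bmp2[idx[i]], ", ", ped$bmp2[midx[i]], ")")
  }
  ## rare-allele carrier state: inherited carriers need a carrier parent
  bad_sm <- !ped$smad6 %in% c("D", "D*", "N", NA)
  if (any(bad_sm))
    stop("pedigree [", ped$fam[1], "]: smad6 genotype must be D, D*, N or missing")
  for (i in seq_len(nrow(ped))) {
    if (is.na(ped$father[i])) next
    if (identical(ped$smad6[i], "D")) {
      pg <- c(ped$smad6[idx[i]], ped$smad6[midx[i]])
      if (all(!is.na(pg)) && !any(pg %in% c("D", "D*")))
        stop("pedigree [", ped$fam[1], "]: ", where(i),
             " carries the damaging allele but neither parent does ",
             "(flag de novo carriers as 'D*')")
    }
  }
  invisible(TRUE)
}

.ped_cols <- c("fam", "id", "father", "mother", "sex", "affected", "proband",
               "smad6", "bmp2")

#' Read / write two-locus pedigree files
#'
#' The file format is PED-style, whitespace-delimited, without header:
#' the six standard columns (family id, individual id, father id, mother id
#' — `0` for founders —, sex 1/2/0, affection 2 affected / 1 unaffected),
#' a proband flag (1/0), and two genotype columns — damaging-allele carrier
#' state (`D`, `D*` for de novo, `N`, `.` missing) and SNP risk-allele dose
#' (`0`/`1`/`2`, `.` missing).
#'
#' Violations of the pedigree invariants are reported with the offending
#' individual and source line number.
#'
#' @param path file path.
#' @return `read_pedigree` returns a list of `"pedigree"` objects, one per
#'   family, named by family id.
#' @export
read_pedigree <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (!length(keep)) stop("read_pedigree: empty file ", path)
  toks <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(toks)
  if (any(nf != 9))
    stop("read_pedigree: expected 9 whitespace-delimited fields, got ",
         nf[which(nf != 9)[1]], " at line ", keep[which(nf != 9)[1]])
  m <- do.call(rbind, toks)
  aff_code <- m[, 6]
  if (!all(aff_code %in% c("1", "2")))
    stop("read_pedigree: affection must be 1 (unaffected) or 2 (affected), line ",
         keep[which(!aff_code %in% c("1", "2"))[1]])
  df <- data.frame(
    fam = m[, 1], id = m[, 2],
    father = ifelse(m[, 3] == "0", NA, m[, 3]),
    mother = ifelse(m[, 4] == "0", NA, m[, 4]),
    sex = as.integer(m[, 5]),
    affected = aff_code == "2",
    proband = m[, 7] == "1",
    smad6 = ifelse(m[, 8] == ".", NA, m[, 8]),
    bmp2 = suppressWarnings(as.integer(ifelse(m[, 9] == ".", NA, m[, 9]))),
    stringsAsFactors = FALSE)
  out <- lapply(split(seq_len(nrow(df)), factor(df$fam, levels = unique(df$fam))),
                function(ix) {
                  p <- pedigree(df[ix, , drop = FALSE], validate = FALSE)
                  rownames(p) <- NULL
                  validate_pedigree(p, line_offset = keep[ix])
                  p
                })
  out
}

#' @rdname read_pedigree
#' @param peds a `"pedigree"` or list of pedigrees.
#' @export
write_pedigree <- function(peds, path) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  rows <- lapply(peds, function(p) {
    p <- as.data.frame(p)
    paste(p$fam, p$id,
          ifelse(is.na(p$father), "0", p$father),
          ifelse(is.na(p$mother), "0", p$mother),
          p$sex,
          ifelse(p$affected, "2", "1"),
          ifelse(p$proband, "1", "0"),
          ifelse(is.na(p$smad6), ".", p$smad6),
          ifelse(is.na(p$bmp2), ".", p$bmp2))
  })
  writeLines(unlist(rows), path)
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree [%s]: %d members (%d affected, %d founders, %d probands)\n",
              x$fam[1], nrow(x), sum(x$affected), sum(is_founder(x)),
              sum(x$proband)))
  print.data.frame(x, ...)
  invisible(x)
}
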