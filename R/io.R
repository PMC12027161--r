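#' Read a genotype matrix from TSV or VCF
#'
#' TSV: rows = individuals, first column `individual_id`, remaining columns
#' = SNP effect-allele dosages (0/1/2, empty or `NA` = missing). VCF 4.2:
#' one sample column per individual; the per-variant dosage is taken from
#' the GT field. When `sumstats` is supplied, VCF dosages are reconciled
#' with the summary-statistics alleles: the dosage counts the effect
#' allele, flipping when REF/ALT are swapped relative to
#' effect/other allele; variants whose alleles cannot be reconciled are
#' dropped with a warning. Without `sumstats`, the ALT allele count is
#' returned. Missing GT (`./.`) becomes `NA`.
#'
#' @param path File path.
#' @param format `"tsv"` or `"vcf"` (default guessed from the extension).
#' @param sumstats Optional summary statistics for VCF allele
#'   reconciliation.
#' @return Genotype tibble (`individual_id` plus one dosage column per SNP).
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf"),
                           sumstats = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    out <- readr::read_tsv(path, show_col_types = FALSE,
                           progress = FALSE)
    names(out)[1] <- "individual_id"
    out$individual_id <- as.character(out$individual_id)
    geno_matrix(out)  # validates the dosage domain
    return(as_tibble(out))
  }

  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ref <- vcfR::getREF(v); alt <- vcfR::getALT(v)
  ids <- vcfR::getID(v)
  alt_count <- function(x) {
    ifelse(is.na(x) | grepl("\\.", x),
           NA_real_,
           vapply(strsplit(x, "[/|]"), function(a) sum(a == "1"), numeric(1)))
  }
  dos <- apply(gt, 2, alt_count)            # variants x samples
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = nrow(gt))
  dimnames(dos) <- dimnames(gt)

  if (!is.null(sumstats)) {
    m <- match(ids, sumstats$snp_id)
    keep <- !is.na(m)
    ea <- sumstats$effect_allele[m]; oa <- sumstats$other_allele[m]
    straight <- keep & alt == ea & ref == oa
    flipped <- keep & alt == oa & ref == ea
    bad <- keep & !straight & !flipped
    if (any(bad)) {
      warn(sprintf("dropping %d variant(s) with irreconcilable alleles: %s",
                   sum(bad), paste(head(ids[bad], 5), collapse = ", ")))
    }
    dos[flipped, ] <- 2 - dos[flipped, , drop = FALSE]
    dos <- dos[straight | flipped, , drop = FALSE]
    ids <- ids[straight | flipped]
  }
  m <- t(dos)
  colnames(m) <- ids
  geno_tibble(m)
}

#' Write a genotype matrix as TSV or minimal VCF 4.2
#'
#' The VCF writer emits one record per SNP with REF = other allele,
#' ALT = effect allele, a GT-only FORMAT, and one sample column per
#' individual (dosage 0 -> `0/0`, 1 -> `0/1`, 2 -> `1/1`,
#' missing -> `./.`).
#'
#' @param geno Genotype tibble.
#' @param path Output path.
#' @param format `"tsv"` or `"vcf"`.
#' @param sumstats Summary statistics supplying the alleles (required for
#'   VCF output).
#' @return The path, invisibly.
#' @export
write_genotypes <- function(geno, path, format = c("tsv", "vcf"),
                            sumstats = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(geno, path, progress = FALSE)
    return(invisible(path))
  }
  if (is.null(sumstats)) abort("VCF output needs `sumstats` for the alleles")
  m <- geno_matrix(geno)
  snps <- colnames(m)
  st <- sumstats[match(snps, sumstats$snp_id), ]
  if (anyNA(st$snp_id)) abort("summary statistics missing some SNPs")
  gt_code <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(m)), collapse = "\t")
  )
  body <- vapply(seq_along(snps), function(j) {
    gts <- ifelse(is.na(m[, j]), "./.", gt_code[m[, j] + 1])
    paste(c("1", j, snps[j], st$other_allele[j], st$effect_allele[j],
            ".", "PASS", ".", "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read/write GWAS-style summary statistics as TSV
#'
#' The on-disk header is `SNP`, `A1` (effect allele), `A2` (other allele),
#' `BETA`, optionally `MAF`.
#'
#' @param path File path.
#' @return `read_summary_stats()`: tibble with `snp_id`, `effect_allele`,
#'   `other_allele`, `beta` (and `maf` when present).
#' @export
read_summary_stats <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("SNP", "A1", "A2", "BETA")
  if (!all(need %in% names(x))) {
    abort(paste("summary statistics need columns",
                paste(need, collapse = ", ")))
  }
  out <- tibble(snp_id = as.character(x$SNP), effect_allele = x$A1,
                other_allele = x$A2, beta = as.numeric(x$BETA))
  if ("MAF" %in% names(x)) out$maf <- as.numeric(x$MAF)
  out
}

#' @rdname read_summary_stats
#' @param sumstats Summary-statistics tibble.
#' @export
write_summary_stats <- function(sumstats, path) {
  out <- tibble(SNP = sumstats$snp_id, A1 = sumstats$effect_allele,
                A2 = sumstats$other_allele, BETA = sumstats$beta)
  if ("maf" %in% names(sumstats)) out$MAF <- sumstats$maf
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read/write a phenotype table as TSV
#'
#' Columns: `individual_id`, `label` (case/control), `age`, `sex` (0 =
#' female, 1 = male), `smoker`, `diabetes` (0/1), `cholesterol` (mmol/L).
#'
#' @param path File path.
#' @return `read_phenotypes()`: the encoded phenotype tibble.
#' @export
read_phenotypes <- function(path) {
  encode_phenotypes(readr::read_tsv(path, show_col_types = FALSE,
                                    progress = FALSE))
}

#' @rdname read_phenotypes
#' @param pheno Phenotype tibble.
#' @export
write_phenotypes <- function(pheno, path) {
  readr::write_tsv(pheno, path, progress = FALSE)
  invisible(path)
}

#' Write every table of a simulated cohort to a directory
#'
#' Emits `genotypes.tsv`, `apoe.tsv`, `phenotypes.tsv`, `sumstats.tsv` and
#' a `provenance.json` echoing the simulation parameters (and any planted
#' QC-violation ids).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "load_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genotypes(cohort$genotypes, file.path(dir, "genotypes.tsv"))
  readr::write_tsv(cohort$apoe, file.path(dir, "apoe.tsv"), progress = FALSE)
  write_phenotypes(cohort$phenotypes, file.path(dir, "phenotypes.tsv"))
  write_summary_stats(cohort$sumstats, file.path(dir, "sumstats.tsv"))
  prov <- list(params = unclass(cohort$params),
               planted = attr(cohort$genotypes, "planted"))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
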