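#' Write a simulated cohort to standard interchange files
#'
#' Emits plain-text files into \code{out_dir}: \code{genotypes.vcf}
#' (VCF 4.2, one \code{DS} dosage FORMAT field per sample),
#' \code{sumstats.tsv} (tab-delimited, header
#' \code{SNP CHR BP A1 A2 BETA SE P MAF}), \code{phenotypes.tsv}
#' (FAM-like: \code{FID IID FATHER MOTHER SEX STATUS AGE APOE}; STATUS 2 =
#' affected, 1 = unaffected; APOE coded as the sorted allele pair, e.g.
#' \code{34} for e3/e4) and \code{covariates.tsv} (IID plus principal
#' components). Numeric columns are written at full double precision so files
#' round-trip losslessly through [read_dosage_vcf()], [read_sumstats()] and
#' [read_phenotypes()].
#'
#' @param cohort,panel,stats outputs of [simulate_cohort()] and
#'   [generate_summary_stats()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, panel, stats, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vcf_path <- file.path(out_dir, "genotypes.vcf")
  ss_path <- file.path(out_dir, "sumstats.tsv")
  ph_path <- file.path(out_dir, "phenotypes.tsv")

  s <- panel$snps
  dos <- panel$dosage
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(dos)), collapse = "\t"))
  if (nrow(s) > 0 && nrow(dos) > 0) {
    body <- vapply(seq_len(nrow(s)), function(j) {
      paste(c(s$chr[j], s$pos[j], s$id[j], s$ref[j], s$alt[j], ".", "PASS",
              ".", "DS", format(dos[, j], trim = TRUE, scientific = FALSE)),
            collapse = "\t")
    }, character(1))
  } else body <- character(0)
  writeLines(c(header, body), vcf_path)

  full_prec <- function(df) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
    df
  }
  utils::write.table(full_prec(stats), ss_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ph <- data.frame(FID = cohort$fid, IID = cohort$iid, FATHER = cohort$father,
                   MOTHER = cohort$mother, SEX = cohort$sex,
                   STATUS = ifelse(cohort$affected, 2L, 1L),
                   AGE = cohort$age, APOE = cohort$apoe,
                   stringsAsFactors = FALSE)
  utils::write.table(full_prec(ph), ph_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  cv_path <- file.path(out_dir, "covariates.tsv")
  pcn <- grep("^PC[0-9]+$", names(cohort), value = TRUE)
  cv <- cbind(data.frame(IID = cohort$iid, stringsAsFactors = FALSE),
              cohort[, pcn, drop = FALSE])
  utils::write.table(full_prec(cv), cv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(vcf = vcf_path, sumstats = ss_path, phenotypes = ph_path,
              covariates = cv_path))
}

#' Read a dosage VCF into SNP metadata and a dosage matrix
#'
#' Reads a VCF whose FORMAT field carries a per-sample \code{DS} dosage, as
#' written by [write_cohort()], via \pkg{vcfR}.
#'
#' @param path VCF file path.
#' @return list with \code{snps} (id, chr, pos, ref, alt) and \code{dosage}
#'   (individuals x SNPs numeric matrix, rownames = sample IDs).
#' @export
read_dosage_vcf <- function(path) {
  lines <- readLines(path, n = 10000L)
  n_rec <- sum(!startsWith(lines, "#"))
  if (n_rec == 0 && length(lines) < 10000L) {
    hdr <- lines[startsWith(lines, "#CHROM")]
    samples <- strsplit(hdr, "\t")[[1]][-(1:9)]
    return(list(snps = data.frame(id = character(0), chr = character(0),
                                  pos = integer(0), ref = character(0),
                                  alt = character(0), stringsAsFactors = FALSE),
                dosage = matrix(numeric(0), length(samples), 0,
                                dimnames = list(samples, NULL))))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  rownames(ds) <- fix$ID
  list(snps = data.frame(id = fix$ID, chr = fix$CHROM, pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE),
       dosage = t(ds))
}

#' Read a summary-statistics table
#'
#' @param path tab-delimited file with header SNP CHR BP A1 A2 BETA SE P MAF.
#' @return data.frame of per-SNP weights.
#' @export
read_sumstats <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(CHR = "character"))
}

#' Read a FAM-like phenotype table
#'
#' @param path tab-delimited file written by [write_cohort()].
#' @return data.frame with FID, IID, FATHER, MOTHER, SEX, STATUS, AGE, APOE.
#' @export
read_phenotypes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(APOE = "character"))
}
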