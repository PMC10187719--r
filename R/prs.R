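#' Clumping + thresholding parameters
#'
#' @param p_threshold keep SNPs with association p-value at or below this.
#' @param r2_max LD r-squared bound: a retained SNP removes neighbours with
#'   \code{r2 >= r2_max}.
#' @param window_bp clumping window in base pairs.
#' @param maf_min minimum minor allele frequency.
#' @return list of class \code{clump_params}.
#' @export
clump_params <- function(p_threshold = 0.1, r2_max = 0.2, window_bp = 250000,
                         maf_min = 0.01) {
  stopifnot(p_threshold > 0, p_threshold <= 1, r2_max > 0, r2_max < 1,
            window_bp > 0, maf_min >= 0, maf_min < 0.5)
  structure(list(p_threshold = p_threshold, r2_max = r2_max,
                 window_bp = window_bp, maf_min = maf_min),
            class = "clump_params")
}

#' The canonical APOE exclusion region
#'
#' The 2 MB window flanking APOE on GRCh38: chromosome 19,
#' 42,905,791-46,909,393.
#' @return list with chr, start, end, build.
#' @export
apoe_exclusion_region <- function() {
  list(chr = "19", start = 42905791L, end = 46909393L, build = "GRCh38")
}

#' Greedy LD clumping of GWAS summary statistics
#'
#' Standard clumping+thresholding index-SNP selection: SNPs failing the MAF or
#' p-value filter are dropped; remaining SNPs are visited in ascending p-value
#' order (ties broken by SNP id), each retained SNP removing all not-yet-kept
#' SNPs on the same chromosome within \code{window_bp} whose dosage r-squared
#' with it (computed from the genotype panel) is at least \code{r2_max}.
#'
#' @param stats summary statistics (SNP, CHR, BP, P, MAF columns used).
#' @param panel a \code{genotype_panel} supplying LD.
#' @param params a [clump_params()].
#' @return list with \code{retained} (character vector of SNP ids) and
#'   \code{report} (per-SNP status: retained / filtered_maf / filtered_p /
#'   removed_ld, with the index SNP responsible for each LD removal).
#' @export
clump_snps <- function(stats, panel, params = clump_params()) {
  idx <- match(stats$SNP, panel$snps$id)
  if (all(is.na(idx))) stop("no overlap between summary statistics and genotype panel")
  st <- stats[!is.na(idx), , drop = FALSE]
  status <- rep(NA_character_, nrow(st))
  removed_by <- rep(NA_character_, nrow(st))
  status[st$MAF < params$maf_min] <- "filtered_maf"
  status[is.na(status) & st$P > params$p_threshold] <- "filtered_p"

  cand <- which(is.na(status))
  ord <- cand[order(st$P[cand], st$SNP[cand])]
  alive <- rep(TRUE, nrow(st))
  dose <- panel$dosage[, match(st$SNP, panel$snps$id), drop = FALSE]
  for (i in ord) {
    if (!alive[i] || !is.na(status[i])) next
    status[i] <- "retained"
    near <- which(alive & is.na(status) &
                    st$CHR == st$CHR[i] &
                    abs(st$BP - st$BP[i]) <= params$window_bp)
    if (length(near)) {
      r2 <- suppressWarnings(as.numeric(stats::cor(dose[, i], dose[, near]))^2)
      hit <- near[!is.na(r2) & r2 >= params$r2_max]
      status[hit] <- "removed_ld"
      removed_by[hit] <- st$SNP[i]
      alive[hit] <- FALSE
    }
  }
  report <- data.frame(SNP = st$SNP, status = status, removed_by = removed_by,
                       stringsAsFactors = FALSE)
  list(retained = st$SNP[status == "retained"], report = report)
}

#' Compute raw polygenic scores from weights and dosages
#'
#' \code{score_i = sum_j beta_j * d_ij} over the weight SNPs resolvable in the
#' panel and outside the exclusion region. Alleles are normalized: a weight
#' whose effect allele matches the panel's counted (alt) allele contributes
#' directly; one reported on the opposite allele contributes through the
#' complementary dosage \code{2 - d}. Weights whose allele pair matches
#' neither orientation are dropped with a warning. Missing dosages contribute
#' the SNP's mean dosage.
#'
#' @param panel a \code{genotype_panel}.
#' @param weights data.frame with SNP, A1 (effect allele), A2, BETA; typically
#'   summary statistics restricted to the clumped SNP set.
#' @param exclusion exclusion region as from [apoe_exclusion_region()], or
#'   \code{NULL} for none.
#' @return numeric score vector named by individual id, with attributes
#'   \code{n_snps_used} and \code{dropped} (unresolvable SNP ids).
#' @export
compute_prs <- function(panel, weights, exclusion = apoe_exclusion_region()) {
  s <- panel$snps
  j <- match(weights$SNP, s$id)
  w <- weights[!is.na(j), , drop = FALSE]
  j <- j[!is.na(j)]
  if (!is.null(exclusion)) {
    inside <- s$chr[j] == exclusion$chr & s$pos[j] >= exclusion$start &
      s$pos[j] <= exclusion$end
    w <- w[!inside, , drop = FALSE]
    j <- j[!inside]
  }
  direct <- w$A1 == s$alt[j] & w$A2 == s$ref[j]
  flipped <- w$A1 == s$ref[j] & w$A2 == s$alt[j]
  bad <- !direct & !flipped
  dropped_ids <- w$SNP[bad]
  if (any(bad)) {
    warning(sprintf("%d weight SNP(s) with unresolvable alleles dropped: %s",
                    sum(bad), paste(utils::head(dropped_ids, 5), collapse = ", ")))
    w <- w[!bad, , drop = FALSE]; j <- j[!bad]
    direct <- direct[!bad]
  }
  n <- nrow(panel$dosage)
  score <- numeric(n)
  if (nrow(w)) {
    D <- panel$dosage[, j, drop = FALSE]
    # mean-impute missing dosages per SNP
    if (anyNA(D)) {
      mu <- colMeans(D, na.rm = TRUE)
      na_idx <- which(is.na(D), arr.ind = TRUE)
      D[na_idx] <- mu[na_idx[, 2]]
    }
    # effect-allele dosage: alt-counted directly, or 2 - d on the flipped strand
    beta <- w$BETA
    score <- as.numeric(D %*% (beta * ifelse(direct, 1, -1))) +
      sum(2 * beta[!direct])
  }
  names(score) <- rownames(panel$dosage)
  attr(score, "n_snps_used") <- nrow(w)
  attr(score, "dropped") <- dropped_ids
  score
}

#' Residualize scores on covariates
#'
#' Least-squares regression of the score on the covariates plus an intercept;
#' returns the residuals, which are orthogonal to the covariates. Collinear
#' covariate columns are dropped with a warning.
#'
#' @param scores numeric vector.
#' @param covariates numeric matrix or data.frame (e.g. the first three
#'   principal components); \code{NULL} or all-zero columns reduce to centering.
#' @return adjusted (residual) scores, same length and names as input.
#' @export
adjust_covariates <- function(scores, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0)
    return(scores - mean(scores))
  X <- as.matrix(covariates)
  # constant columns carry no information; drop them quietly
  X <- X[, apply(X, 2, stats::sd) > 0, drop = FALSE]
  if (ncol(X) == 0) return(scores - mean(scores))
  X <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- qrX$pivot[-seq_len(qrX$rank)]
    warning("dropping collinear covariate column(s): ",
            paste(colnames(X)[drop_cols], collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  res <- stats::lm.fit(X, scores)$residuals
  names(res) <- names(scores)
  res
}

#' Add the APOE-tag SNP effects to an APOE-excluded PRS
#'
#' \code{PRS.AD_i = PRS_i + beta_e4 * d_e4_i + beta_e2 * d_e2_i}: the
#' APOE-region-excluded score augmented by the two SNPs tagging the e4 and e2
#' alleles. Individuals with a missing APOE dosage get a missing PRS.AD.
#'
#' @param prs numeric base scores.
#' @param apoe_dosages matrix or data.frame with two columns: e4-tag and
#'   e2-tag allele dosages.
#' @param apoe_betas length-2 numeric: effects of the e4-tag and e2-tag SNPs.
#' @return PRS.AD vector.
#' @export
make_prs_ad <- function(prs, apoe_dosages, apoe_betas) {
  stopifnot(length(apoe_betas) == 2, NCOL(apoe_dosages) == 2)
  d <- as.matrix(apoe_dosages)
  out <- prs + d[, 1] * apoe_betas[1] + d[, 2] * apoe_betas[2]
  out[!stats::complete.cases(d)] <- NA_real_
  out
}

#' Quantile bins and percentile ranks
#'
#' Assigns each score a bin 1..k by empirical quantile over the reference set,
#' with bin sizes differing by at most one and exact ties broken by stable
#' id order (so the assignment is deterministic for degenerate inputs).
#'
#' @param scores numeric vector.
#' @param k number of bins (>= 2); 5 for quintiles, 10 for deciles.
#' @param ids tie-breaking identifiers; defaults to names or index order.
#' @return list with \code{bin} (integer 1..k) and \code{pctile} (rank/n in
#'   (0, 1]), both aligned to the input order.
#' @export
bin_quantiles <- function(scores, k = 5, ids = NULL) {
  n <- length(scores)
  if (k < 2) stop("k must be at least 2")
  if (n < k) stop("need at least k scores")
  if (is.null(ids)) ids <- if (!is.null(names(scores))) names(scores) else as.character(seq_len(n))
  ord <- order(scores, ids)
  pos <- integer(n); pos[ord] <- seq_len(n)
  list(bin = as.integer(ceiling(pos * k / n)), pctile = pos / n)
}

#' Score a cohort end-to-end
#'
#' Convenience wrapper over the scoring stages: clump the summary statistics
#' against the panel, compute the APOE-region-excluded raw PRS, residualize on
#' the first \code{k_pcs} principal components, standardize to mean 0 / SD 1,
#' build PRS.AD from the two APOE-tag SNPs, and attach quintile/decile bins and
#' percentile ranks (computed over the full cohort).
#'
#' @param cohort,panel,stats simulated cohort pieces (or file-loaded
#'   equivalents with the same columns).
#' @param params [clump_params()].
#' @param exclusion exclusion region; default the APOE 2 MB window.
#' @param apoe_snp_ids ids of the e4-tag and e2-tag SNPs in \code{stats}.
#' @param k_pcs number of principal-component covariates to adjust for.
#' @return the cohort with columns PRS_RAW, PRS_ADJ, PRS_STD, PRS_AD,
#'   PRS_AD_STD, QUINTILE, DECILE, PCTILE appended; the clump report is in
#'   attribute \code{clump_report}.
#' @export
score_cohort <- function(cohort, panel, stats, params = clump_params(),
                         exclusion = apoe_exclusion_region(),
                         apoe_snp_ids = c("rs429358", "rs7412"), k_pcs = 3) {
  cl <- clump_snps(stats, panel, params)
  w <- stats[stats$SNP %in% cl$retained, , drop = FALSE]
  raw <- compute_prs(panel, w, exclusion = exclusion)
  n_used <- attr(raw, "n_snps_used")
  raw <- raw[match(cohort$iid, names(raw))]
  pcs <- as.matrix(cohort[, paste0("PC", seq_len(k_pcs)), drop = FALSE])
  adj <- adjust_covariates(raw, pcs)
  std <- adj / stats::sd(adj)

  ai <- match(apoe_snp_ids, stats$SNP)
  if (anyNA(ai)) stop("APOE-tag SNPs not found in summary statistics")
  pj <- match(apoe_snp_ids, panel$snps$id)
  # orient each APOE-tag effect to the panel's counted allele
  flip <- stats$A1[ai] == panel$snps$ref[pj]
  betas <- stats$BETA[ai] * ifelse(flip, -1, 1)
  d <- panel$dosage[match(cohort$iid, rownames(panel$dosage)), apoe_snp_ids,
                    drop = FALSE]
  prs_ad <- make_prs_ad(adj, d, betas)
  prs_ad_std <- (prs_ad - mean(prs_ad, na.rm = TRUE)) / stats::sd(prs_ad, na.rm = TRUE)

  q5 <- bin_quantiles(std, 5, ids = cohort$iid)
  q10 <- bin_quantiles(std, 10, ids = cohort$iid)
  cohort$PRS_RAW <- unname(raw)
  cohort$PRS_ADJ <- unname(adj)
  cohort$PRS_STD <- unname(std)
  cohort$PRS_AD <- unname(prs_ad)
  cohort$PRS_AD_STD <- unname(prs_ad_std)
  cohort$QUINTILE <- q5$bin
  cohort$DECILE <- q10$bin
  cohort$PCTILE <- q5$pctile
  attr(cohort, "clump_report") <- cl$report
  attr(cohort, "n_snps_used") <- n_used
  cohort
}
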