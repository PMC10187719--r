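#' Simulation configuration for a multiplex family cohort
#'
#' Bundles and validates every parameter of the synthetic cohort generator.
#' The liability of each individual decomposes as
#' \code{g_prs + g_apoe + g_poly + e} with variances \code{r2_prs},
#' \code{r2_apoe}, \code{r2_polygenic} and the residual making the total 1.
#' Affection is assigned by an age-declining liability threshold calibrated to
#' the age-band prevalence schedule (see [assign_onset()]).
#'
#' @param n_families number of two-parent nuclear families.
#' @param sibship_probs probability vector over sibship sizes 2..6.
#' @param n_unrelated number of unrelated (founder) singletons.
#' @param n_snps number of panel SNPs (excluding the two APOE-tag SNPs, which
#'   are always appended on chromosome 19 inside the APOE exclusion region).
#' @param maf_range minor-allele-frequency range for panel SNPs.
#' @param block_size SNPs per LD block; LD is block-diagonal with exchangeable
#'   within-block haplotype correlation \code{block_rho} and zero across blocks.
#' @param block_rho latent (Gaussian-copula) within-block haplotype correlation.
#' @param prop_causal fraction of panel SNPs given nonzero liability effects.
#' @param r2_prs liability variance of the polygenic score component.
#' @param r2_apoe liability variance of the APOE-like major locus.
#' @param r2_polygenic liability variance of the residual shared polygenic
#'   component (sibling correlation 0.5, untagged by the SNP panel).
#' @param apoe_e4_freq,apoe_e2_freq population frequencies of the e4 and e2
#'   alleles (e3 takes the remainder).
#' @param prevalence_schedule named numeric vector: names are age-band lower
#'   edges (years), values the cumulative prevalence reached within the band.
#'   Default 3%/17%/32% at 65-74 / 75-84 / 85+.
#' @param exam_age_range censoring/examination ages are drawn uniformly on
#'   this interval for every individual.
#' @param n_gwas effective sample size of the emulated base GWAS, controlling
#'   summary-statistic noise.
#' @param seed master seed; all generator randomness derives from it.
#' @return a validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_families = 600,
                       sibship_probs = c(0.40, 0.25, 0.20, 0.10, 0.05),
                       n_unrelated = 300,
                       n_snps = 2000,
                       maf_range = c(0.05, 0.5),
                       block_size = 10,
                       block_rho = 0.8,
                       prop_causal = 0.2,
                       r2_prs = 0.068,
                       r2_apoe = 0.052,
                       r2_polygenic = 0.35,
                       apoe_e4_freq = 0.14,
                       apoe_e2_freq = 0.08,
                       prevalence_schedule = c(`65` = 0.03, `75` = 0.17, `85` = 0.32),
                       exam_age_range = c(65, 95),
                       n_gwas = 1e5,
                       seed = 1L) {
  cfg <- list(n_families = as.integer(n_families),
              sibship_probs = sibship_probs / sum(sibship_probs),
              n_unrelated = as.integer(n_unrelated),
              n_snps = as.integer(n_snps),
              maf_range = maf_range, block_size = as.integer(block_size),
              block_rho = block_rho, prop_causal = prop_causal,
              r2_prs = r2_prs, r2_apoe = r2_apoe, r2_polygenic = r2_polygenic,
              apoe_e4_freq = apoe_e4_freq, apoe_e2_freq = apoe_e2_freq,
              prevalence_schedule = prevalence_schedule,
              exam_age_range = exam_age_range,
              n_gwas = n_gwas, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$r2_prs < 0 || cfg$r2_apoe < 0 || cfg$r2_polygenic < 0)
    stop("variance fractions must be non-negative")
  if (cfg$r2_prs + cfg$r2_apoe + cfg$r2_polygenic >= 1)
    stop("liability variance budget exceeded: r2_prs + r2_apoe + r2_polygenic must be < 1")
  ps <- cfg$prevalence_schedule
  if (is.null(names(ps)) || anyNA(as.numeric(names(ps))))
    stop("prevalence_schedule must be named by age-band lower edges")
  if (any(ps <= 0) || any(ps >= 1)) stop("prevalences must be in (0, 1)")
  if (length(ps) > 1 && any(diff(ps) <= 0))
    stop("prevalence_schedule must be strictly increasing with age band")
  if (is.unsorted(as.numeric(names(ps)), strictly = TRUE))
    stop("age-band edges must be strictly increasing")
  f4 <- cfg$apoe_e4_freq; f2 <- cfg$apoe_e2_freq
  if (f4 <= 0 || f4 >= 1 || f2 <= 0 || f2 >= 1 || f4 + f2 >= 1)
    stop("APOE allele frequencies must be in (0,1) with e4 + e2 < 1")
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must lie in (0, 0.5]")
  if (length(cfg$sibship_probs) != 5) stop("sibship_probs covers sizes 2..6")
  invisible(cfg)
}

#' Assign affection status and onset/censoring age from liability
#'
#' Disease onset is deterministic given liability under an age-declining
#' threshold: an individual is affected by age band \code{b} iff their
#' liability exceeds \eqn{T(b) = \Phi^{-1}(1 - K(b))}, where \eqn{K(b)} is the
#' band's cumulative prevalence. Affection is evaluated at each individual's
#' examination age; onset age is drawn uniformly within the first band whose
#' threshold the liability exceeds (never after the exam age). Unaffected
#' individuals are right-censored at the exam age. This construction makes the
#' population cumulative incidence piecewise-linear through the schedule values
#' at band ends, giving a closed-form oracle for the survival-curve estimators.
#'
#' @param liability numeric vector of unit-variance liabilities.
#' @param schedule prevalence schedule as in [sim_config()].
#' @param exam_age examination/censoring ages; if \code{NULL}, drawn uniformly
#'   on \code{exam_age_range} (consumes random numbers).
#' @param exam_age_range range for drawn exam ages.
#' @return data.frame with \code{affected} (logical), \code{age} (onset age if
#'   affected, censoring age otherwise) and \code{exam_age}.
#' @export
assign_onset <- function(liability, schedule, exam_age = NULL,
                         exam_age_range = c(65, 95)) {
  n <- length(liability)
  lo <- as.numeric(names(schedule))
  hi <- c(lo[-1], Inf)
  thr <- stats::qnorm(1 - as.numeric(schedule))   # decreasing in band
  if (is.null(exam_age)) exam_age <- stats::runif(n, exam_age_range[1], exam_age_range[2])
  band_at_exam <- findInterval(exam_age, lo)
  affected <- band_at_exam >= 1 & liability > thr[pmax(band_at_exam, 1L)]
  # first band whose threshold the liability exceeds (thresholds decrease)
  onset_band <- rep(NA_integer_, n)
  for (b in rev(seq_along(thr))) onset_band[liability > thr[b]] <- b
  age <- exam_age
  if (any(affected)) {
    ob <- onset_band[affected]
    lower <- lo[ob]
    upper <- pmin(hi[ob], exam_age[affected])
    age[affected] <- lower + stats::runif(sum(affected)) * (upper - lower)
  }
  data.frame(affected = affected, age = age, exam_age = exam_age)
}

# exchangeable-correlation haplotype blocks via a Gaussian copula:
# z_j = sqrt(rho) u + sqrt(1-rho) e_j, allele present iff z_j < qnorm(maf_j)
simulate_haplotypes <- function(n_hap, maf, blocks, rho) {
  H <- matrix(0L, nrow = n_hap, ncol = length(maf))
  for (b in unique(blocks)) {
    cols <- which(blocks == b)
    u <- stats::rnorm(n_hap)
    z <- sqrt(rho) * matrix(u, n_hap, length(cols)) +
      sqrt(1 - rho) * matrix(stats::rnorm(n_hap * length(cols)), n_hap)
    H[, cols] <- 1L * (z < matrix(stats::qnorm(maf[cols]), n_hap, length(cols), byrow = TRUE))
  }
  H
}

# center a raw genetic component and rescale it so its realized variance
# equals the configured target exactly; returns the component and the scale
scale_component <- function(g_raw, target_var) {
  g_raw <- g_raw - mean(g_raw)
  s <- stats::sd(g_raw)
  if (target_var == 0 || s == 0) return(list(g = rep(0, length(g_raw)), scale = 0))
  k <- sqrt(target_var) / s
  list(g = g_raw * k, scale = k)
}

#' Simulate a multiplex family cohort with genotypes
#'
#' Generates two-parent nuclear families (plus unrelated singletons), SNP
#' genotypes by Mendelian transmission of whole LD-block haplotypes from
#' simulated parental haplotypes, an APOE-like three-allele (e2/e3/e4) major
#' locus transmitted Mendelianly, and a unit-variance liability decomposed into
#' a SNP-panel polygenic component, the APOE-locus component, a shared
#' polygenic residual (sibling correlation 0.5) and an independent
#' environmental residual. Affection and onset/censoring ages follow
#' [assign_onset()] under the configured prevalence schedule.
#'
#' Two APOE-tag SNPs (\code{rs429358} for e4, \code{rs7412} for e2) are
#' appended to the panel on chromosome 19 inside the canonical APOE exclusion
#' region; their dosages are the individual's e4 and e2 allele counts.
#'
#' @param config a [sim_config()].
#' @return list with \code{cohort} (data.frame of class \code{fam_cohort}) and
#'   \code{panel} (list of class \code{genotype_panel} with \code{snps}
#'   metadata and a \code{dosage} matrix, individuals x SNPs).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  nf <- config$n_families
  sib_sizes <- sample(2:6, nf, replace = TRUE, prob = config$sibship_probs)
  n_sibs <- sum(sib_sizes)
  n_par <- 2L * nf
  n_unrel <- config$n_unrelated
  n_total <- n_par + n_sibs + n_unrel

  # ---- SNP map: block-diagonal LD, all panel SNPs on chr 1 ----
  m <- config$n_snps
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  blocks <- rep(seq_len(ceiling(m / config$block_size)), each = config$block_size)[seq_len(m)]
  within <- stats::ave(seq_len(m), blocks, FUN = seq_along)
  pos <- (blocks - 1L) * 1000000L + (within - 1L) * 25000L + 1L
  snps <- data.frame(id = sprintf("rs%06d", seq_len(m)),
                     chr = "1", pos = pos, ref = "A", alt = "G",
                     maf = maf, block = blocks, beta_true = 0,
                     stringsAsFactors = FALSE)

  # ---- founder haplotypes and Mendelian transmission ----
  founders <- n_par + n_unrel
  H <- simulate_haplotypes(2L * founders, maf, blocks, config$block_rho)
  founder_dos <- H[seq(1, 2 * founders, 2), , drop = FALSE] +
    H[seq(2, 2 * founders, 2), , drop = FALSE]

  fam_of_sib <- rep(seq_len(nf), sib_sizes)
  child_dos <- matrix(0L, n_sibs, m)
  father_row0 <- 2L * (2L * fam_of_sib - 2L)   # haplotype rows of father: +1, +2
  mother_row0 <- 2L * (2L * fam_of_sib - 1L)
  for (b in unique(blocks)) {
    cols <- which(blocks == b)
    f_rows <- father_row0 + sample(1:2, n_sibs, replace = TRUE)
    m_rows <- mother_row0 + sample(1:2, n_sibs, replace = TRUE)
    child_dos[, cols] <- H[f_rows, cols, drop = FALSE] + H[m_rows, cols, drop = FALSE]
  }

  # individuals ordered: parents (by family), siblings (by family), unrelated
  dos <- rbind(founder_dos[seq_len(n_par), , drop = FALSE],
               child_dos,
               founder_dos[n_par + seq_len(n_unrel), , drop = FALSE])

  # ---- APOE-like locus: alleles 1=e2, 2=e3, 3=e4, Mendelian transmission ----
  afreq <- c(config$apoe_e2_freq, 1 - config$apoe_e2_freq - config$apoe_e4_freq,
             config$apoe_e4_freq)
  founder_al <- matrix(sample(1:3, 2L * founders, replace = TRUE, prob = afreq),
                       founders, 2)
  child_al <- cbind(
    founder_al[cbind(2L * fam_of_sib - 1L, sample(1:2, n_sibs, replace = TRUE))],
    founder_al[cbind(2L * fam_of_sib,      sample(1:2, n_sibs, replace = TRUE))])
  apoe_al <- rbind(founder_al[seq_len(n_par), , drop = FALSE],
                   child_al,
                   founder_al[n_par + seq_len(n_unrel), , drop = FALSE])
  n_e4 <- rowSums(apoe_al == 3L)
  n_e2 <- rowSums(apoe_al == 1L)
  apoe_code <- apply(apoe_al, 1, function(a) paste0(sort(c(2, 3, 4)[a]), collapse = ""))

  # append the two APOE-tag SNPs (inside chr19:42905791-46909393)
  snps <- rbind(snps,
    data.frame(id = c("rs429358", "rs7412"), chr = "19",
               pos = c(44908684L, 44908822L), ref = c("T", "C"), alt = c("C", "T"),
               maf = c(config$apoe_e4_freq, config$apoe_e2_freq),
               block = NA_integer_, beta_true = 0, stringsAsFactors = FALSE))
  dos <- cbind(dos, n_e4, n_e2)
  colnames(dos) <- snps$id

  # ---- liability components ----
  # panel PRS component (causal SNPs drawn outside the APOE region)
  causal <- sample(seq_len(m), size = max(1L, round(config$prop_causal * m)))
  beta0 <- stats::rnorm(length(causal))
  Xc <- sweep(dos[, causal, drop = FALSE], 2, colMeans(dos[, causal, drop = FALSE]))
  comp <- scale_component(as.numeric(Xc %*% beta0), config$r2_prs)
  g_prs <- comp$g
  snps$beta_true[causal] <- beta0 * comp$scale

  # APOE-locus component: e4 risk-increasing, e2 protective at half magnitude
  g_apoe_raw <- (n_e4 - mean(n_e4)) - 0.5 * (n_e2 - mean(n_e2))
  comp_a <- scale_component(g_apoe_raw, config$r2_apoe)
  g_apoe <- comp_a$g
  snps$beta_true[snps$id == "rs429358"] <- comp_a$scale
  snps$beta_true[snps$id == "rs7412"] <- -0.5 * comp_a$scale

  # shared polygenic residual: founders ~ N(0, h); child = midparent + N(0, h/2)
  h <- config$r2_polygenic
  gp_founder <- stats::rnorm(founders, sd = sqrt(h))
  gp_par <- gp_founder[seq_len(n_par)]
  gp_child <- (gp_founder[2L * fam_of_sib - 1L] + gp_founder[2L * fam_of_sib]) / 2 +
    stats::rnorm(n_sibs, sd = sqrt(h / 2))
  g_poly <- c(gp_par, gp_child, gp_founder[n_par + seq_len(n_unrel)])

  e_var <- 1 - config$r2_prs - config$r2_apoe - config$r2_polygenic
  env <- stats::rnorm(n_total, sd = sqrt(e_var))
  liability <- g_prs + g_apoe + g_poly + env

  # ---- identifiers, roles, phenotype ----
  fid_par <- rep(sprintf("F%04d", seq_len(nf)), each = 2)
  fid_sib <- sprintf("F%04d", fam_of_sib)
  fid_unr <- sprintf("U%04d", seq_len(n_unrel))
  fid <- c(fid_par, fid_sib, fid_unr)
  iid <- c(paste0(fid_par, c("_P1", "_P2")),
           paste0(fid_sib, "_S", unlist(lapply(sib_sizes, seq_len))),
           if (n_unrel > 0) paste0(fid_unr, "_X1") else character(0))
  father <- c(rep("0", n_par), paste0(fid_sib, "_P1"), rep("0", n_unrel))
  mother <- c(rep("0", n_par), paste0(fid_sib, "_P2"), rep("0", n_unrel))
  role <- c(rep("parent", n_par), rep("sibling", n_sibs), rep("unrelated", n_unrel))

  sex <- sample(1:2, n_total, replace = TRUE)
  pcs <- matrix(stats::rnorm(3L * n_total), n_total, 3,
                dimnames = list(NULL, paste0("PC", 1:3)))
  onset <- assign_onset(liability, config$prevalence_schedule,
                        exam_age_range = config$exam_age_range)

  cohort <- data.frame(fid = fid, iid = iid, father = father, mother = mother,
                       role = role, sex = sex, apoe = apoe_code,
                       n_e4 = n_e4, n_e2 = n_e2, apoe_e4 = n_e4 > 0,
                       g_prs = g_prs, g_apoe = g_apoe, g_poly = g_poly, env = env,
                       liability = liability,
                       affected = onset$affected, age = onset$age,
                       exam_age = onset$exam_age,
                       stringsAsFactors = FALSE)
  cohort <- cbind(cohort, as.data.frame(pcs))
  class(cohort) <- c("fam_cohort", "data.frame")

  rownames(dos) <- iid
  panel <- structure(list(snps = snps, dosage = dos), class = "genotype_panel")
  list(cohort = cohort, panel = panel)
}

#' Ascertain multiplex families
#'
#' Retains families with at least two affected siblings, of whom at least one
#' has onset after \code{min_onset} (default 60), mirroring multiplex
#' ascertainment of a proband with late onset plus an affected sibling.
#' Unrelated singleton individuals are retained only if affected, and flagged
#' (\code{unrelated_case = TRUE}) rather than treated as family members.
#'
#' @param cohort a cohort from [simulate_cohort()].
#' @param min_onset minimum proband onset age.
#' @return the ascertained cohort; number of retained families in attribute
#'   \code{n_families}.
#' @export
ascertain_families <- function(cohort, min_onset = 60) {
  sibs <- cohort[cohort$role == "sibling", , drop = FALSE]
  keep_fam <- vapply(split(sibs, sibs$fid), function(fs) {
    aff <- fs$affected
    sum(aff) >= 2 && any(aff & fs$age > min_onset)
  }, logical(1))
  fams <- names(keep_fam)[keep_fam]
  in_fam <- cohort$fid %in% fams & cohort$role != "unrelated"
  singleton <- cohort$role == "unrelated" & cohort$affected
  out <- cohort[in_fam | singleton, , drop = FALSE]
  out$unrelated_case <- out$role == "unrelated"
  attr(out, "n_families") <- length(fams)
  class(out) <- c("fam_cohort", "data.frame")
  out
}

#' Emulate base-GWAS summary statistics for the panel
#'
#' Emits one row per panel SNP with observed effect \code{BETA = beta_true +
#' noise}, standard error from the effective GWAS sample size
#' (\code{se = 1/sqrt(2 maf (1-maf) n_gwas)}), and a normal-reference p-value.
#' A random subset of SNPs is emitted with swapped allele labels (and the
#' matching sign flip) to exercise allele normalization in the scorer.
#'
#' @param panel a \code{genotype_panel}.
#' @param n_gwas effective GWAS sample size (larger = less noise).
#' @param flip_frac fraction of SNPs reported on the opposite allele.
#' @param noise if \code{FALSE}, emit the true effects exactly (se still
#'   reported); used for noise-free oracles.
#' @param seed integer seed.
#' @return data.frame with columns SNP, CHR, BP, A1, A2, BETA, SE, P, MAF
#'   (A1 = effect allele).
#' @export
generate_summary_stats <- function(panel, n_gwas = 1e5, flip_frac = 0.3,
                                   noise = TRUE, seed = 1L) {
  set.seed(seed)
  s <- panel$snps
  maf <- pmin(pmax(s$maf, 1e-4), 0.5)
  se <- 1 / sqrt(2 * maf * (1 - maf) * n_gwas)
  beta <- s$beta_true + if (noise) stats::rnorm(nrow(s)) * se else 0
  p <- 2 * stats::pnorm(-abs(beta / se))
  out <- data.frame(SNP = s$id, CHR = s$chr, BP = s$pos,
                    A1 = s$alt, A2 = s$ref, BETA = beta, SE = se, P = p,
                    MAF = s$maf, stringsAsFactors = FALSE)
  flip <- stats::runif(nrow(out)) < flip_frac
  out$A1[flip] <- s$ref[flip]
  out$A2[flip] <- s$alt[flip]
  out$BETA[flip] <- -out$BETA[flip]
  out
}
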