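#' Hardy-Weinberg goodness-of-fit chi-square test
#'
#' Compares observed genotype counts with Hardy-Weinberg expectations
#' (p^2, 2pq, q^2) using a 1-df Pearson chi-square, no continuity correction.
#' Intended for CONTROL-stratum counts: a departure there flags genotyping
#' error rather than association signal.
#'
#' @param counts integer vector `c(n_00, n_01, n_11)` (hom-ref, het,
#'   hom-variant), e.g. from [genotype_counts()].
#' @return list with `chi2`, `p`, `monomorphic`. A monomorphic SNP gets
#'   `chi2 = 0`, `p = 1` and the flag set.
#' @export
hwe_chisq <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 3L, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("HWE test on empty stratum")
  p_ref <- (2 * counts[1L] + counts[2L]) / (2 * n)
  if (p_ref %in% c(0, 1))
    return(list(chi2 = 0, p = 1, monomorphic = TRUE))
  q <- 1 - p_ref
  expected <- n * c(p_ref^2, 2 * p_ref * q, q^2)
  chi2 <- sum((counts - expected)^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
       monomorphic = FALSE)
}

#' Minor allele frequency per SNP
#' @param gm a `genotype_matrix`.
#' @return named numeric vector in [0, 0.5].
#' @export
maf <- function(gm) {
  va <- colMeans(gm$calls, na.rm = TRUE) / 2  # variant allele frequency
  pmin(va, 1 - va)
}

#' Apply pre-association SNP filters
#'
#' Removes SNPs failing Hardy-Weinberg equilibrium in controls
#' (default alpha 0.01), and optionally MAF and call-rate floors.  MAF and
#' call rate are computed over all subjects; HWE over controls only.
#'
#' @param gm a `genotype_matrix`.
#' @param subjects a `subject_table` (control stratum must be non-empty).
#' @param hwe_alpha remove SNPs with control HWE p below this (0 disables).
#' @param maf_min remove SNPs with MAF below this (default 0: pass-through).
#' @param call_rate_min remove SNPs with call rate below this (default 0).
#' @return list with `gm` (filtered `genotype_matrix`) and `report`
#'   (data.frame: snp_id, maf, call_rate, hwe_chi2, hwe_p, monomorphic,
#'   pass, reason). Filters are checked in the order
#'   call_rate, maf, hwe; the first failure is the recorded reason.
#' @export
apply_qc <- function(gm, subjects, hwe_alpha = 0.01,
                     maf_min = 0, call_rate_min = 0) {
  stopifnot(hwe_alpha >= 0, hwe_alpha <= 1)
  controls <- subjects$id[subjects$status == "control"]
  if (!length(controls)) stop("control stratum is empty")
  snps <- snp_ids(gm)
  cr <- call_rate(gm)
  mafs <- maf(gm)
  hwe <- lapply(snps, function(s)
    hwe_chisq(genotype_counts(gm, s, subjects, "control")))
  report <- data.frame(
    snp_id = snps,
    maf = unname(mafs),
    call_rate = unname(cr),
    hwe_chi2 = vapply(hwe, `[[`, 0, "chi2"),
    hwe_p = vapply(hwe, `[[`, 0, "p"),
    monomorphic = vapply(hwe, `[[`, FALSE, "monomorphic"),
    stringsAsFactors = FALSE)
  reason <- rep(NA_character_, length(snps))
  reason[report$hwe_p < hwe_alpha & hwe_alpha > 0] <- "hwe"
  reason[report$maf < maf_min] <- "maf"
  reason[report$call_rate < call_rate_min] <- "call_rate"
  report$pass <- is.na(reason)
  report$reason <- reason
  keep <- snps[report$pass]
  if (!length(keep)) stop("QC removed every SNP in the panel")
  list(gm = subset_genotypes(gm, snps = keep), report = report)
}

#' Write a QC report as TSV
#' @param report the `report` element of [apply_qc()].
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
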