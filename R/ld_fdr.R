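#' Composite LD r-squared between two SNPs
#'
#' Squared Pearson correlation of the 0/1/2 genotype dosage vectors over
#' subjects with non-missing calls at both SNPs (phase-free composite LD).
#'
#' @param gm a `genotype_matrix`.
#' @param snp_i,snp_j SNP ids.
#' @return r-squared in [0, 1]; NA (with a warning) when fewer than 2
#'   complete pairs or either SNP is monomorphic over the complete pairs.
#' @export
genotype_r2 <- function(gm, snp_i, snp_j) {
  gi <- gm$calls[, snp_i]; gj <- gm$calls[, snp_j]
  ok <- !is.na(gi) & !is.na(gj)
  if (sum(ok) < 2L) {
    warning("fewer than 2 complete genotype pairs for ", snp_i, "/", snp_j)
    return(NA_real_)
  }
  if (stats::var(gi[ok]) == 0 || stats::var(gj[ok]) == 0) {
    warning("monomorphic SNP in r2 computation: ", snp_i, "/", snp_j)
    return(NA_real_)
  }
  stats::cor(gi[ok], gj[ok])^2
}

#' Pairwise LD matrix
#' @param gm a `genotype_matrix`.
#' @param snps SNP ids (default all).
#' @return symmetric matrix of genotype r-squared; unit diagonal for
#'   polymorphic SNPs.
#' @export
ld_matrix <- function(gm, snps = snp_ids(gm)) {
  r <- suppressWarnings(
    stats::cor(gm$calls[, snps, drop = FALSE], use = "pairwise.complete.obs"))
  r2 <- r^2
  dimnames(r2) <- list(snps, snps)
  r2
}

#' Greedy LD pruning by significance
#'
#' Processes SNPs in ascending p-value order; a SNP is dropped when its
#' r-squared with an already-retained SNP exceeds `threshold`, so the more
#' significant SNP of a correlated pair survives. Given distinct p-values
#' the result does not depend on the input ordering.
#'
#' @param pvals named numeric vector of p-values (names = SNP ids).
#' @param ld square r-squared matrix covering those SNPs (NA entries are
#'   treated as uncorrelated).
#' @param threshold r-squared above which SNPs are considered redundant
#'   (default 0.8).
#' @return character vector of retained SNP ids, in the original input
#'   order.
#' @export
ld_prune <- function(pvals, ld, threshold = 0.8) {
  stopifnot(!is.null(names(pvals)), all(names(pvals) %in% rownames(ld)))
  ord <- names(pvals)[order(pvals, seq_along(pvals))]
  retained <- character(0)
  for (s in ord) {
    r2 <- ld[s, retained]
    if (!length(retained) || all(is.na(r2) | r2 <= threshold))
      retained <- c(retained, s)
  }
  names(pvals)[names(pvals) %in% retained]
}

#' Benjamini-Hochberg FDR q-values
#'
#' Step-up adjusted p-values: `q_(i) = min_{j >= i} (m * p_(j) / j)`,
#' clipped to 1.  A Storey-type estimator with a fixed lambda is available
#' as an option but BH is the reference behaviour (pi0 estimation is
#' unstable on small panels).
#'
#' @param pvals numeric vector of p-values in [0, 1] (names kept).
#' @param method `"BH"` (default) or `"storey"` (lambda = 0.5).
#' @return data.frame of class `qvalue_table` with columns `snp_id`
#'   (names or index), `p`, `rank`, `q`, in the input order.
#' @export
fdr_qvalues <- function(pvals, method = c("BH", "storey")) {
  method <- match.arg(method)
  if (!length(pvals))
    return(structure(data.frame(snp_id = character(0), p = numeric(0),
                                rank = integer(0), q = numeric(0)),
                     class = c("qvalue_table", "data.frame")))
  stopifnot(all(pvals >= 0 & pvals <= 1))
  m <- length(pvals)
  ord <- order(pvals)
  ps <- pvals[ord]
  q_sorted <- rev(cummin(rev(m * ps / seq_len(m))))
  if (method == "storey") {
    lambda <- 0.5
    pi0 <- min(1, mean(pvals > lambda) / (1 - lambda))
    q_sorted <- q_sorted * pi0
  }
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m); q[ord] <- q_sorted
  rk <- integer(m); rk[ord] <- seq_len(m)
  out <- data.frame(
    snp_id = if (!is.null(names(pvals))) names(pvals) else as.character(seq_len(m)),
    p = unname(pvals), rank = rk, q = q, stringsAsFactors = FALSE)
  class(out) <- c("qvalue_table", "data.frame")
  out
}

#' LD-prune p-values then compute q-values
#'
#' The multiplicity pipeline used downstream: restrict to SNPs surviving
#' greedy LD pruning at `r2_threshold`, then BH-adjust the surviving
#' p-values.
#'
#' @param pvals named p-value vector.
#' @param gm `genotype_matrix` used to compute pairwise r-squared.
#' @param r2_threshold LD redundancy threshold (default 0.8).
#' @param method passed to [fdr_qvalues()].
#' @return a `qvalue_table` over the retained SNPs.
#' @export
prune_and_adjust <- function(pvals, gm, r2_threshold = 0.8, method = "BH") {
  ld <- ld_matrix(gm, names(pvals))
  keep <- ld_prune(pvals, ld, r2_threshold)
  fdr_qvalues(pvals[keep], method = method)
}
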