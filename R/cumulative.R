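#' Unfavorable-genotype direction for a significant SNP
#'
#' Dichotomizes a SNP under its best-fitting model and labels the group that
#' carries the higher case odds as unfavorable: the exposed (variant-
#' carrying) group when OR > 1, its complement when OR < 1.  For additive
#' SNPs the carrier split (any variant allele vs none) is used, oriented by
#' the OR's direction.
#'
#' @param result an `assoc_result` row with a selected model and OR.
#' @return list of class `unfavorable_spec`: `snp_id`, `model`,
#'   `unfavorable_genotypes` (subset of 0:2), `direction` (`"exposed"` or
#'   `"unexposed"`); or NULL (with a message) when OR is exactly 1.
#' @export
unfavorable_direction <- function(result) {
  if (is.na(result$model) || is.na(result$or)) {
    message("SNP ", result$snp_id, " has no usable fit; excluded")
    return(NULL)
  }
  if (result$or == 1) {
    message("SNP ", result$snp_id, " has OR exactly 1; excluded")
    return(NULL)
  }
  exposed <- switch(result$model,
                    dominant = c(1L, 2L),
                    additive = c(1L, 2L),   # carrier split
                    recessive = 2L)
  if (result$or > 1) {
    unf <- exposed; dir <- "exposed"
  } else {
    unf <- setdiff(0:2, exposed); dir <- "unexposed"
  }
  structure(list(snp_id = result$snp_id, model = result$model,
                 unfavorable_genotypes = unf, direction = dir),
            class = "unfavorable_spec")
}

#' Unfavorable-genotype specs for a significant panel
#' @param assoc an `assoc_table`, optionally carrying a `q` column.
#' @param rule `"q"` (default): SNPs with q below `alpha`; `"p"`: p below
#'   `alpha`.
#' @param alpha significance threshold (default 0.05).
#' @return list of `unfavorable_spec` (OR == 1 rows silently dropped).
#' @export
unfavorable_panel <- function(assoc, rule = c("q", "p"), alpha = 0.05) {
  rule <- match.arg(rule)
  if (rule == "q" && is.null(assoc$q))
    stop("rule = 'q' requires a q column (run the multiplicity stage first)")
  keep <- if (rule == "q") !is.na(assoc$q) & assoc$q < alpha
          else !is.na(assoc$p) & assoc$p < alpha
  specs <- lapply(seq_len(nrow(assoc))[keep],
                  function(i) suppressMessages(unfavorable_direction(assoc[i, ])))
  Filter(Negate(is.null), specs)
}

#' Count unfavorable genotypes per subject
#'
#' For each subject, the number of specs whose unfavorable genotype set
#' contains the subject's call; missing genotypes contribute 0.
#'
#' @param gm a `genotype_matrix`.
#' @param specs list of `unfavorable_spec`.
#' @param subjects optional `subject_table` giving the subject order
#'   (default: genotype-matrix order).
#' @return named integer vector of counts per subject.
#' @export
count_unfavorable <- function(gm, specs, subjects = NULL) {
  stopifnot(length(specs) > 0)
  ids <- if (is.null(subjects)) subject_ids(gm) else subjects$id
  counts <- integer(length(ids))
  rows <- match(ids, subject_ids(gm))
  for (sp in specs) {
    g <- gm$calls[rows, sp$snp_id]
    counts <- counts + as.integer(!is.na(g) & g %in% sp$unfavorable_genotypes)
  }
  stats::setNames(counts, ids)
}

#' Quartile risk-group boundaries for unfavorable counts
#'
#' Nearest-rank 25/50/75 percentiles of the pooled count distribution, with
#' tied cut points collapsed upward so every group is non-empty.  Boundaries
#' come back as inclusive integer ranges.
#'
#' @param counts integer vector of per-subject unfavorable counts.
#' @return data.frame with `group`, `lo`, `hi`, `label` (e.g. "3~7");
#'   fewer than 4 groups (with a warning) when the distribution is too
#'   concentrated.
#' @export
quartile_groups <- function(counts) {
  stopifnot(length(counts) > 0)
  xs <- sort(counts)
  n <- length(xs)
  cuts <- unique(xs[ceiling(c(0.25, 0.5, 0.75) * n)])
  cuts <- cuts[cuts < max(xs)]          # a cut at the maximum adds no group
  lo <- c(min(xs), cuts + 1L)
  hi <- c(cuts, max(xs))
  if (length(lo) < 4L)
    warning("fewer than 4 distinct risk groups (", length(lo), ")")
  data.frame(group = seq_along(lo), lo = lo, hi = hi,
             label = ifelse(lo == hi, as.character(lo), paste0(lo, "~", hi)),
             stringsAsFactors = FALSE)
}

#' Assign subjects to risk groups
#' @param counts per-subject unfavorable counts.
#' @param groups data.frame from [quartile_groups()].
#' @return integer group index per subject.
#' @export
assign_risk_group <- function(counts, groups) {
  idx <- findInterval(counts, groups$lo)
  stopifnot(all(idx >= 1L), all(counts <= max(groups$hi)))
  idx
}

#' Risk-group odds ratios and trend test
#'
#' Adjusted logistic OR of each group versus the lowest-count reference
#' group, plus a trend p from a logistic fit with the 0-based group index
#' as a single ordinal term (covariate-adjusted Wald test).
#'
#' @param counts per-subject unfavorable counts, aligned with `subjects`.
#' @param subjects a `subject_table`.
#' @param adjust adjust for age/ethnicity/smoking (default TRUE).
#' @param groups optional precomputed boundaries (data.frame as returned by
#'   [quartile_groups()]); default: quartiles of `counts`.
#' @return data.frame of class `risk_group_table`: group, label, case_n,
#'   control_n, or, ci_low, ci_high, p (reference row has OR 1 and NA p);
#'   attribute `trend_p`.
#' @export
group_or_trend <- function(counts, subjects, adjust = TRUE, groups = NULL) {
  if (is.null(groups)) groups <- quartile_groups(counts)
  gidx <- assign_risk_group(counts, groups)
  y <- as.numeric(subjects$status == "case")
  X0 <- if (adjust) build_design(subjects)
        else matrix(1, length(y), 1L, dimnames = list(NULL, "(Intercept)"))
  rows <- lapply(seq_len(nrow(groups)), function(k) {
    case_n <- sum(y == 1 & gidx == k); control_n <- sum(y == 0 & gidx == k)
    if (k == 1L)
      return(data.frame(group = k, label = groups$label[k], case_n = case_n,
                        control_n = control_n, or = 1, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_))
    sel <- gidx %in% c(1L, k)
    fit <- fit_logistic(y[sel],
                        cbind(X0[sel, , drop = FALSE],
                              grp = as.numeric(gidx[sel] == k)))
    if (!fit$ok || sum(y == 1 & gidx == k) == 0 || sum(y == 0 & gidx == k) == 0) {
      or <- NA_real_; lo <- hi <- pp <- NA_real_
    } else {
      b <- fit$beta["grp"]; se <- fit$se["grp"]
      or <- exp(unname(b)); lo <- exp(unname(b - 1.96 * se))
      hi <- exp(unname(b + 1.96 * se)); pp <- unname(fit$p["grp"])
    }
    data.frame(group = k, label = groups$label[k], case_n = case_n,
               control_n = control_n, or = or, ci_low = lo, ci_high = hi,
               p = pp)
  })
  out <- do.call(rbind, rows)
  trend_fit <- fit_logistic(y, cbind(X0, trend = as.numeric(gidx - 1L)))
  attr(out, "trend_p") <- if (trend_fit$ok) unname(trend_fit$p["trend"]) else NA_real_
  attr(out, "groups") <- groups
  class(out) <- c("risk_group_table", "data.frame")
  out
}

#' Write a risk-group table as TSV
#' @param tab a `risk_group_table`.
#' @param path output path.
#' @export
write_risk_groups <- function(tab, path) {
  df <- as.data.frame(tab)
  df$trend_p <- attr(tab, "trend_p")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
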