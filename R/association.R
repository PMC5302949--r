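#' Genetic model codings
#'
#' Maps variant-allele counts \{0,1,2\} to the predictor used by each genetic
#' model: dominant (any variant allele vs none), recessive (two variant
#' alleles vs fewer), additive (allele dose, 0/1/2).
#'
#' @param g integer vector of genotype calls (NA allowed).
#' @param model `"dominant"`, `"additive"` or `"recessive"`.
#' @return numeric vector; NA preserved.
#' @export
code_genotype <- function(g, model = c("dominant", "additive", "recessive")) {
  model <- match.arg(model)
  switch(model,
         dominant  = as.numeric(g > 0),
         recessive = as.numeric(g == 2),
         additive  = as.numeric(g))
}

.MODELS <- c("dominant", "additive", "recessive")

#' Crude odds ratio with Wald 95% CI from a 2x2 table
#'
#' `or = (a*d)/(b*c)` with `exp(log(or) +/- 1.96 * sqrt(1/a+1/b+1/c+1/d))`.
#' If any cell is zero, the Haldane-Anscombe correction adds 0.5 to all four
#' cells before computing; if the denominator is still zero the OR is
#' flagged infinite rather than raising.
#'
#' @param a exposed cases.
#' @param b unexposed cases.
#' @param c exposed controls.
#' @param d unexposed controls.
#' @return list with `or`, `ci_low`, `ci_high`, `infinite` (logical).
#' @export
crude_or <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (any(c(a, b, c, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  if (b * c == 0)
    return(list(or = Inf, ci_low = NA_real_, ci_high = NA_real_,
                infinite = TRUE))
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or,
       ci_low = exp(log(or) - 1.96 * se),
       ci_high = exp(log(or) + 1.96 * se),
       infinite = FALSE)
}

#' Pearson chi-square on a 2x2 table (1 df, no continuity correction)
#' @param a,b,c,d cell counts as in [crude_or()].
#' @return list with `chi2` and `p`; `p = 1` when a margin is empty.
#' @export
chisq_2x2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)   # avoid integer overflow in (ad-bc)^2
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (n == 0 || r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    return(list(chi2 = 0, p = 1))
  chi2 <- n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
  list(chi2 = chi2, p = stats::pchisq(chi2, 1L, lower.tail = FALSE))
}

#' Dichotomized 2x2 table for a SNP under a binary model coding
#' @param gm a `genotype_matrix`.
#' @param snp_id SNP id.
#' @param subjects a `subject_table`.
#' @param model `"dominant"` or `"recessive"`.
#' @return list `(a, b, c, d)`: exposed cases, unexposed cases, exposed
#'   controls, unexposed controls (complete cases for this SNP).
#' @export
two_by_two <- function(gm, snp_id, subjects, model = "dominant") {
  stopifnot(model %in% c("dominant", "recessive"))
  g <- gm$calls[match(subjects$id, subject_ids(gm)), snp_id]
  x <- code_genotype(g, model)
  case <- subjects$status == "case"
  ok <- !is.na(x)
  list(a = sum(x == 1 & case & ok), b = sum(x == 0 & case & ok),
       c = sum(x == 1 & !case & ok), d = sum(x == 0 & !case & ok))
}

#' Covariate design matrix for adjusted models
#'
#' Intercept + continuous age + indicator sets for ethnicity (reference
#' White) and smoking (reference Never).  Columns constant over the supplied
#' subjects are dropped so the logistic fit stays full rank.
#'
#' @param subjects a `subject_table`.
#' @param covariates character subset of `c("age","ethnicity","smoking")`.
#' @return numeric matrix with an `(Intercept)` first column.
#' @export
build_design <- function(subjects,
                         covariates = c("age", "ethnicity", "smoking")) {
  X <- matrix(1, nrow(subjects), 1L, dimnames = list(NULL, "(Intercept)"))
  if ("age" %in% covariates) X <- cbind(X, age = subjects$age)
  dummy <- function(f, ref) {
    lv <- setdiff(levels(f), ref)
    m <- vapply(lv, function(l) as.numeric(f == l), numeric(length(f)))
    if (length(f) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, lv))
    m
  }
  if ("ethnicity" %in% covariates)
    X <- cbind(X, dummy(subjects$ethnicity, "White"))
  if ("smoking" %in% covariates)
    X <- cbind(X, dummy(subjects$smoking, "Never"))
  keep <- c(TRUE, apply(X[, -1L, drop = FALSE], 2L,
                        function(col) stats::var(col, na.rm = TRUE) > 0))
  X[, keep, drop = FALSE]
}

#' Maximum-likelihood logistic regression
#'
#' Thin wrapper around `stats::glm.fit` returning Wald statistics, with
#' separation / non-convergence flagged instead of raised.
#'
#' @param y binary outcome vector (0/1).
#' @param X design matrix including an intercept column.
#' @return list with `beta`, `se`, `p` (named per column), `converged`,
#'   `separation` and `ok` (`converged && !separation`). When the fit is not
#'   ok the estimates are returned as NA.
#' @export
fit_logistic <- function(y, X) {
  stopifnot(nrow(X) == length(y), all(y %in% 0:1))
  nm <- colnames(X)
  bad <- function() list(beta = stats::setNames(rep(NA_real_, ncol(X)), nm),
                         se = stats::setNames(rep(NA_real_, ncol(X)), nm),
                         p = stats::setNames(rep(NA_real_, ncol(X)), nm),
                         converged = FALSE, separation = TRUE, ok = FALSE)
  if (length(unique(y)) < 2L) return(bad())
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(X, y, family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit)) return(bad())
  beta <- stats::setNames(fit$coefficients, nm)
  mu <- fit$fitted.values
  w <- mu * (1 - mu)
  separation <- any(abs(beta) > 15, na.rm = TRUE) ||
    max(mu) > 1 - 1e-10 || min(mu) < 1e-10
  if (!fit$converged || separation || anyNA(beta)) return(bad())
  XtWX <- crossprod(X * sqrt(w))
  cov <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
  if (is.null(cov)) return(bad())
  se <- stats::setNames(sqrt(diag(cov)), nm)
  z <- beta / se
  list(beta = beta, se = se,
       p = stats::setNames(2 * stats::pnorm(-abs(z)), nm),
       converged = TRUE, separation = FALSE, ok = TRUE)
}

# Fit one genetic model for one SNP; complete cases for that SNP.
.fit_snp_model <- function(gm, snp_id, subjects, model, adjust = TRUE,
                           covariates = c("age", "ethnicity", "smoking")) {
  g <- gm$calls[match(subjects$id, subject_ids(gm)), snp_id]
  ok <- !is.na(g) & !is.na(subjects$age)
  sub <- subjects[ok, , drop = FALSE]
  x <- code_genotype(g[ok], model)
  y <- as.numeric(sub$status == "case")
  X <- if (adjust) build_design(sub, covariates)
       else matrix(1, length(y), 1L, dimnames = list(NULL, "(Intercept)"))
  if (stats::var(x) == 0)
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                p = NA_real_, ok = FALSE))
  fit <- fit_logistic(y, cbind(X, snp = x))
  if (!fit$ok)
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                p = NA_real_, ok = FALSE))
  b <- fit$beta["snp"]; se <- fit$se["snp"]
  list(or = exp(b), ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
       p = unname(fit$p["snp"]), ok = TRUE)
}

#' Best-fitting genetic model for one SNP
#'
#' Fits dominant, additive and recessive covariate-adjusted logistic models
#' and reports the model with the smallest Wald p.  When the homozygous
#' variant genotype is rare — fewer than `min_homozygote` subjects (or
#' percent, see `hom_rule`) in cases or in controls — only the dominant
#' model is considered, as it retains the most power.  Ties break toward
#' additive, then dominant, then recessive.
#'
#' @param gm a `genotype_matrix`.
#' @param snp_id SNP id (should have passed QC).
#' @param subjects a `subject_table`.
#' @param min_homozygote threshold for the rare-homozygote rule (default 5).
#' @param hom_rule `"count"` (default: fewer than `min_homozygote` subjects)
#'   or `"percent"` (fewer than `min_homozygote` percent of the stratum).
#' @param adjust adjust for age, ethnicity and smoking (default TRUE).
#' @return one-row data.frame of class `assoc_result`: snp_id, gene, model,
#'   or, ci_low, ci_high, p, crude_or, models_considered
#'   (comma-separated), note (`"full"` / `"dominant_only"` / `"no_fit"`).
#' @export
best_model_select <- function(gm, snp_id, subjects, min_homozygote = 5,
                              hom_rule = c("count", "percent"),
                              adjust = TRUE) {
  hom_rule <- match.arg(hom_rule)
  cc <- genotype_counts(gm, snp_id, subjects, "case")
  ct <- genotype_counts(gm, snp_id, subjects, "control")
  hom_stat <- if (hom_rule == "count") c(cc["n_11"], ct["n_11"])
              else 100 * c(cc["n_11"] / sum(cc), ct["n_11"] / sum(ct))
  dominant_only <- any(hom_stat < min_homozygote)
  models <- if (dominant_only) "dominant" else .MODELS
  fits <- lapply(models, function(m)
    .fit_snp_model(gm, snp_id, subjects, m, adjust = adjust))
  names(fits) <- models
  ps <- vapply(fits, `[[`, 0, "p")
  okv <- vapply(fits, `[[`, FALSE, "ok")
  gene <- if (!is.null(gm$annotation)) {
    g <- gm$annotation$gene[gm$annotation$snp_id == snp_id]
    if (length(g)) g else NA_character_
  } else NA_character_
  if (!any(okv)) {
    res <- data.frame(snp_id = snp_id, gene = gene, model = NA_character_,
                      or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      p = NA_real_, crude_or = NA_real_,
                      models_considered = paste(models, collapse = ","),
                      note = "no_fit", stringsAsFactors = FALSE)
    class(res) <- c("assoc_result", "data.frame")
    return(res)
  }
  # argmin over converged fits; tie-break order additive > dominant > recessive
  pref <- c(additive = 1L, dominant = 2L, recessive = 3L)
  cand <- models[okv]
  best <- cand[order(ps[cand], pref[cand])][1L]
  f <- fits[[best]]
  ctab <- if (best == "additive") two_by_two(gm, snp_id, subjects, "dominant")
          else two_by_two(gm, snp_id, subjects, best)
  cor_ <- crude_or(ctab$a, ctab$b, ctab$c, ctab$d)
  res <- data.frame(snp_id = snp_id, gene = gene, model = best,
                    or = unname(f$or), ci_low = unname(f$ci_low),
                    ci_high = unname(f$ci_high), p = f$p,
                    crude_or = cor_$or,
                    models_considered = paste(models, collapse = ","),
                    note = if (dominant_only) "dominant_only" else "full",
                    stringsAsFactors = FALSE)
  class(res) <- c("assoc_result", "data.frame")
  res
}

#' Per-SNP association over a whole panel
#'
#' Runs [best_model_select()] for every SNP and returns a Table-2-style
#' data.frame, ordered as in the panel.
#'
#' @inheritParams best_model_select
#' @return data.frame of class `assoc_table` (one row per SNP).
#' @export
associate_panel <- function(gm, subjects, min_homozygote = 5,
                            hom_rule = "count", adjust = TRUE) {
  check_cohort(gm, subjects)
  rows <- lapply(snp_ids(gm), function(s)
    best_model_select(gm, s, subjects, min_homozygote = min_homozygote,
                      hom_rule = hom_rule, adjust = adjust))
  out <- do.call(rbind, rows)
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Write an association table as TSV
#' @param tab an `assoc_table` (optionally with q-value/bootstrap columns).
#' @param path output path.
#' @export
write_assoc_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
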