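# Deterministic 31-bit substream seed from a master seed and a string key,
# so per-SNP bootstrap results do not depend on panel order.
substream_seed <- function(master, key) {
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(master) * 48271 + h) %% 2147483647)
}

#' Bootstrap internal validation of a per-SNP association
#'
#' Draws `B` resamples of whole subjects with replacement (original size,
#' cases and controls pooled), refits the SNP's SELECTED model — with the
#' same covariate adjustment — on each resample, and counts resamples whose
#' Wald p falls below 0.05 / 0.01 / 0.001.  Replicates where the fit is
#' degenerate (monomorphic resample, separation) count as NOT significant.
#'
#' @param gm a `genotype_matrix`.
#' @param subjects a `subject_table`.
#' @param result an `assoc_result` row from [best_model_select()].
#' @param B number of resamples (default 100).
#' @param seed master seed; the SNP id spawns an independent substream.
#' @param adjust covariate adjustment in the refits (default TRUE).
#' @return list with `snp_id`, `B`, `n_p05`, `n_p01`, `n_p001`,
#'   `boot_or_median`, `boot_ci` (percentile 2.5/97.5), `n_degenerate`.
#' @export
bootstrap_validate <- function(gm, subjects, result, B = 100, seed = 1,
                               adjust = TRUE) {
  stopifnot(B >= 0)
  snp <- result$snp_id
  model <- result$model
  if (is.na(model)) stop("result carries no selected model for ", snp)
  if (B == 0)
    return(list(snp_id = snp, B = 0L, n_p05 = 0L, n_p01 = 0L, n_p001 = 0L,
                boot_or_median = NA_real_, boot_ci = c(NA_real_, NA_real_),
                n_degenerate = 0L))
  n <- nrow(subjects)
  set.seed(substream_seed(seed, snp))
  ps <- ors <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    sub <- subjects[idx, , drop = FALSE]
    sub$id <- subjects$id[idx]          # keep genotype linkage, allow dups
    g <- gm$calls[match(sub$id, subject_ids(gm)), snp]
    ok <- !is.na(g) & !is.na(sub$age)
    x <- code_genotype(g[ok], model)
    y <- as.numeric(sub$status[ok] == "case")
    if (length(unique(x)) < 2L || length(unique(y)) < 2L) next
    X <- if (adjust) build_design(sub[ok, , drop = FALSE])
         else matrix(1, sum(ok), 1L, dimnames = list(NULL, "(Intercept)"))
    fit <- fit_logistic(y, cbind(X, snp = x))
    if (!fit$ok) next
    ps[b] <- fit$p["snp"]
    ors[b] <- exp(fit$beta["snp"])
  }
  degenerate <- sum(is.na(ps))
  out <- list(snp_id = snp, B = as.integer(B),
              n_p05 = sum(ps < 0.05, na.rm = TRUE),
              n_p01 = sum(ps < 0.01, na.rm = TRUE),
              n_p001 = sum(ps < 0.001, na.rm = TRUE),
              boot_or_median = stats::median(ors, na.rm = TRUE),
              boot_ci = unname(stats::quantile(ors, c(0.025, 0.975),
                                               na.rm = TRUE, names = FALSE)),
              n_degenerate = as.integer(degenerate))
  stopifnot(out$n_p001 <= out$n_p01, out$n_p01 <= out$n_p05, out$n_p05 <= B)
  out
}

#' Bootstrap validation across an association table
#' @param gm,subjects cohort data.
#' @param assoc an `assoc_table` from [associate_panel()].
#' @param B,seed,adjust see [bootstrap_validate()].
#' @return `assoc` with columns `boot_p05`, `boot_p01`, `boot_p001`,
#'   `boot_or_median` appended (NA for rows without a selected model).
#' @export
bootstrap_panel <- function(gm, subjects, assoc, B = 100, seed = 1,
                            adjust = TRUE) {
  res <- lapply(seq_len(nrow(assoc)), function(i) {
    if (is.na(assoc$model[i]) || B == 0)
      return(list(n_p05 = NA_integer_, n_p01 = NA_integer_,
                  n_p001 = NA_integer_, boot_or_median = NA_real_))
    bootstrap_validate(gm, subjects, assoc[i, ], B = B, seed = seed,
                       adjust = adjust)
  })
  assoc$boot_p05 <- vapply(res, function(r) as.integer(r$n_p05), 1L)
  assoc$boot_p01 <- vapply(res, function(r) as.integer(r$n_p01), 1L)
  assoc$boot_p001 <- vapply(res, function(r) as.integer(r$n_p001), 1L)
  assoc$boot_or_median <- vapply(res, function(r) as.numeric(r$boot_or_median), 1)
  assoc
}

#' Percentile bootstrap CI for a group odds ratio
#'
#' Resamples subjects with replacement and recomputes the odds ratio of
#' `group == comparison` vs `group == reference` each time; with covariates
#' the OR comes from an adjusted logistic fit, otherwise from the 2x2
#' cross-product.  Resamples where either group is empty (or the fit is
#' degenerate) are redrawn, up to `max_retries` total.
#'
#' @param group factor/character group assignment per subject.
#' @param outcome binary vector (1 = case).
#' @param covariates optional data.frame of adjustment covariates
#'   (a `subject_table` works; its id/status columns are ignored).
#' @param B resample count (default 10000).
#' @param seed RNG seed.
#' @param reference reference group label (default first factor level).
#' @param comparison comparison group label (default second level).
#' @param max_retries cap on redraws across the run (default `B`).
#' @return list with `ci` = c(low, high) (percentile 2.5/97.5), `or_median`,
#'   `B`, `n_retries`.
#' @export
bootstrap_or_ci <- function(group, outcome, covariates = NULL, B = 10000,
                            seed = 1, reference = NULL, comparison = NULL,
                            max_retries = B) {
  group <- as.factor(group)
  stopifnot(nlevels(group) >= 2L, all(outcome %in% 0:1),
            length(group) == length(outcome))
  if (is.null(reference)) reference <- levels(group)[1L]
  if (is.null(comparison)) comparison <- setdiff(levels(group), reference)[1L]
  keep <- group %in% c(reference, comparison)
  group <- droplevels(factor(group[keep], levels = c(reference, comparison)))
  outcome <- outcome[keep]
  if (!is.null(covariates)) covariates <- covariates[keep, , drop = FALSE]
  n <- length(outcome)
  set.seed(seed)
  ors <- rep(NA_real_, B)
  retries <- 0L
  one_or <- function(idx) {
    g <- group[idx]; y <- outcome[idx]
    if (!all(table(g) > 0)) return(NA_real_)
    if (is.null(covariates)) {
      a <- sum(y == 1 & g == comparison); b <- sum(y == 1 & g == reference)
      cc <- sum(y == 0 & g == comparison); d <- sum(y == 0 & g == reference)
      crude_or(a, b, cc, d)$or
    } else {
      X <- .covariate_design(covariates[idx, , drop = FALSE])
      fit <- fit_logistic(y, cbind(X, grp = as.numeric(g == comparison)))
      if (!fit$ok) NA_real_ else exp(unname(fit$beta["grp"]))
    }
  }
  b <- 1L
  while (b <= B) {
    v <- one_or(sample.int(n, n, replace = TRUE))
    if (is.na(v) || !is.finite(v)) {
      retries <- retries + 1L
      if (retries > max_retries) stop("bootstrap_or_ci: retry cap exceeded")
      next
    }
    ors[b] <- v
    b <- b + 1L
  }
  list(ci = unname(stats::quantile(ors, c(0.025, 0.975), names = FALSE)),
       or_median = stats::median(ors), B = as.integer(B),
       n_retries = retries)
}

# Design matrix from an arbitrary covariate frame: numeric columns pass
# through, factors/characters expand to treatment dummies; id/status dropped.
.covariate_design <- function(df) {
  df <- as.data.frame(df)
  df <- df[, setdiff(names(df), c("id", "status")), drop = FALSE]
  X <- matrix(1, nrow(df), 1L, dimnames = list(NULL, "(Intercept)"))
  for (nm in names(df)) {
    col <- df[[nm]]
    if (is.numeric(col)) {
      if (stats::var(col, na.rm = TRUE) > 0) {
        X <- cbind(X, col); colnames(X)[ncol(X)] <- nm
      }
    } else {
      f <- as.factor(col)
      for (l in levels(f)[-1L]) {
        v <- as.numeric(f == l)
        if (stats::var(v) > 0) {
          X <- cbind(X, v); colnames(X)[ncol(X)] <- paste0(nm, l)
        }
      }
    }
  }
  X
}
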