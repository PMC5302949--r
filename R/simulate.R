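#' Configuration for a synthetic matched case-control cohort
#'
#' The defaults state the world the pipeline targets: 417 cases and 417
#' frequency-matched controls, a candidate panel of 587 SNPs in 65 genes,
#' Hardy-Weinberg genotypes with MAF uniform on [0.05, 0.5], control-like
#' covariate frequencies (ethnicity ~82% White, smoking ~69% never; ages
#' around 60.5 +/- 10.5 years), and no SNP effects unless configured.
#'
#' @param n_cases,n_controls cohort arm sizes (default 417 / 417).
#' @param snp_specs data.frame with columns `snp_id`, `gene`, `maf`,
#'   `model` (dominant/additive/recessive), `or` (odds ratio per coded
#'   unit); default [default_snp_specs()] at panel scale with all OR = 1.
#' @param ld_blocks list of `list(snps = <ids>, r2 = <target>)`; SNPs not in
#'   any block are independent.
#' @param age_mean,age_sd source-population age distribution in years.
#' @param ethnicity_probs,smoking_probs named probability vectors over the
#'   canonical levels.
#' @param baseline_logit intercept of the disease model (default
#'   `qlogis(0.1)`, i.e. 10% baseline prevalence in the source population).
#' @param pool_size source-population size; default sized so case and
#'   matched-control draws succeed with margin.
#' @param match_age_window age window (years) for control matching
#'   (default 5).
#' @param seed master seed; all randomness flows from it through named
#'   substreams.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cases = 417, n_controls = 417,
                             snp_specs = NULL, ld_blocks = list(),
                             age_mean = 60.5, age_sd = 10.5,
                             ethnicity_probs = c(White = 0.82,
                                                 Hispanic = 0.115,
                                                 Black = 0.045,
                                                 Other = 0.02),
                             smoking_probs = c(Never = 0.685,
                                               Former = 0.23,
                                               Current = 0.085),
                             baseline_logit = stats::qlogis(0.1),
                             pool_size = NULL,
                             match_age_window = 5,
                             seed = 1) {
  if (n_cases <= 0) stop("n_cases must be positive")
  if (n_controls <= 0) stop("n_controls must be positive")
  if (is.null(snp_specs)) snp_specs <- default_snp_specs(seed = seed)
  snp_specs <- as.data.frame(snp_specs, stringsAsFactors = FALSE)
  stopifnot(all(c("snp_id", "maf", "model", "or") %in% names(snp_specs)),
            all(snp_specs$maf > 0 & snp_specs$maf <= 0.5),
            all(snp_specs$or > 0),
            all(snp_specs$model %in% .MODELS))
  if (is.null(snp_specs$gene)) snp_specs$gene <- "GENE1"
  for (b in ld_blocks) {
    stopifnot(all(b$snps %in% snp_specs$snp_id), b$r2 >= 0, b$r2 < 1)
  }
  stopifnot(abs(sum(ethnicity_probs) - 1) < 1e-8,
            abs(sum(smoking_probs) - 1) < 1e-8)
  prev <- stats::plogis(baseline_logit)
  if (is.null(pool_size))
    pool_size <- ceiling(max(2.5 * n_cases / prev,
                             4 * (n_cases + n_controls)))
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 snp_specs = snp_specs, ld_blocks = ld_blocks,
                 age_mean = age_mean, age_sd = age_sd,
                 ethnicity_probs = ethnicity_probs,
                 smoking_probs = smoking_probs,
                 baseline_logit = baseline_logit,
                 pool_size = pool_size,
                 match_age_window = match_age_window,
                 seed = seed),
            class = "synthetic_config")
}

#' Default null SNP panel at candidate-gene scale
#'
#' 587 SNPs spread over 65 genes, MAF uniform on [0.05, 0.5], additive
#' coding and OR 1 (no effects) — the null panel the calibration checks
#' assume.
#'
#' @param n_snps,n_genes panel dimensions (defaults 587 / 65).
#' @param maf_range MAF sampling range.
#' @param seed seed for the MAF draw.
#' @return data.frame usable as `snp_specs`.
#' @export
default_snp_specs <- function(n_snps = 587, n_genes = 65,
                              maf_range = c(0.05, 0.5), seed = 1) {
  set.seed(substream_seed(seed, "snp_specs"))
  data.frame(
    snp_id = sprintf("rs%06d", seq_len(n_snps)),
    gene = sprintf("GENE%02d", rep_len(seq_len(n_genes), n_snps)),
    maf = stats::runif(n_snps, maf_range[1L], maf_range[2L]),
    model = "additive",
    or = 1,
    stringsAsFactors = FALSE)
}

# Latent-Gaussian correlation giving a target correlation between two
# variant-allele indicators thresholded at qnorm(maf) (equal MAFs).
.calibrate_latent_rho <- function(target_r, maf) {
  if (target_r <= 0) return(0)
  q <- stats::qnorm(maf)
  indicator_cor <- function(rho) {
    if (rho >= 1) return(1)
    p11 <- stats::integrate(function(z)
      stats::dnorm(z) * stats::pnorm((q - rho * z) / sqrt(1 - rho^2)),
      -Inf, q, rel.tol = 1e-9)$value
    (p11 - maf^2) / (maf * (1 - maf))
  }
  stats::uniroot(function(rho) indicator_cor(rho) - target_r,
                 c(1e-6, 1 - 1e-6), tol = 1e-6)$root
}

# Draw an n x k matrix of variant-allele dosages for one LD block:
# two latent haplotype draws per subject, equicorrelated across SNPs.
.draw_block <- function(n, mafs, target_r2) {
  k <- length(mafs)
  if (k == 1L || target_r2 <= 0) {
    g <- vapply(mafs, function(m) stats::rbinom(n, 2L, m), integer(n))
    if (n == 1L) g <- matrix(g, nrow = 1L)
    return(g)
  }
  rho <- .calibrate_latent_rho(sqrt(target_r2), mean(mafs))
  hap <- function() {
    shared <- stats::rnorm(n)
    z <- sqrt(rho) * shared +
      sqrt(1 - rho) * matrix(stats::rnorm(n * k), n, k)
    t(t(z) < stats::qnorm(mafs)) * 1L
  }
  hap() + hap()
}

#' Simulate a frequency-matched case-control cohort
#'
#' Draws a large source population with Hardy-Weinberg genotypes (LD blocks
#' via a shared latent-Gaussian haplotype construction), assigns disease by
#' a logistic model over the configured SNP effects under their genetic
#' codings, samples cases from the affected pool, and frequency-matches
#' controls to cases on ethnicity (exact) and age (within the configured
#' window) by rejection sampling from the unaffected pool.  Fully
#' reproducible from the master seed.
#'
#' @param config a `synthetic_config`.
#' @return list with `gm` (a `genotype_matrix`, cases then controls) and
#'   `subjects` (a `subject_table`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  specs <- config$snp_specs
  n_pool <- config$pool_size
  # covariates
  set.seed(substream_seed(config$seed, "covariates"))
  age <- pmax(18, stats::rnorm(n_pool, config$age_mean, config$age_sd))
  eth <- sample(names(config$ethnicity_probs), n_pool, replace = TRUE,
                prob = config$ethnicity_probs)
  smk <- sample(names(config$smoking_probs), n_pool, replace = TRUE,
                prob = config$smoking_probs)
  # genotypes
  set.seed(substream_seed(config$seed, "genotypes"))
  calls <- matrix(NA_integer_, n_pool, nrow(specs),
                  dimnames = list(sprintf("P%06d", seq_len(n_pool)),
                                  specs$snp_id))
  in_block <- rep(FALSE, nrow(specs))
  for (b in config$ld_blocks) {
    j <- match(b$snps, specs$snp_id)
    calls[, j] <- .draw_block(n_pool, specs$maf[j], b$r2)
    in_block[j] <- TRUE
  }
  for (j in which(!in_block))
    calls[, j] <- stats::rbinom(n_pool, 2L, specs$maf[j])
  # disease model
  set.seed(substream_seed(config$seed, "status"))
  eta <- rep(config$baseline_logit, n_pool)
  for (j in which(specs$or != 1))
    eta <- eta + log(specs$or[j]) *
      code_genotype(calls[, j], specs$model[j])
  affected <- stats::runif(n_pool) < stats::plogis(eta)
  if (sum(affected) < config$n_cases)
    stop("source pool has only ", sum(affected), " affected subjects; ",
         "need ", config$n_cases, " cases (increase pool_size)")
  # sampling + matching
  set.seed(substream_seed(config$seed, "matching"))
  case_idx <- sample(which(affected), config$n_cases)
  avail <- !affected
  ctrl_idx <- integer(config$n_controls)
  # cycle through cases so control matching mirrors the case frequencies;
  # a case with no remaining compatible control is substituted by another
  # case (frequency matching constrains distributions, not pairs), and the
  # run only errors when no case has a compatible control left
  target <- rep_len(case_idx, config$n_controls)
  w <- config$match_age_window
  compatible <- function(ci) which(avail & eth == eth[ci] &
                                     abs(age - age[ci]) <= w)
  for (i in seq_len(config$n_controls)) {
    cand <- compatible(target[i])
    if (!length(cand)) {
      for (cj in sample(case_idx)) {
        cand <- compatible(cj)
        if (length(cand)) break
      }
      if (!length(cand))
        stop("control matching exhausted for stratum: ethnicity=",
             eth[target[i]], ", age=", round(age[target[i]], 1))
    }
    pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
    ctrl_idx[i] <- pick
    avail[pick] <- FALSE
  }
  sel <- c(case_idx, ctrl_idx)
  ids <- sprintf("S%04d", seq_along(sel))
  subjects <- subject_table(
    id = ids,
    status = rep(c("case", "control"), c(config$n_cases, config$n_controls)),
    age = round(age[sel], 1),
    ethnicity = eth[sel],
    smoking = smk[sel])
  g <- calls[sel, , drop = FALSE]
  rownames(g) <- ids
  ann <- data.frame(snp_id = specs$snp_id, gene = specs$gene,
                    ref_allele = "A", var_allele = "G",
                    stringsAsFactors = FALSE)
  list(gm = genotype_matrix(g, ann), subjects = subjects)
}

#' Mean pairwise genotype r-squared within an LD block
#'
#' Generator calibration check: the latent-Gaussian construction is
#' approximate, and this measures what it actually achieved.
#'
#' @param gm a `genotype_matrix`.
#' @param block character vector of >= 2 SNP ids.
#' @return mean off-diagonal r-squared; NA (with a warning) for a
#'   single-SNP block.
#' @export
ld_block_r2_check <- function(gm, block) {
  if (length(block) < 2L) {
    warning("single-SNP block: r2 undefined")
    return(NA_real_)
  }
  r2 <- ld_matrix(gm, block)
  mean(r2[upper.tri(r2)])
}

#' Published contingency-table fixtures
#'
#' Case/control counts transcribed from the source study's printed tables
#' (significant single SNPs; cumulative unfavorable-genotype groups; CART
#' terminal nodes), bundled as plain-text TSVs.  No individual-level data
#' are fabricated: these are aggregate counts only, used for deterministic
#' estimator checks.
#'
#' @param table `"snp"`, `"cumulative"` or `"cart"`.
#' @return data.frame of the requested table.
#' @export
study_fixture <- function(table = c("snp", "cumulative", "cart")) {
  table <- match.arg(table)
  file <- system.file("extdata",
                      paste0("study_", table, "_counts.tsv"),
                      package = "snpcart", mustWork = TRUE)
  utils::read.delim(file, stringsAsFactors = FALSE)
}

#' A 2x2 fixture table by key
#'
#' Returns `(a, b, c, d)` = (exposed cases, unexposed cases, exposed
#' controls, unexposed controls).  Keys: an rs-id from the single-SNP table
#' (dichotomized under its best model; additive rows are not dichotomizable
#' and error), a cumulative group label (`"8~9"`, `"10"`, `"11~12"`; vs the
#' lowest group), or `"node2"` ... `"node9"` (vs node 1).
#'
#' @param key fixture key.
#' @return list `(a, b, c, d)`.
#' @export
fixture_2x2 <- function(key) {
  snp <- study_fixture("snp")
  if (key %in% snp$snp_id) {
    r <- snp[snp$snp_id == key, ]
    if (is.na(r$case_exposed))
      stop("additive-model SNP ", key, " has no 2x2 dichotomization")
    return(list(a = r$case_exposed, b = r$case_unexposed,
                c = r$ctrl_exposed, d = r$ctrl_unexposed))
  }
  cum <- study_fixture("cumulative")
  if (key %in% cum$label) {
    r <- cum[cum$label == key, ]; ref <- cum[1L, ]
    return(list(a = r$case_n, b = ref$case_n, c = r$control_n,
                d = ref$control_n))
  }
  cart <- study_fixture("cart")
  nd <- paste0("node", cart$node)
  if (key %in% nd) {
    r <- cart[nd == key, ]; ref <- cart[1L, ]
    return(list(a = r$case_n, b = ref$case_n, c = r$control_n,
                d = ref$control_n))
  }
  stop("unknown fixture key: ", key)
}
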