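# Shared in-code fixtures: tiny cohorts built deterministically.

make_gm <- function(calls, snp_ids = NULL, subject_ids = NULL,
                    annotation = NULL) {
  if (!is.matrix(calls)) calls <- matrix(calls, ncol = 1L)
  if (is.null(snp_ids))
    snp_ids <- if (!is.null(colnames(calls))) colnames(calls)
               else sprintf("rs%03d", seq_len(ncol(calls)))
  if (is.null(subject_ids))
    subject_ids <- if (!is.null(rownames(calls))) rownames(calls)
                   else sprintf("S%03d", seq_len(nrow(calls)))
  dimnames(calls) <- list(subject_ids, snp_ids)
  genotype_matrix(calls, annotation)
}

make_subjects <- function(n_case, n_control, seed = 1) {
  set.seed(seed)
  n <- n_case + n_control
  subject_table(
    id = sprintf("S%03d", seq_len(n)),
    status = rep(c("case", "control"), c(n_case, n_control)),
    age = round(rnorm(n, 60, 10), 1),
    ethnicity = sample(c("White", "Hispanic", "Black", "Other"), n,
                       replace = TRUE, prob = c(0.8, 0.12, 0.05, 0.03)),
    smoking = sample(c("Never", "Former", "Current"), n,
                     replace = TRUE, prob = c(0.7, 0.2, 0.1)))
}

# Cohort whose genotype margins reproduce the bundled single-SNP study
# fixture: per SNP, exposure indicators are dealt to match the printed
# dichotomized counts (seeded random assignment; independent across SNPs).
make_study_cohort <- function(seed = 1) {
  snp <- study_fixture("snp")
  snp <- snp[!is.na(snp$case_exposed), ]     # dichotomizable rows only
  n_case <- max(snp$case_exposed + snp$case_unexposed)
  n_control <- max(snp$ctrl_exposed + snp$ctrl_unexposed)
  subjects <- make_subjects(n_case, n_control, seed = seed)
  set.seed(seed + 1000)
  calls <- matrix(NA_integer_, n_case + n_control, nrow(snp),
                  dimnames = list(subjects$id, snp$snp_id))
  is_case <- subjects$status == "case"
  for (i in seq_len(nrow(snp))) {
    exposed_code <- if (snp$model[i] == "recessive") 2L else 1L
    g <- integer(n_case + n_control)
    g[sample(which(is_case), snp$case_exposed[i])] <- exposed_code
    g[sample(which(!is_case), snp$ctrl_exposed[i])] <- exposed_code
    # per-SNP shortfalls vs the arm size are missing calls
    na_case <- n_case - snp$case_exposed[i] - snp$case_unexposed[i]
    if (na_case > 0)
      g[sample(which(is_case & g == 0L), na_case)] <- NA_integer_
    na_ctrl <- n_control - snp$ctrl_exposed[i] - snp$ctrl_unexposed[i]
    if (na_ctrl > 0)
      g[sample(which(!is_case & g == 0L), na_ctrl)] <- NA_integer_
    # spread the collapsed side over both its genotypes (the printed tables
    # only constrain the dichotomy) so the two carrier splits differ
    if (snp$model[i] == "recessive") {
      unexp <- which(g == 0L)
      g[sample(unexp, floor(length(unexp) / 2))] <- 1L
    } else {
      exp_ <- which(g == 1L)
      g[sample(exp_, floor(length(exp_) / 4))] <- 2L
    }
    calls[, i] <- g
  }
  list(gm = genotype_matrix(calls), subjects = subjects, table = snp)
}
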