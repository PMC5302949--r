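#' Construct a genotype matrix
#'
#' The central container of the pipeline: subjects in rows, SNPs in columns,
#' calls coded as copies of the *variant* allele (0, 1, 2) with `NA` for
#' missing.  The variant allele is whatever the annotation declares, not the
#' minor allele, so the coding is stable across strata.
#'
#' @param calls integer matrix with subject ids as rownames and SNP ids as
#'   colnames; values in \{0, 1, 2, NA\}.
#' @param annotation optional data.frame with columns `snp_id`, `gene`,
#'   `ref_allele`, `var_allele` and optionally `chrom`, `pos` (1-based).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, annotation = NULL) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix")
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("`calls` needs subject rownames and SNP colnames")
  if (anyDuplicated(colnames(calls)))
    stop("duplicate snp_id: ",
         paste(unique(colnames(calls)[duplicated(colnames(calls))]), collapse = ", "))
  if (anyDuplicated(rownames(calls)))
    stop("duplicate subject id")
  storage.mode(calls) <- "integer"
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid genotype call at subject '%s', snp '%s'",
                 rownames(calls)[idx[1L]], colnames(calls)[idx[2L]]))
  }
  if (!is.null(annotation)) {
    annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
    if (!all(c("snp_id") %in% names(annotation)))
      stop("annotation needs an `snp_id` column")
    if (anyDuplicated(annotation$snp_id)) stop("duplicate snp_id in annotation")
    missing_ann <- setdiff(colnames(calls), annotation$snp_id)
    if (length(missing_ann))
      stop("annotation missing SNPs: ", paste(utils::head(missing_ann, 5), collapse = ", "))
    annotation <- annotation[match(colnames(calls), annotation$snp_id), , drop = FALSE]
    rownames(annotation) <- NULL
  }
  structure(list(calls = calls, annotation = annotation),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d SNPs (%.1f%% missing)\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subject ids of a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return character vector.
#' @export
subject_ids <- function(gm) rownames(gm$calls)

#' SNP ids of a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return character vector.
#' @export
snp_ids <- function(gm) colnames(gm$calls)

#' Subset a genotype matrix by SNPs and/or subjects
#' @param gm a `genotype_matrix`.
#' @param snps SNP ids to keep (default all).
#' @param subjects subject ids to keep (default all).
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(gm, snps = snp_ids(gm), subjects = subject_ids(gm)) {
  stopifnot(all(snps %in% snp_ids(gm)), all(subjects %in% subject_ids(gm)))
  ann <- gm$annotation
  if (!is.null(ann)) ann <- ann[match(snps, ann$snp_id), , drop = FALSE]
  genotype_matrix(gm$calls[subjects, snps, drop = FALSE], ann)
}

# canonical covariate levels
.ETHNICITY_LEVELS <- c("White", "Hispanic", "Black", "Other")
.SMOKING_LEVELS   <- c("Never", "Former", "Current")

#' Read genotypes from file
#'
#' Supported dialects:
#' \describe{
#'   \item{matrix-tsv}{header row of SNP ids, first column subject id, cells
#'     in \{0,1,2,NA\} counting variant alleles.}
#'   \item{vcf}{GT fields only (requires the VariantAnnotation package);
#'     0/0 -> 0, 0/1 -> 1, 1/1 -> 2, ./. -> NA. Multi-allelic records are an
#'     error.}
#'   \item{ped-map}{PLINK text PED/MAP allele pairs. The variant allele is
#'     taken from `annotation$var_allele` when supplied, otherwise the minor
#'     allele in the file.}
#' }
#'
#' @param path path to the genotype file (PED file for `ped-map`).
#' @param dialect one of `"matrix-tsv"`, `"vcf"`, `"ped-map"`.
#' @param map_path MAP file path (ped-map only; default `path` with .map).
#' @param annotation optional SNP annotation data.frame (see
#'   [genotype_matrix()]).
#' @return a `genotype_matrix`.
#' @export
read_genotypes <- function(path,
                           dialect = c("matrix-tsv", "vcf", "ped-map"),
                           map_path = NULL, annotation = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect,
         "matrix-tsv" = .read_matrix_tsv(path, annotation),
         "vcf"        = .read_vcf(path),
         "ped-map"    = .read_ped_map(path, map_path, annotation))
}

.read_matrix_tsv <- function(path, annotation) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("matrix-tsv parse error: need header + data (", path, ")")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  snps <- header[-1L]
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nfield <- lengths(rows)
  if (any(nfield != length(header)))
    stop("matrix-tsv parse error at line ", which(nfield != length(header))[1L] + 1L,
         ": expected ", length(header), " fields")
  ids <- vapply(rows, `[[`, "", 1L)
  cells <- t(vapply(rows, function(r) r[-1L], character(length(snps))))
  if (length(snps) == 1L) cells <- matrix(cells, ncol = 1L)
  ok <- matrix(cells %in% c("0", "1", "2", "NA", ""), nrow = nrow(cells))
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop("matrix-tsv parse error at line ", bad[1L] + 1L,
         ": unknown genotype symbol '", cells[bad[1L], bad[2L]], "'")
  }
  calls <- suppressWarnings(matrix(as.integer(cells), nrow = length(ids),
                                   dimnames = list(ids, snps)))
  genotype_matrix(calls, annotation)
}

.read_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("the 'vcf' dialect requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  if (any(lengths(alt) != 1L))
    stop("multi-allelic SNPs are not supported")
  gt <- VariantAnnotation::geno(vcf)$GT        # variants x samples
  map <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
           "1|0" = 1L, "1/1" = 2L, "1|1" = 2L, "./." = NA_integer_,
           ".|." = NA_integer_, "." = NA_integer_)
  unknown <- setdiff(unique(as.vector(gt)), names(map))
  if (length(unknown))
    stop("unknown GT value(s): ", paste(unknown, collapse = ", "))
  calls <- matrix(map[as.vector(gt)], nrow = nrow(gt),
                  dimnames = dimnames(gt))
  rr <- SummarizedExperiment::rowRanges(vcf)
  ann <- data.frame(
    snp_id = rownames(gt),
    ref_allele = as.character(VariantAnnotation::ref(vcf)),
    var_allele = vapply(alt, function(a) as.character(a)[1L], ""),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    stringsAsFactors = FALSE)
  genotype_matrix(t(calls), ann)
}

.read_ped_map <- function(path, map_path, annotation) {
  if (is.null(map_path)) map_path <- sub("\\.ped$", ".map", path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  snps <- map[[2L]]
  ped <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(ped) != 6L + 2L * length(snps))
    stop("PED/MAP parse error: ", ncol(ped), " PED columns for ",
         length(snps), " MAP SNPs")
  ids <- ped[[2L]]
  calls <- matrix(NA_integer_, nrow(ped), length(snps),
                  dimnames = list(ids, snps))
  var_alleles <- if (!is.null(annotation))
    annotation$var_allele[match(snps, annotation$snp_id)] else rep(NA_character_, length(snps))
  for (j in seq_along(snps)) {
    a1 <- ped[[6L + 2L * j - 1L]]
    a2 <- ped[[6L + 2L * j]]
    missing <- a1 %in% c("0", ".", "N") | a2 %in% c("0", ".", "N")
    alleles <- setdiff(unique(c(a1[!missing], a2[!missing])), character(0))
    if (length(alleles) > 2L)
      stop("SNP ", snps[j], " has >2 alleles in PED file")
    va <- var_alleles[j]
    if (is.na(va)) {
      # minor-allele fallback when no annotation is given
      counts <- table(factor(c(a1[!missing], a2[!missing]), levels = alleles))
      va <- names(counts)[which.min(counts)]
    } else if (length(alleles) && !va %in% alleles && length(alleles) == 2L) {
      stop("annotated variant allele '", va, "' absent for SNP ", snps[j])
    }
    g <- (a1 == va) + (a2 == va)
    g[missing] <- NA_integer_
    calls[, j] <- as.integer(g)
  }
  genotype_matrix(calls, annotation)
}

#' Write a genotype matrix as matrix-tsv
#' @param gm a `genotype_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path) {
  cells <- gm$calls
  txt <- rbind(c("subject_id", colnames(cells)),
               cbind(rownames(cells),
                     matrix(ifelse(is.na(cells), "NA", as.character(cells)),
                            nrow = nrow(cells))))
  writeLines(apply(txt, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

#' Read a subject covariate table
#'
#' Expects a CSV with header `id,status,age,ethnicity,smoking`.  `status` is
#' normalized case-insensitively to `case`/`control`; ethnicity to
#' White/Hispanic/Black/Other and smoking to Never/Former/Current.
#'
#' @param path CSV path.
#' @param unknown_levels `"error"` (default) to fail on an unrecognized
#'   ethnicity/smoking level, or `"other"` to map unknown ethnicities to
#'   `Other` (smoking has no catch-all and always errors).
#' @return data.frame of class `subject_table` with columns
#'   `id`, `status` (factor control/case), `age`, `ethnicity`, `smoking`.
#' @export
read_covariates <- function(path, unknown_levels = c("error", "other")) {
  unknown_levels <- match.arg(unknown_levels)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "status", "age", "ethnicity", "smoking")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("covariate file missing column(s): ",
                         paste(miss, collapse = ", "))
  subject_table(df$id, df$status, df$age, df$ethnicity, df$smoking,
                unknown_levels = unknown_levels)
}

#' Construct a subject table
#' @param id subject ids.
#' @param status case/control labels (case-insensitive).
#' @param age ages in years (NA allowed).
#' @param ethnicity,smoking categorical covariates.
#' @param unknown_levels see [read_covariates()].
#' @return a `subject_table` data.frame.
#' @export
subject_table <- function(id, status, age, ethnicity, smoking,
                          unknown_levels = c("error", "other")) {
  unknown_levels <- match.arg(unknown_levels)
  if (anyDuplicated(id)) stop("duplicate subject id")
  st <- tolower(trimws(as.character(status)))
  if (any(is.na(st) | !st %in% c("case", "control")))
    stop("status must be case/control and never missing; offenders: ",
         paste(utils::head(id[is.na(st) | !st %in% c("case", "control")], 5),
               collapse = ", "))
  age <- as.numeric(age)
  if (any(!is.na(age) & age <= 0)) stop("age must be > 0 when present")
  norm_level <- function(x, levels, what) {
    x <- trimws(as.character(x))
    m <- levels[match(tolower(x), tolower(levels))]
    if (anyNA(m)) {
      if (unknown_levels == "other" && "Other" %in% levels) {
        m[is.na(m)] <- "Other"
      } else {
        stop("unknown ", what, " level(s): ",
             paste(unique(x[is.na(m)]), collapse = ", "))
      }
    }
    factor(m, levels = levels)
  }
  out <- data.frame(
    id = as.character(id),
    status = factor(st, levels = c("control", "case")),
    age = age,
    ethnicity = norm_level(ethnicity, .ETHNICITY_LEVELS, "ethnicity"),
    smoking = norm_level(smoking, .SMOKING_LEVELS, "smoking"),
    stringsAsFactors = FALSE)
  class(out) <- c("subject_table", "data.frame")
  out
}

#' Write a subject table as CSV
#' @param subjects a `subject_table`.
#' @param path output path.
#' @export
write_covariates <- function(subjects, path) {
  utils::write.csv(as.data.frame(subjects)[, c("id", "status", "age",
                                               "ethnicity", "smoking")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check genotype/covariate id consistency
#' @param gm a `genotype_matrix`.
#' @param subjects a `subject_table`.
#' @return invisibly TRUE; errors listing offending ids otherwise.
#' @export
check_cohort <- function(gm, subjects) {
  only_g <- setdiff(subject_ids(gm), subjects$id)
  only_s <- setdiff(subjects$id, subject_ids(gm))
  if (length(only_g) || length(only_s))
    stop("genotype/covariate id mismatch; genotype-only: [",
         paste(utils::head(only_g, 10), collapse = ", "),
         "] covariate-only: [",
         paste(utils::head(only_s, 10), collapse = ", "), "]")
  invisible(TRUE)
}

#' Genotype counts for a SNP within a stratum
#'
#' Counts non-missing genotypes 0/1/2 among the requested stratum.
#'
#' @param gm a `genotype_matrix`.
#' @param snp_id a SNP id present in `gm`.
#' @param subjects a `subject_table` aligned with `gm` (required unless
#'   `stratum = "all"`).
#' @param stratum `"all"`, `"case"` or `"control"`.
#' @return named integer vector `c(n_00, n_01, n_11)` (hom-ref, het,
#'   hom-variant).
#' @export
genotype_counts <- function(gm, snp_id, subjects = NULL,
                            stratum = c("all", "case", "control")) {
  stratum <- match.arg(stratum)
  if (!snp_id %in% snp_ids(gm)) stop("unknown snp_id: ", snp_id)
  g <- gm$calls[, snp_id]
  if (stratum != "all") {
    if (is.null(subjects)) stop("`subjects` required for stratified counts")
    keep <- subjects$id[as.character(subjects$status) == stratum]
    g <- g[subject_ids(gm) %in% keep]
  }
  tab <- tabulate(g + 1L, nbins = 3L)
  c(n_00 = tab[1L], n_01 = tab[2L], n_11 = tab[3L])
}

#' Per-SNP call rate
#' @param gm a `genotype_matrix`.
#' @return named numeric vector of non-missing fractions per SNP.
#' @export
call_rate <- function(gm) colMeans(!is.na(gm$calls))
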