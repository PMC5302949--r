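#' Pipeline configuration
#'
#' Collects every threshold the analysis uses: HWE alpha 0.01, single-SNP
#' significance 0.05, q threshold 0.05, LD redundancy r2 0.8, 100 bootstrap
#' validation resamples, 10,000 bootstrap CI resamples, CART alpha 0.05.
#'
#' @param genotypes path to a matrix-tsv genotype file (or a
#'   `genotype_matrix`).
#' @param covariates path to a covariate CSV (or a `subject_table`).
#' @param out_dir output directory for the report bundle.
#' @param hwe_alpha,maf_min,call_rate_min QC thresholds.
#' @param alpha single-SNP significance level.
#' @param q_threshold q-value significance level.
#' @param r2_threshold LD pruning threshold.
#' @param boot_B bootstrap validation resamples (0 skips the stage).
#' @param ci_B bootstrap CI resamples for group ORs.
#' @param cart_alpha,cart_min_node CART growth controls.
#' @param unfavorable_rule `"q"` or `"p"` panel rule for the cumulative
#'   stage.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes, covariates, out_dir = ".",
                            hwe_alpha = 0.01, maf_min = 0,
                            call_rate_min = 0, alpha = 0.05,
                            q_threshold = 0.05, r2_threshold = 0.8,
                            boot_B = 100, ci_B = 10000,
                            cart_alpha = 0.05, cart_min_node = 20,
                            unfavorable_rule = "q", seed = 1) {
  cfg <- as.list(environment())
  thr <- c(hwe_alpha = hwe_alpha, alpha = alpha, q_threshold = q_threshold,
           r2_threshold = r2_threshold, cart_alpha = cart_alpha)
  if (any(thr <= 0 | thr >= 1))
    stop("thresholds must lie in (0, 1): ",
         paste(names(thr)[thr <= 0 | thr >= 1], collapse = ", "))
  stopifnot(boot_B >= 0, ci_B >= 0)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' QC (HWE in controls) -> per-SNP best-model association -> LD-pruned BH
#' q-values -> bootstrap internal validation -> cumulative unfavorable-
#' genotype risk groups -> CART interaction tree.  Writes the six report
#' files plus a machine-readable run manifest into `out_dir` and returns
#' everything invisibly.
#'
#' @param config a `pipeline_config`.
#' @param quiet suppress progress messages.
#' @return (invisibly) list with `qc`, `assoc`, `qtab`, `risk`, `tree`,
#'   `cart_nodes`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()
  gm <- if (inherits(config$genotypes, "genotype_matrix")) config$genotypes
        else read_genotypes(config$genotypes, "matrix-tsv")
  subjects <- if (inherits(config$covariates, "subject_table")) config$covariates
              else read_covariates(config$covariates)
  check_cohort(gm, subjects)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  say("QC: ", ncol(gm$calls), " SNPs, ", nrow(subjects), " subjects")
  qc <- apply_qc(gm, subjects, hwe_alpha = config$hwe_alpha,
                 maf_min = config$maf_min,
                 call_rate_min = config$call_rate_min)
  write_qc_report(qc$report, out("qc_report.tsv"))
  gm <- qc$gm
  say("QC removed ", sum(!qc$report$pass), " SNPs")

  say("association: best-model selection over ", ncol(gm$calls), " SNPs")
  assoc <- associate_panel(gm, subjects)
  qtab <- prune_and_adjust(
    stats::setNames(assoc$p, assoc$snp_id)[!is.na(assoc$p)],
    gm, r2_threshold = config$r2_threshold)
  assoc$q <- qtab$q[match(assoc$snp_id, qtab$snp_id)]
  utils::write.table(qtab, out("qvalues.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)

  sig <- !is.na(assoc$q) & assoc$q < config$q_threshold
  if (config$boot_B > 0 && any(sig)) {
    say("bootstrap validation (B=", config$boot_B, ") of ",
        sum(sig), " q-significant SNPs")
    boot <- bootstrap_panel(gm, subjects, assoc[sig, , drop = FALSE],
                            B = config$boot_B, seed = config$seed)
    for (col in c("boot_p05", "boot_p01", "boot_p001", "boot_or_median")) {
      assoc[[col]] <- NA
      assoc[[col]][sig] <- boot[[col]]
    }
  }
  write_assoc_table(assoc, out("association.tsv"))

  panel <- unfavorable_panel(assoc, rule = config$unfavorable_rule,
                             alpha = if (config$unfavorable_rule == "q")
                               config$q_threshold else config$alpha)
  risk <- NULL
  if (length(panel) >= 2L) {
    say("cumulative risk groups over ", length(panel), " unfavorable specs")
    counts <- count_unfavorable(gm, panel, subjects)
    risk <- group_or_trend(counts, subjects)
    write_risk_groups(risk, out("risk_groups.tsv"))
  } else say("cumulative stage skipped: fewer than 2 unfavorable specs")

  p_sig <- assoc$snp_id[!is.na(assoc$p) & assoc$p < config$alpha]
  tree <- NULL; cart_nodes <- NULL
  if (length(p_sig)) {
    say("CART over ", length(p_sig), " p-significant SNPs")
    tree <- grow_tree(gm, subjects, p_sig, alpha = config$cart_alpha,
                      min_node_size = config$cart_min_node)
    writeLines(render_tree(tree), out("cart_tree.txt"))
    if (tree$n_terminal > 1L) {
      cart_nodes <- terminal_node_ors(tree, subjects)
      write_cart_nodes(cart_nodes, out("cart_nodes.tsv"))
    }
  } else say("CART skipped: no p-significant SNPs")

  manifest <- list(
    package = "snpcart",
    version = as.character(utils::packageVersion("snpcart")),
    seed = config$seed,
    thresholds = list(hwe_alpha = config$hwe_alpha, alpha = config$alpha,
                      q_threshold = config$q_threshold,
                      r2_threshold = config$r2_threshold,
                      boot_B = config$boot_B, ci_B = config$ci_B,
                      cart_alpha = config$cart_alpha,
                      cart_min_node = config$cart_min_node,
                      unfavorable_rule = config$unfavorable_rule),
    n_subjects = nrow(subjects),
    n_snps_input = nrow(qc$report),
    snps_removed_qc = qc$report$snp_id[!qc$report$pass],
    n_q_significant = sum(sig),
    n_p_significant = length(p_sig),
    n_terminal_nodes = if (is.null(tree)) NA else tree$n_terminal,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(qc = qc$report, assoc = assoc, qtab = qtab, risk = risk,
                 tree = tree, cart_nodes = cart_nodes, manifest = manifest))
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `qc`, `assoc`, `fdr`, `bootstrap`, `cumulative`,
#' `cart` run single stages; `all` runs the whole pipeline.  Invoke as
#' `Rscript -e 'snpcart::snpcart_cli()' <subcommand> --genotypes ... `.
#'
#' @param args command-line arguments (default `commandArgs(TRUE)`).
#' @return exit status, invisibly.
#' @export
snpcart_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: snpcart <simulate|qc|assoc|fdr|bootstrap|cumulative|cart|all> [options]")
    return(invisible(1L))
  }
  cmd <- args[1L]
  opts <- list(
    optparse::make_option("--genotypes", type = "character"),
    optparse::make_option("--covariates", type = "character"),
    optparse::make_option("--out", type = "character", default = "."),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--hwe-alpha", type = "double", default = 0.01,
                          dest = "hwe_alpha"),
    optparse::make_option("--alpha", type = "double", default = 0.05),
    optparse::make_option("--q-threshold", type = "double", default = 0.05,
                          dest = "q_threshold"),
    optparse::make_option("--r2-threshold", type = "double", default = 0.8,
                          dest = "r2_threshold"),
    optparse::make_option("--boot-B", type = "integer", default = 100L,
                          dest = "boot_B"),
    optparse::make_option("--ci-B", type = "integer", default = 10000L,
                          dest = "ci_B"),
    optparse::make_option("--cart-alpha", type = "double", default = 0.05,
                          dest = "cart_alpha"),
    optparse::make_option("--cart-min-node", type = "integer", default = 20L,
                          dest = "cart_min_node"),
    optparse::make_option("--n-cases", type = "integer", default = 417L,
                          dest = "n_cases"),
    optparse::make_option("--n-controls", type = "integer", default = 417L,
                          dest = "n_controls"),
    optparse::make_option("--n-snps", type = "integer", default = 587L,
                          dest = "n_snps"))
  parsed <- optparse::parse_args(
    optparse::OptionParser(option_list = opts), args = args[-1L])

  if (cmd == "simulate") {
    cfg <- synthetic_config(n_cases = parsed$n_cases,
                            n_controls = parsed$n_controls,
                            snp_specs = default_snp_specs(parsed$n_snps,
                                                          seed = parsed$seed),
                            seed = parsed$seed)
    sim <- simulate_cohort(cfg)
    dir.create(parsed$out, showWarnings = FALSE, recursive = TRUE)
    write_genotypes(sim$gm, file.path(parsed$out, "genotypes.tsv"))
    write_covariates(sim$subjects, file.path(parsed$out, "covariates.csv"))
    message("wrote ", file.path(parsed$out, "genotypes.tsv"))
    return(invisible(0L))
  }

  known <- c("all", "qc", "assoc", "fdr", "bootstrap", "cumulative", "cart")
  if (!cmd %in% known) stop("unknown subcommand: ", cmd)
  need_inputs <- function() {
    if (is.null(parsed$genotypes) || is.null(parsed$covariates))
      stop("--genotypes and --covariates are required for '", cmd, "'")
    list(gm = read_genotypes(parsed$genotypes, "matrix-tsv"),
         subjects = read_covariates(parsed$covariates))
  }

  if (cmd == "all") {
    cfg <- pipeline_config(parsed$genotypes, parsed$covariates,
                           out_dir = parsed$out,
                           hwe_alpha = parsed$hwe_alpha,
                           alpha = parsed$alpha,
                           q_threshold = parsed$q_threshold,
                           r2_threshold = parsed$r2_threshold,
                           boot_B = parsed$boot_B, ci_B = parsed$ci_B,
                           cart_alpha = parsed$cart_alpha,
                           cart_min_node = parsed$cart_min_node,
                           seed = parsed$seed)
    run_pipeline(cfg)
    return(invisible(0L))
  }

  inp <- need_inputs()
  dir.create(parsed$out, showWarnings = FALSE, recursive = TRUE)
  if (cmd == "qc") {
    qc <- apply_qc(inp$gm, inp$subjects, hwe_alpha = parsed$hwe_alpha)
    write_qc_report(qc$report, file.path(parsed$out, "qc_report.tsv"))
  } else {
    qc <- apply_qc(inp$gm, inp$subjects, hwe_alpha = parsed$hwe_alpha)
    assoc <- associate_panel(qc$gm, inp$subjects)
    if (cmd == "assoc") {
      write_assoc_table(assoc, file.path(parsed$out, "association.tsv"))
    } else {
      qtab <- prune_and_adjust(
        stats::setNames(assoc$p, assoc$snp_id)[!is.na(assoc$p)], qc$gm,
        r2_threshold = parsed$r2_threshold)
      assoc$q <- qtab$q[match(assoc$snp_id, qtab$snp_id)]
      if (cmd == "fdr") {
        utils::write.table(qtab, file.path(parsed$out, "qvalues.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
      } else if (cmd == "bootstrap") {
        sig <- !is.na(assoc$q) & assoc$q < parsed$q_threshold
        boot <- bootstrap_panel(qc$gm, inp$subjects,
                                assoc[sig, , drop = FALSE],
                                B = parsed$boot_B, seed = parsed$seed)
        for (col in c("boot_p05", "boot_p01", "boot_p001", "boot_or_median")) {
          assoc[[col]] <- NA
          assoc[[col]][sig] <- boot[[col]]
        }
        write_assoc_table(assoc, file.path(parsed$out, "association.tsv"))
      } else if (cmd == "cumulative") {
        panel <- unfavorable_panel(assoc, rule = "q",
                                   alpha = parsed$q_threshold)
        counts <- count_unfavorable(qc$gm, panel, inp$subjects)
        risk <- group_or_trend(counts, inp$subjects)
        write_risk_groups(risk, file.path(parsed$out, "risk_groups.tsv"))
      } else {
        p_sig <- assoc$snp_id[!is.na(assoc$p) & assoc$p < parsed$alpha]
        tree <- grow_tree(qc$gm, inp$subjects, p_sig,
                          alpha = parsed$cart_alpha,
                          min_node_size = parsed$cart_min_node)
        writeLines(render_tree(tree), file.path(parsed$out, "cart_tree.txt"))
        if (tree$n_terminal > 1L)
          write_cart_nodes(terminal_node_ors(tree, inp$subjects),
                           file.path(parsed$out, "cart_nodes.tsv"))
      }
    }
  }
  invisible(0L)
}
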