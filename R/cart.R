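#' Candidate carrier-dichotomy splits for a node
#'
#' For every SNP in the panel, scores both carrier collapses — WW vs WV+VV
#' ("dominant") and WW+WV vs VV ("recessive") — by the 1-df Pearson
#' chi-square p of the dichotomy-by-status 2x2 table over the node's
#' subjects.  Splits sending every subject (with a non-missing call, before
#' majority routing) to one side are excluded; monomorphic SNPs contribute
#' none.
#'
#' @param node_ids subject ids in the node.
#' @param snp_panel SNP ids considered, in tie-break priority order.
#' @param gm a `genotype_matrix`.
#' @param subjects a `subject_table`.
#' @return data.frame: snp_id, dichotomy (`"WW|WV+VV"` or `"WW+WV|VV"`),
#'   p_split, chi2; ordered by panel, dominant split first.
#' @export
candidate_splits <- function(node_ids, snp_panel, gm, subjects) {
  status <- subjects$status[match(node_ids, subjects$id)]
  rows <- match(node_ids, subject_ids(gm))
  out <- list()
  for (s in snp_panel) {
    g <- gm$calls[rows, s]
    for (d in c("WW|WV+VV", "WW+WV|VV")) {
      x <- if (d == "WW|WV+VV") code_genotype(g, "dominant")
           else code_genotype(g, "recessive")
      ok <- !is.na(x)
      if (!any(ok) || length(unique(x[ok])) < 2L) next
      a <- sum(x == 1 & status == "case", na.rm = TRUE)
      b <- sum(x == 0 & status == "case", na.rm = TRUE)
      cc <- sum(x == 1 & status == "control", na.rm = TRUE)
      dd <- sum(x == 0 & status == "control", na.rm = TRUE)
      cs <- chisq_2x2(a, b, cc, dd)
      out[[length(out) + 1L]] <-
        data.frame(snp_id = s, dichotomy = d, p_split = cs$p, chi2 = cs$chi2,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(snp_id = character(0), dichotomy = character(0),
                      p_split = numeric(0), chi2 = numeric(0)))
  do.call(rbind, out)
}

# Route node subjects by a split: left = "low" side (WW, or WW+WV), right =
# carrier side. Missing genotypes follow the majority child.
.route_split <- function(node_ids, snp_id, dichotomy, gm) {
  g <- gm$calls[match(node_ids, subject_ids(gm)), snp_id]
  x <- if (dichotomy == "WW|WV+VV") code_genotype(g, "dominant")
       else code_genotype(g, "recessive")
  left <- !is.na(x) & x == 0
  right <- !is.na(x) & x == 1
  if (any(is.na(x))) {
    if (sum(right) >= sum(left)) right[is.na(x)] <- TRUE
    else left[is.na(x)] <- TRUE
  }
  list(left = node_ids[left], right = node_ids[right])
}

#' Grow a recursive-partitioning tree with chi-square goodness-of-split
#'
#' Deterministic binary CART over carrier dichotomizations: at each node the
#' minimum-p candidate split is applied while `p_split < alpha`, both
#' children have at least `min_node_size` subjects, and depth is below
#' `max_depth`.  Ties break by panel order, then dominant before recessive
#' dichotomy.  No randomness is involved.
#'
#' @param gm a `genotype_matrix`.
#' @param subjects a `subject_table`.
#' @param snp_panel SNP ids used as split attributes.
#' @param alpha goodness-of-split threshold (default 0.05).
#' @param min_node_size minimum subjects per child (default 20).
#' @param max_depth maximum split depth (default 10).
#' @return object of class `cart_tree`: `root` (nested node list with
#'   fields id, depth, ids, case_n, control_n, split, children),
#'   `n_terminal`, plus the calling parameters.
#' @export
grow_tree <- function(gm, subjects, snp_panel, alpha = 0.05,
                      min_node_size = 20, max_depth = 10) {
  stopifnot(length(snp_panel) > 0, all(snp_panel %in% snp_ids(gm)))
  status <- function(ids) {
    st <- subjects$status[match(ids, subjects$id)]
    c(case_n = sum(st == "case"), control_n = sum(st == "control"))
  }
  counter <- new.env(); counter$i <- 0L
  build <- function(ids, depth) {
    counter$i <- counter$i + 1L
    cn <- status(ids)
    node <- list(id = counter$i, depth = depth, ids = ids,
                 case_n = unname(cn["case_n"]),
                 control_n = unname(cn["control_n"]),
                 split = NULL, children = NULL)
    if (depth >= max_depth || length(ids) < 2 * min_node_size) return(node)
    cand <- candidate_splits(ids, snp_panel, gm, subjects)
    if (!nrow(cand)) return(node)
    # stable tie-break: panel order then dichotomy order (as enumerated)
    cand <- cand[order(cand$p_split), , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      if (cand$p_split[k] >= alpha) break
      halves <- .route_split(ids, cand$snp_id[k], cand$dichotomy[k], gm)
      if (length(halves$left) >= min_node_size &&
          length(halves$right) >= min_node_size) {
        node$split <- list(snp_id = cand$snp_id[k],
                           dichotomy = cand$dichotomy[k],
                           p_split = cand$p_split[k])
        node$children <- list(left = build(halves$left, depth + 1L),
                              right = build(halves$right, depth + 1L))
        break
      }
    }
    node
  }
  root <- build(subjects$id, 0L)
  tree <- structure(list(root = root, alpha = alpha,
                         min_node_size = min_node_size,
                         max_depth = max_depth, snp_panel = snp_panel),
                    class = "cart_tree")
  tree$n_terminal <- length(terminal_nodes(tree))
  tree
}

#' Terminal nodes of a CART tree
#' @param tree a `cart_tree`.
#' @return list of terminal node lists, in left-to-right tree order.
#' @export
terminal_nodes <- function(tree) {
  walk <- function(node) {
    if (is.null(node$split)) return(list(node))
    c(walk(node$children$left), walk(node$children$right))
  }
  walk(tree$root)
}

#' @export
print.cart_tree <- function(x, ...) {
  cat(render_tree(x), sep = "\n")
  invisible(x)
}

#' Terminal-node odds ratios versus the lowest-risk node
#'
#' Orders terminal nodes by ascending case fraction (node 1 = lowest risk,
#' the reference), then fits the adjusted OR of each node versus node 1 and
#' a trend test over the ordered node index.
#'
#' @param tree a `cart_tree`.
#' @param subjects a `subject_table`.
#' @param adjust adjust for age/ethnicity/smoking (default TRUE).
#' @return data.frame of class `cart_node_table`: node, case_n, control_n,
#'   case_pct, or, ci_low, ci_high, p, infinite; attribute `trend_p`.
#' @export
terminal_node_ors <- function(tree, subjects, adjust = TRUE) {
  terms <- terminal_nodes(tree)
  frac <- vapply(terms, function(n) n$case_n / (n$case_n + n$control_n), 0)
  ord <- order(frac, vapply(terms, `[[`, 0L, "id"))
  terms <- terms[ord]
  ref <- terms[[1L]]
  if (ref$case_n == 0 || ref$control_n == 0)
    stop("reference node lacks cases or controls")
  node_of <- rep(NA_integer_, nrow(subjects))
  for (k in seq_along(terms))
    node_of[match(terms[[k]]$ids, subjects$id)] <- k
  stopifnot(!anyNA(node_of))
  y <- as.numeric(subjects$status == "case")
  X0 <- if (adjust) build_design(subjects)
        else matrix(1, length(y), 1L, dimnames = list(NULL, "(Intercept)"))
  rows <- lapply(seq_along(terms), function(k) {
    nd <- terms[[k]]
    base <- data.frame(node = k, case_n = nd$case_n, control_n = nd$control_n,
                       case_pct = 100 * nd$case_n / (nd$case_n + nd$control_n))
    if (k == 1L)
      return(cbind(base, or = 1, ci_low = NA_real_, ci_high = NA_real_,
                   p = NA_real_, infinite = FALSE))
    if (nd$control_n == 0)
      return(cbind(base, or = Inf, ci_low = NA_real_, ci_high = NA_real_,
                   p = NA_real_, infinite = TRUE))
    sel <- node_of %in% c(1L, k)
    fit <- fit_logistic(y[sel], cbind(X0[sel, , drop = FALSE],
                                      grp = as.numeric(node_of[sel] == k)))
    if (!fit$ok)
      return(cbind(base, or = NA_real_, ci_low = NA_real_,
                   ci_high = NA_real_, p = NA_real_, infinite = FALSE))
    b <- unname(fit$beta["grp"]); se <- unname(fit$se["grp"])
    cbind(base, or = exp(b), ci_low = exp(b - 1.96 * se),
          ci_high = exp(b + 1.96 * se), p = unname(fit$p["grp"]),
          infinite = FALSE)
  })
  out <- do.call(rbind, rows)
  trend_fit <- fit_logistic(y, cbind(X0, trend = as.numeric(node_of - 1L)))
  attr(out, "trend_p") <- if (trend_fit$ok) unname(trend_fit$p["trend"]) else NA_real_
  class(out) <- c("cart_node_table", "data.frame")
  out
}

#' Serialize a CART tree as indented text
#'
#' One line per node; splits show the SNP and the WW/WV/VV dichotomy labels,
#' terminals show case/control counts.  Deterministic, and parseable back
#' with [parse_tree()].
#'
#' @param tree a `cart_tree`.
#' @return character vector of lines.
#' @export
render_tree <- function(tree) {
  walk <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (is.null(node$split))
      return(sprintf("%sleaf cases=%d controls=%d", pad,
                     node$case_n, node$control_n))
    c(sprintf("%ssplit %s [%s] p=%.6g cases=%d controls=%d", pad,
              node$split$snp_id, node$split$dichotomy, node$split$p_split,
              node$case_n, node$control_n),
      walk(node$children$left, indent + 1L),
      walk(node$children$right, indent + 1L))
  }
  walk(tree$root, 0L)
}

#' Parse [render_tree()] output back into a structural tree
#'
#' Subject id lists are not serialized, so the result carries structure and
#' counts only (fields snp_id, dichotomy, p_split, case_n, control_n,
#' children).
#'
#' @param lines character vector from [render_tree()].
#' @return nested node list of class `cart_structure`.
#' @export
parse_tree <- function(lines) {
  depth <- nchar(sub("\\S.*$", "", lines)) / 2L
  parse_at <- function(i) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "leaf")) {
      m <- as.integer(regmatches(ln, gregexpr("[0-9]+", ln))[[1L]])
      return(list(node = list(snp_id = NULL, case_n = m[1L], control_n = m[2L],
                              children = NULL), next_i = i + 1L))
    }
    snp <- sub("^split (\\S+) .*$", "\\1", ln)
    dich <- sub("^.*\\[(.*)\\].*$", "\\1", ln)
    p <- as.numeric(sub("^.*p=(\\S+) .*$", "\\1", ln))
    cn <- as.integer(sub("^.*cases=([0-9]+) .*$", "\\1", ln))
    ctn <- as.integer(sub("^.*controls=([0-9]+)$", "\\1", ln))
    left <- parse_at(i + 1L)
    right <- parse_at(left$next_i)
    list(node = list(snp_id = snp, dichotomy = dich, p_split = p,
                     case_n = cn, control_n = ctn,
                     children = list(left = left$node, right = right$node)),
         next_i = right$next_i)
  }
  structure(parse_at(1L)$node, class = "cart_structure")
}

# Structural skeleton of a grown tree, comparable with parse_tree() output.
tree_structure <- function(tree) {
  walk <- function(node) {
    if (is.null(node$split))
      return(list(snp_id = NULL, case_n = node$case_n,
                  control_n = node$control_n, children = NULL))
    list(snp_id = node$split$snp_id, dichotomy = node$split$dichotomy,
         p_split = node$split$p_split, case_n = node$case_n,
         control_n = node$control_n,
         children = list(left = walk(node$children$left),
                         right = walk(node$children$right)))
  }
  structure(walk(tree$root), class = "cart_structure")
}

#' Write the CART node table as TSV
#' @param tab a `cart_node_table`.
#' @param path output path.
#' @export
write_cart_nodes <- function(tab, path) {
  df <- as.data.frame(tab)
  df$trend_p <- attr(tab, "trend_p")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
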