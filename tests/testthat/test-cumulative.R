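test_that("unfavorable_direction orients by OR sign under each model", {
  # risk-increasing dominant SNP: carriers unfavorable
  r <- data.frame(snp_id = "rs2889", model = "dominant", or = 1.53)
  sp <- unfavorable_direction(r)
  expect_equal(sp$unfavorable_genotypes, c(1L, 2L))
  expect_equal(sp$direction, "exposed")

  # protective recessive SNP: the non-homozygous-variant group unfavorable
  r <- data.frame(snp_id = "rs11152377", model = "recessive", or = 0.53)
  sp <- unfavorable_direction(r)
  expect_equal(sp$unfavorable_genotypes, c(0L, 1L))
  expect_equal(sp$direction, "unexposed")

  # protective additive SNP: carrier split, non-carriers unfavorable
  r <- data.frame(snp_id = "rs135014", model = "additive", or = 0.73)
  sp <- unfavorable_direction(r)
  expect_equal(sp$unfavorable_genotypes, 0L)

  r <- data.frame(snp_id = "rsX", model = "dominant", or = 1)
  expect_message(sp <- unfavorable_direction(r), "OR exactly 1")
  expect_null(sp)
})

test_that("count_unfavorable counts spec membership; missing contributes 0", {
  specs <- list(
    structure(list(snp_id = "rs1", unfavorable_genotypes = c(1L, 2L)),
              class = "unfavorable_spec"),
    structure(list(snp_id = "rs2", unfavorable_genotypes = 2L),
              class = "unfavorable_spec"),
    structure(list(snp_id = "rs3", unfavorable_genotypes = c(0L, 1L)),
              class = "unfavorable_spec"))
  calls <- rbind(S1 = c(1L, 2L, 0L),   # matches all three
                 S2 = c(0L, 2L, 2L),   # matches rs2 only
                 S3 = c(NA, NA, NA),   # all missing -> 0
                 S4 = c(2L, 0L, 1L))   # rs1 and rs3
  gm <- make_gm(calls, snp_ids = c("rs1", "rs2", "rs3"))
  counts <- count_unfavorable(gm, specs)
  expect_equal(unname(counts), c(3L, 1L, 0L, 2L))
})

test_that("quartile_groups: nearest-rank percentile arithmetic", {
  # 0..3 each x25 -> four singleton groups
  g <- quartile_groups(rep(0:3, each = 25))
  expect_equal(g$lo, 0:3)
  expect_equal(g$hi, 0:3)
  expect_equal(g$label, as.character(0:3))

  # all-identical counts collapse to a single group, with a warning
  expect_warning(g1 <- quartile_groups(rep(7, 50)), "fewer than 4")
  expect_equal(nrow(g1), 1)

  # distribution shaped like the published cohort: cuts at 7 / 9 / 10
  counts <- rep(c(3:7, 8, 9, 10, 11, 12),
                c(rep(42, 5), 103, 107, 209, 104, 104))
  g2 <- quartile_groups(counts)
  expect_equal(g2$label, c("3~7", "8~9", "10", "11~12"))

  # groups partition the observed range for random inputs (property)
  set.seed(33)
  for (i in 1:50) {
    x <- sample(0:12, 200, replace = TRUE)
    gg <- suppressWarnings(quartile_groups(x))
    idx <- assign_risk_group(x, gg)
    expect_true(all(idx >= 1 & idx <= nrow(gg)))
    expect_true(all(x >= gg$lo[idx] & x <= gg$hi[idx])) # containment
    expect_equal(sort(unique(idx)), seq_len(nrow(gg))) # no empty group
  }
})

test_that("group ORs reproduce published cumulative cross-products (unadjusted)", {
  cum <- study_fixture("cumulative")
  # rebuild subject-level counts: group label -> a representative count value
  rep_count <- c("3~7" = 5L, "8~9" = 8L, "10" = 10L, "11~12" = 11L)
  counts <- rep(rep_count[cum$label], cum$case_n + cum$control_n)
  status <- unlist(mapply(function(ca, co) rep(c("case", "control"), c(ca, co)),
                          cum$case_n, cum$control_n))
  subjects <- subject_table(id = sprintf("S%03d", seq_along(counts)),
                            status = status, age = 60,
                            ethnicity = "White", smoking = "Never")
  # the published groups are not exact quartiles of their own count
  # distribution (group 1 holds ~12% of subjects), so the boundaries are
  # supplied explicitly; quartile arithmetic is tested separately above
  bounds <- data.frame(group = 1:4, lo = c(3L, 8L, 10L, 11L),
                       hi = c(7L, 9L, 10L, 12L),
                       label = c("3~7", "8~9", "10", "11~12"))
  tab <- group_or_trend(unname(counts), subjects, adjust = FALSE,
                        groups = bounds)
  expect_equal(tab$case_n, cum$case_n)
  expect_equal(tab$control_n, cum$control_n)
  expect_equal(tab$or, c(1, 2.598, 4.2595, 7.1905), tolerance = 1e-3)
  expect_lt(attr(tab, "trend_p"), 0.001)
})

test_that("identical case fractions across groups give OR 1, flat trend", {
  counts <- rep(c(1L, 5L, 9L, 12L), each = 100)
  status <- rep(rep(c("case", "control"), 50), 4)
  subjects <- subject_table(id = sprintf("S%03d", 1:400), status = status,
                            age = 55, ethnicity = "White", smoking = "Never")
  tab <- group_or_trend(counts, subjects, adjust = FALSE)
  expect_equal(tab$or, rep(1, 4), tolerance = 1e-8)
  expect_gt(attr(tab, "trend_p"), 0.9)
})

test_that("reversing every spec maps count c to (#specs - c)", {
  set.seed(44)
  specs <- list(
    structure(list(snp_id = "rs1", unfavorable_genotypes = c(1L, 2L)),
              class = "unfavorable_spec"),
    structure(list(snp_id = "rs2", unfavorable_genotypes = 2L),
              class = "unfavorable_spec"),
    structure(list(snp_id = "rs3", unfavorable_genotypes = 0L),
              class = "unfavorable_spec"))
  flipped <- lapply(specs, function(sp) {
    sp$unfavorable_genotypes <- setdiff(0:2, sp$unfavorable_genotypes)
    sp
  })
  gm <- make_gm(matrix(sample(0:2, 60, TRUE), 20, 3),
                snp_ids = c("rs1", "rs2", "rs3"))
  c1 <- count_unfavorable(gm, specs)
  c2 <- count_unfavorable(gm, flipped)
  expect_equal(unname(c1 + c2), rep(3L, 20))
})

test_that("monotone group ORs emerge under a log-additive risk simulation", {
  # scaled-down: 30 replications, majority must be fully monotone
  monotone <- 0L
  for (r in 1:30) {
    set.seed(600 + r)
    n <- 600
    k <- 8
    x <- matrix(rbinom(n * k, 1, 0.5), n, k)  # unfavorable indicators
    y <- rbinom(n, 1, plogis(-1.5 + 0.35 * rowSums(x)))
    subjects <- subject_table(id = sprintf("S%04d", 1:n),
                              status = ifelse(y == 1, "case", "control"),
                              age = rnorm(n, 60, 8), ethnicity = "White",
                              smoking = "Never")
    tab <- suppressWarnings(group_or_trend(rowSums(x), subjects,
                                           adjust = FALSE))
    ors <- tab$or[!is.na(tab$or)]
    if (all(diff(ors) > 0)) monotone <- monotone + 1L
  }
  expect_gt(monotone, 15)
})

test_that("unfavorable_panel applies the q and p rules", {
  assoc <- data.frame(snp_id = c("a", "b", "c"),
                      model = c("dominant", "recessive", "dominant"),
                      or = c(1.6, 0.5, 1.2),
                      p = c(0.001, 0.002, 0.2),
                      q = c(0.01, 0.2, 0.9))
  expect_length(unfavorable_panel(assoc, rule = "q"), 1)
  expect_length(unfavorable_panel(assoc, rule = "p"), 2)
  expect_error(unfavorable_panel(assoc[, -5], rule = "q"), "q column")
})
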