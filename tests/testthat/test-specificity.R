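ref_fixture <- function(vals_target, vals_bg, gene_ids = NULL) {
  n_bg <- length(vals_bg[[1]])
  expr <- make_expr(c(list(EC = vals_target), vals_bg), gene_ids = gene_ids)
  sheet <- make_sheet(names(expr)[-1],
                      c("target", rep("background", length(vals_bg))))
  list(expr = expr, sheet = sheet)
}

test_that("present/absent calls use the strict 50% rule", {
  fx <- ref_fixture(c(100, 100, 0),
                    list(c1 = c(51, 50, 5), c2 = c(200, 10, 0)))
  calls <- present_absent_calls(fx$expr, fx$sheet)
  lookup <- function(g, s) calls$call[calls$gene_id == g & calls$sample_id == s]
  expect_identical(lookup("g01", "c1"), "present")  # 51 > 50
  expect_identical(lookup("g02", "c1"), "absent")   # 50 is not > 50
  expect_identical(lookup("g02", "c2"), "absent")
  # L = 0: every positive value present, zero absent
  expect_identical(lookup("g03", "c1"), "present")
  expect_identical(lookup("g03", "c2"), "absent")
})

test_that("enrichment score is the absent fraction and permutation invariant", {
  expect_identical(enrichment_score(rep("absent", 6)), 1)
  expect_identical(enrichment_score(rep("present", 4)), 0)
  expect_identical(enrichment_score(c("absent", "absent", "absent", "present")),
                   0.75)
  expect_error(enrichment_score(character()), class = "restrictr_usage_error")
  expect_error(enrichment_score(c("absent", "maybe")),
               class = "restrictr_usage_error")

  set.seed(5)
  calls <- sample(c("present", "absent"), 20, replace = TRUE)
  for (i in 1:5) {
    expect_identical(enrichment_score(sample(calls)), enrichment_score(calls))
  }
})

test_that("outlier analysis matches direct arithmetic and classifies lineage", {
  vals <- c(1, 1, 1, 1, 1, 1, 10)
  ids <- paste0("s", 1:7)
  expr <- make_expr(setNames(as.list(vals), ids), gene_ids = "g1")
  # direct arithmetic: mu = 16/7, s = sd(vals); only s7 exceeds 2s
  mu <- mean(vals); s <- sd(vals)
  expect_true(abs(10 - mu) > 2 * s)
  expect_true(all(abs(1 - mu) <= 2 * s))

  sheet_t <- make_sheet(ids, c(rep("background", 6), "target"))
  res <- outlier_analysis(expr, sheet_t)
  expect_identical(res$outlier_samples[[1]], "s7")
  expect_identical(res$outlier_class, "target_only")

  sheet_b <- make_sheet(ids, c(rep("target", 6), "background"))
  res <- outlier_analysis(expr, sheet_b)
  expect_identical(res$outlier_class, "mixed")

  const <- make_expr(setNames(as.list(rep(5, 7)), ids), gene_ids = "g1")
  res <- outlier_analysis(const, sheet_t)
  expect_identical(res$outlier_class, "none")
  expect_length(res$outlier_samples[[1]], 0L)

  # a low-side target outlier is not a restricted-gene signature
  low <- make_expr(setNames(as.list(c(10, 10, 10, 10, 10, 10, 1)), ids),
                   gene_ids = "g1")
  res <- outlier_analysis(low, sheet_t)
  expect_identical(res$outlier_class, "mixed")
})

test_that("reference fold change reduces to the planted ratio", {
  fx <- ref_fixture(c(64.625 * 20, 100, 400),
                    list(c1 = c(20, 100, 400), c2 = c(20, 100, 400)))
  rf <- ref_fold(fx$expr, fx$sheet)
  expect_equal(rf$ref_fold, c(64.625, 1, 1))

  cfg <- sim_config(n_genes = 30L, n_restricted = 1L, noise_log_sd = 0,
                    fold_range = c(20, 20 + 1e-12), pattern_mix = 0, seed = 2L)
  d <- generate_primary_dataset(cfg)
  r <- generate_reference_compendium(cfg, d$truth)
  rf <- ref_fold(r$expression, r$samples)
  planted <- d$truth$gene_id[d$truth$is_restricted]
  expect_equal(rf$ref_fold[rf$gene_id == planted], 20, tolerance = 1e-9)
})

test_that("rank score is the product of the two fold changes", {
  expect_identical(rank_score(1, 7.5), 7.5)
  expect_equal(rank_score(c(2, 3), c(4, 5)), c(8, 15))
  expect_error(rank_score(-1, 2), class = "restrictr_usage_error")
  expect_error(rank_score(2, 0), class = "restrictr_usage_error")
})

test_that("specificity monotonicity: lowering a non-target cell never hurts", {
  set.seed(9)
  fx <- ref_fixture(rlnorm(20, 5),
                    list(c1 = rlnorm(20, 4.4), c2 = rlnorm(20, 4.4),
                         c3 = rlnorm(20, 4.4)))
  base_ecs <- enrichment_score(present_absent_calls(fx$expr, fx$sheet))
  base_rf <- ref_fold(fx$expr, fx$sheet)
  lowered <- fx$expr
  lowered$c2 <- lowered$c2 * 0.3
  new_ecs <- enrichment_score(present_absent_calls(lowered, fx$sheet))
  new_rf <- ref_fold(lowered, fx$sheet)
  expect_true(all(new_ecs$ecs >= base_ecs$ecs))
  expect_true(all(new_rf$ref_fold >= base_rf$ref_fold))
})

test_that("selection keeps the top fraction of the eligible pool", {
  records <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:12),
    fc = c(10, 9, 8, 7, 6, 5, 4, 3, 2.5, 2, 50, 40),
    ecs = c(rep(1, 10), 0.9, 1),
    outlier_class = c(rep("target_only", 11), "mixed"),
    ref_fold = c(10, 9, 8, 7, 6, 5, 4, 3, 2.9, 3, 50, 40),
    outlier_samples = replicate(12, "EC", simplify = FALSE)
  )
  records$rank_score <- records$fc * records$ref_fold
  # pool: g01..g08 and g10 (g09 fails ref_fold, g11 fails ecs, g12 outlier)
  sel <- select_restricted(records, top_fraction = 0.60, min_ref_fold = 3)
  expect_identical(nrow(sel), 6L)  # ceiling(0.6 * 9)
  expect_false("g09" %in% sel$gene_id)
  expect_false("g11" %in% sel$gene_id)
  expect_false("g12" %in% sel$gene_id)
  expect_identical(sel$gene_id, sel$gene_id[order(-sel$rank_score, sel$gene_id)])

  # pool of 10 keeps 6
  pool10 <- records[1:10, ]
  pool10$ref_fold[9] <- 3
  pool10$rank_score <- pool10$fc * pool10$ref_fold
  expect_identical(nrow(select_restricted(pool10)), 6L)

  # deny and allow lists act after the top-fraction cut
  sel <- select_restricted(pool10, denylist = "g01", allowlist = "g10")
  expect_false("g01" %in% sel$gene_id)
  expect_true("g10" %in% sel$gene_id)

  expect_warning(empty <- select_restricted(records[11:12, ]), "empty")
  expect_identical(nrow(empty), 0L)
})

test_that("rank ties are broken lexicographically and reproducibly", {
  records <- tibble::tibble(
    gene_id = c("gB", "gA", "gC"),
    fc = 4, ecs = 1, outlier_class = "target_only", ref_fold = 4,
    outlier_samples = replicate(3, "EC", simplify = FALSE),
    rank_score = 16
  )
  sel <- select_restricted(records, top_fraction = 2 / 3)
  expect_identical(sel$gene_id, c("gA", "gB"))
  expect_identical(select_restricted(records, top_fraction = 2 / 3)$gene_id,
                   sel$gene_id)
})
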