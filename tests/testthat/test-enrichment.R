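test_that("Fisher over-representation matches the closed form", {
  bg <- sprintf("g%02d", 1:20)
  set5 <- bg[1:5]
  res <- fisher_overrepresentation(bg[1:5], set5, bg)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_identical(res$overlap, 5L)

  res <- fisher_overrepresentation(bg[6:10], set5, bg)
  expect_identical(res$overlap, 0L)
  expect_identical(res$p_value, 1)

  res <- fisher_overrepresentation(bg, set5, bg)
  expect_identical(res$overlap, res$set_size)
  expect_identical(res$p_value, 1)

  expect_error(fisher_overrepresentation("x", "x", character()),
               class = "restrictr_usage_error")
  expect_error(fisher_overrepresentation("zz", set5, bg),
               class = "restrictr_usage_error")
})

test_that("EASE score penalizes the overlap by one study gene", {
  bg <- sprintf("g%02d", 1:20)
  set5 <- bg[1:5]
  expect_identical(ease_score(bg[c(1, 6:9)], set5, bg), 1)  # singleton overlap
  expect_equal(ease_score(bg[1:5], set5, bg),
               oracle_hyper_tail(4, 5, 20, 4), tolerance = 1e-12)

  set.seed(17)
  for (i in 1:25) {
    N <- sample(8:30, 1)
    bg <- sprintf("b%02d", 1:N)
    study <- sample(bg, sample(2:N, 1))
    gset <- sample(bg, sample(1:N, 1))
    f <- fisher_overrepresentation(study, gset, bg)$p_value
    e <- ease_score(study, gset, bg)
    expect_gte(e, f - 1e-12)
  }
})

test_that("BH adjustment follows the step-up recursion", {
  expect_identical(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "restrictr_usage_error")
  set.seed(3)
  p <- runif(40)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p - 1e-12))
  # monotone with respect to the p-value order
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-12))
})

test_that("gene-set enrichment table combines Fisher, EASE and BH", {
  bg <- sprintf("g%02d", 1:30)
  collection <- tibble::tibble(
    set_id = c("hit", "miss"),
    description = c("", ""),
    genes = list(bg[1:6], bg[25:30])
  )
  res <- gene_set_enrichment(bg[1:6], collection, bg)
  expect_identical(res$set_id[1], "hit")
  expect_equal(res$p_value[res$set_id == "hit"],
               oracle_hyper_tail(6, 6, 30, 6), tolerance = 1e-12)
  expect_true(all(res$adjusted_p >= res$p_value - 1e-12))
  expect_true(all(res$ease_p >= res$p_value - 1e-12))
})

test_that("promoter-site gate requires both the p-value and the ratio", {
  res <- site_enrichment_gate(20, 40, 20, 40)
  expect_equal(res$ratio, 1)
  expect_false(res$passes_gate)

  res <- site_enrichment_gate(12, 40, 10, 40)
  expect_gt(res$p_value, 0.01)
  expect_false(res$passes_gate)

  res <- site_enrichment_gate(30, 40, 10, 40)
  expect_equal(res$p_value, oracle_hyper_tail(30, 40, 80, 40),
               tolerance = 1e-10)
  expect_gt(res$ratio, 1.2)
  expect_true(res$passes_gate)

  expect_warning(res <- site_enrichment_gate(10, 40, 0, 40), "p-value only")
  expect_identical(res$ratio, Inf)
  expect_identical(res$passes_gate, res$p_value < 0.01)

  expect_error(site_enrichment_gate(50, 40, 1, 40),
               class = "restrictr_usage_error")

  tbl <- tibble::tibble(set_id = c("M1", "M2"),
                        yes_hits = c(30, 12), yes_n = 40,
                        no_hits = c(10, 10), no_n = 40)
  res <- site_enrichment(tbl)
  expect_identical(res$set_id, c("M1", "M2"))
  expect_true(res$passes_gate[1] && !res$passes_gate[2])
})

test_that("seed matching finds reverse-complement sites greedily", {
  mir <- tibble::tibble(id = "miR-x", sequence = "UGGAAUGUAAAGAAGUAUGUAU")
  seed7 <- substr("TGGAATGTAAAGAAGTATGTAT", 2, 8)      # GGAATGT
  site <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seed7)))
  expect_identical(site, "ACATTCC")

  utr <- tibble::tibble(id = "u1", sequence = site)
  m <- mirna_seed_match(utr, mir)
  expect_identical(m$n_sites, 1L)
  expect_identical(m$site_positions[[1]], 0L)

  utr <- tibble::tibble(id = "u1", sequence = "GGGGGGGGGGGGGG")
  expect_identical(nrow(mirna_seed_match(utr, mir)), 0L)

  # two tandem copies separated by one base -> 2 sites
  utr <- tibble::tibble(id = "u1", sequence = paste0(site, "A", site))
  m <- mirna_seed_match(utr, mir)
  expect_identical(m$n_sites, 2L)
  expect_identical(m$site_positions[[1]], c(0L, 8L))

  # case and U/T encoding do not change the counts
  utr_ut <- tibble::tibble(id = "u1",
                           sequence = tolower(chartr("T", "U", paste0(site, "A", site))))
  expect_identical(mirna_seed_match(utr_ut, mir)$n_sites, 2L)

  # UTR shorter than the seed has no sites
  short <- tibble::tibble(id = "u1", sequence = "ACAT")
  expect_identical(nrow(mirna_seed_match(short, mir)), 0L)
})

test_that("greedy counts equal the exhaustive offset-scan oracle", {
  set.seed(23)
  mirs <- tibble::tibble(id = paste0("m", 1:5),
                         sequence = replicate(5, random_dna(22)))
  utrs <- tibble::tibble(id = paste0("u", 1:50),
                         sequence = replicate(50, random_dna(200, c("G", "T"))))
  # GT-alphabet UTRs produce runs of overlapping candidate sites for the
  # AC-repeat seed below (reverse complement TGTGTGT), stressing greediness
  mirs$sequence[1] <- paste0("G", paste(rep("AC", 10), collapse = ""))
  m <- mirna_seed_match(utrs, mirs)
  for (i in seq_len(nrow(m))) {
    site <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
      substr(chartr("U", "T", mirs$sequence[mirs$id == m$mirna_id[i]]), 2, 8))))
    oracle <- oracle_greedy_sites(utrs$sequence[utrs$id == m$gene_id[i]], site)
    expect_identical(m$site_positions[[i]], oracle)
  }
  # and no hits were missed: recompute the full pair table from the oracle
  n_oracle <- 0L
  for (mid in mirs$id) {
    site <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
      substr(chartr("U", "T", mirs$sequence[mirs$id == mid]), 2, 8))))
    for (uid in utrs$id) {
      hits <- oracle_greedy_sites(utrs$sequence[utrs$id == uid], site)
      if (length(hits) > 0) n_oracle <- n_oracle + 1L
    }
  }
  expect_identical(nrow(m), n_oracle)
})

test_that("miRNA enrichment compares genes-with-sites by Fisher + BH", {
  study <- tibble::tibble(mirna_id = "m1", n_genes_hit = 5L)
  background <- tibble::tibble(mirna_id = "m1", n_genes_hit = 5L)
  res <- mirna_enrichment(study, background, 5L, 20L)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)

  # equal composition: p stays near 1 and never below the point mass
  study <- tibble::tibble(mirna_id = "m1", n_genes_hit = 5L)
  background <- tibble::tibble(mirna_id = "m1", n_genes_hit = 10L)
  res <- mirna_enrichment(study, background, 10L, 20L)
  point_mass <- choose(10, 5) * choose(10, 5) / choose(20, 10)
  expect_gt(res$p_value, 0.5)
  expect_gte(res$p_value, point_mass)

  empty <- tibble::tibble(mirna_id = character(), n_genes_hit = integer())
  res <- mirna_enrichment(empty, background, 10L, 20L)
  expect_identical(res$p_value, 1)

  expect_error(mirna_enrichment(study, background, 30L, 20L),
               class = "restrictr_usage_error")
  bad <- tibble::tibble(mirna_id = "m1", n_genes_hit = 12L)
  expect_error(mirna_enrichment(bad, background, 15L, 20L),
               class = "restrictr_usage_error")
})

test_that("sequence-level miRNA enrichment reports both hit units", {
  site <- "ACATTCC"
  mir <- tibble::tibble(id = "miR-x", sequence = "UGGAAUGUAAAGAAGUAUGUAU")
  study <- tibble::tibble(id = paste0("s", 1:4),
                          sequence = c(paste0(site, "A", site), site, site,
                                       "GGGGGGGG"))
  extra <- tibble::tibble(id = paste0("b", 1:6), sequence = "GGGGGGGGGG")
  background <- dplyr::bind_rows(study, extra)
  res <- mirna_site_enrichment(study, background, mir)
  expect_identical(res$study_genes_hit, 3L)
  expect_identical(res$study_sites_total, 4L)
  expect_equal(res$p_value, oracle_hyper_tail(3, 3, 10, 4), tolerance = 1e-12)
})
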