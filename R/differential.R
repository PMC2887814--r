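#' Per-gene fold change between two sample groups
#'
#' `fc = mean(target) / max(mean(background), eps)`.  The `eps` floor (1
#' signal unit by default) keeps ratios finite when a gene is essentially
#' silent in the background pool.
#'
#' @param expression Expression tibble (`gene_id` plus sample columns).
#' @param target_samples,background_samples Disjoint, non-empty character
#'   vectors of sample ids.
#' @param eps Denominator floor in signal units.
#' @return Tibble with columns `gene_id`, `fc`.
#' @export
fold_change <- function(expression, target_samples, background_samples, eps = 1) {
  g <- check_groups(expression, target_samples, background_samples, min_n = 1L)
  m <- expr_matrix(expression)
  fc <- rowMeans(m[, g$target, drop = FALSE]) /
    pmax(rowMeans(m[, g$background, drop = FALSE]), eps)
  tibble::tibble(gene_id = expression$gene_id, fc = unname(fc))
}

#' Lower confidence bound of the per-gene fold change
#'
#' The bound divides a one-sided lower confidence limit on the target mean
#' by a one-sided upper limit on the background mean, each at level
#' `1 - (1 - level)/2` (so the default `level = 0.90` uses two one-sided
#' 95% t bounds, a conservative 90% bound on the ratio):
#'
#' \deqn{lcb = \max\!\left(0, \frac{\bar x_t - t_{q,\,n_t-1}\, s_t/\sqrt{n_t}}
#'   {\bar x_b + t_{q,\,n_b-1}\, s_b/\sqrt{n_b}}\right)}
#'
#' The denominator shares the `eps` floor with [fold_change()], which
#' guarantees `lcb <= fc` for every gene.
#'
#' @inheritParams fold_change
#' @param level Nominal confidence level of the two-sided bound.
#' @return Tibble with columns `gene_id`, `fc`, `lcb`.
#' @export
lcb_fold_change <- function(expression, target_samples, background_samples,
                            level = 0.90, eps = 1) {
  g <- check_groups(expression, target_samples, background_samples, min_n = 2L)
  m <- expr_matrix(expression)
  lcb <- lcb_from_matrix(m, g$target, g$background, level, eps)
  fc <- rowMeans(m[, g$target, drop = FALSE]) /
    pmax(rowMeans(m[, g$background, drop = FALSE]), eps)
  tibble::tibble(gene_id = expression$gene_id, fc = unname(fc), lcb = unname(lcb))
}

# vectorized core shared with the permutation loop
lcb_from_matrix <- function(m, target, background, level = 0.90, eps = 1) {
  q <- 1 - (1 - level) / 2
  nt <- length(target); nb <- length(background)
  mt <- rowMeans(m[, target, drop = FALSE])
  mb <- rowMeans(m[, background, drop = FALSE])
  vt <- row_var(m[, target, drop = FALSE], mt)
  vb <- row_var(m[, background, drop = FALSE], mb)
  num <- mt - qt(q, nt - 1) * sqrt(vt / nt)
  den <- pmax(mb + qt(q, nb - 1) * sqrt(vb / nb), eps)
  pmax(0, num / den)
}

row_var <- function(m, means) {
  rowSums((m - means)^2) / (ncol(m) - 1L)
}

check_groups <- function(expression, target, background, min_n = 1L) {
  samples <- setdiff(names(expression), "gene_id")
  if (length(target) < min_n || length(background) < min_n) {
    abort(sprintf("each group needs at least %d sample(s)", min_n),
          class = "restrictr_usage_error")
  }
  if (length(intersect(target, background)) > 0) {
    abort("target and background samples must be disjoint",
          class = "restrictr_usage_error")
  }
  if (!all(c(target, background) %in% samples)) {
    abort("unknown sample id in group definition", class = "restrictr_usage_error")
  }
  list(target = target, background = background)
}

subgroup_samples <- function(sheet, subgroup) {
  target <- sheet$sample_id[sheet$lineage == "target" &
                              sheet$subgroup %in% subgroup]
  if (length(target) == 0L) {
    abort(sprintf("unknown or empty subgroup '%s'", subgroup),
          class = "restrictr_usage_error")
  }
  background <- sheet$sample_id[sheet$lineage == "background"]
  list(target = target, background = background)
}

#' Permutation estimate of the median false discovery rate
#'
#' Counts the genes whose LCB exceeds `lcb_threshold` under the true
#' target/background labels (R), then recomputes that count under random
#' label permutations that preserve the two group sizes.  The estimate is
#' `median(permuted counts) / R`, clipped to `[0, 1]`, with the convention
#' `fdr = 0` when `R = 0`.  When the design admits fewer distinct
#' permutations than `n_perm`, all distinct permutations are used with a
#' warning.
#'
#' @inheritParams call_de
#' @param lcb_threshold LCB cut-off defining the passing set.
#' @param n_perm Number of label permutations (>= 10).
#' @param seed Seed for the permutation stream.
#' @return One-row tibble with columns `comparison`, `n_pass`, `fdr`,
#'   `n_perm_used`.
#' @export
permutation_fdr <- function(expression, sheet, subgroup = NULL,
                            lcb_threshold = 3, n_perm = 100L, seed = 1L,
                            level = 0.90, eps = 1) {
  if (n_perm < 10L) {
    abort("n_perm must be at least 10", class = "restrictr_usage_error")
  }
  sheet <- validate_sample_sheet(sheet, expression)
  g <- if (is.null(subgroup)) {
    list(target = sheet$sample_id[sheet$lineage == "target"],
         background = sheet$sample_id[sheet$lineage == "background"])
  } else {
    subgroup_samples(sheet, subgroup)
  }
  m <- expr_matrix(expression)[, c(g$target, g$background), drop = FALSE]
  nt <- length(g$target)
  n <- ncol(m)
  cols <- colnames(m)

  observed <- sum(lcb_from_matrix(m, g$target, g$background, level, eps) >
                    lcb_threshold)

  n_distinct <- choose(n, nt)
  set.seed(seed)
  if (n_distinct <= n_perm) {
    warn("fewer distinct permutations than n_perm; using all of them")
    picks <- combn(n, nt, simplify = FALSE)
  } else {
    picks <- replicate(n_perm, sample.int(n, nt), simplify = FALSE)
  }
  perm_counts <- purrr::map_int(picks, function(idx) {
    sum(lcb_from_matrix(m, cols[idx], cols[-idx], level, eps) > lcb_threshold)
  })

  fdr <- if (observed == 0L) 0 else min(1, max(0, median(perm_counts) / observed))
  tibble::tibble(
    comparison = if (is.null(subgroup)) "target_vs_background"
                 else paste0(subgroup, "_vs_background"),
    n_pass = as.integer(observed),
    fdr = fdr,
    n_perm_used = length(picks)
  )
}

#' Call differential expression for one subgroup against the background pool
#'
#' A gene passes when its LCB exceeds `lcb_threshold` (strictly) *and* the
#' set-level permutation FDR of the comparison is below `fdr_threshold`.
#' The FDR is an attribute of the passing set, attached to every record of
#' the comparison, not a per-gene q-value.
#'
#' @param expression Expression tibble (`gene_id` plus sample columns).
#' @param sheet Sample sheet matching `expression`.
#' @param subgroup Target subgroup label to compare against the pooled
#'   background samples; `NULL` pools all target samples.
#' @param lcb_threshold,fdr_threshold The pass thresholds.
#' @param level Confidence level passed to [lcb_fold_change()].
#' @param eps Denominator floor in signal units.
#' @param n_perm,seed Permutation settings for the FDR estimate.
#' @return Tibble with columns `gene_id`, `comparison`, `fc`, `lcb`,
#'   `fdr`, `passes` (one row per gene).
#' @export
call_de <- function(expression, sheet, subgroup = NULL,
                    lcb_threshold = 3, fdr_threshold = 0.02,
                    level = 0.90, eps = 1, n_perm = 100L, seed = 1L) {
  sheet <- validate_sample_sheet(sheet, expression)
  g <- if (is.null(subgroup)) {
    list(target = sheet$sample_id[sheet$lineage == "target"],
         background = sheet$sample_id[sheet$lineage == "background"])
  } else {
    subgroup_samples(sheet, subgroup)
  }
  stats <- lcb_fold_change(expression, g$target, g$background, level, eps)
  fdr_row <- permutation_fdr(expression, sheet, subgroup, lcb_threshold,
                             n_perm, seed, level, eps)
  stats |>
    dplyr::mutate(
      comparison = fdr_row$comparison,
      fdr = fdr_row$fdr,
      passes = .data$lcb > lcb_threshold & fdr_row$fdr < fdr_threshold
    ) |>
    dplyr::select("gene_id", "comparison", "fc", "lcb", "fdr", "passes")
}

#' Venn-region overlap of per-subgroup differential-expression lists
#'
#' Computes the exact count of every intersection region of the subgroup
#' lists, the transcript-level union, and the gene-level union after
#' mapping transcripts to genes.  Transcripts missing from `gene_map` are
#' counted as their own gene, with a warning.
#'
#' @param de_lists Named list (>= 2 entries) of character vectors of
#'   transcript ids, one per subgroup.
#' @param gene_map Optional named character vector, transcript -> gene.
#' @return An `overlap_summary` list with elements `regions` (tibble with
#'   `region`, logical membership columns, `count`), `union_transcripts`
#'   and `union_genes`.
#' @export
overlap_summary <- function(de_lists, gene_map = NULL) {
  if (length(de_lists) < 2L || is.null(names(de_lists))) {
    abort("de_lists must be a named list with at least two entries",
          class = "restrictr_usage_error")
  }
  groups <- names(de_lists)
  all_ids <- unique(unlist(de_lists, use.names = FALSE))
  membership <- vapply(de_lists, function(l) all_ids %in% l,
                       logical(length(all_ids)))
  membership <- matrix(membership, nrow = length(all_ids),
                       dimnames = list(all_ids, groups))

  # every non-empty membership signature is a Venn region
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(groups)))
  names(combos) <- groups
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  counts <- apply(combos, 1L, function(sig) {
    sum(apply(membership, 1L, function(row) all(row == sig)))
  })
  regions <- tibble::as_tibble(combos)
  regions$region <- apply(combos, 1L, function(sig) {
    paste(groups[as.logical(sig)], collapse = "&")
  })
  regions$count <- as.integer(counts)
  regions <- regions[c("region", groups, "count")]

  if (is.null(gene_map)) {
    genes <- all_ids
  } else {
    missing <- setdiff(all_ids, names(gene_map))
    if (length(missing) > 0) {
      warn(sprintf("%d transcript(s) missing from gene_map counted as their own gene",
                   length(missing)))
    }
    genes <- ifelse(all_ids %in% names(gene_map), gene_map[all_ids], all_ids)
  }
  structure(
    list(regions = regions,
         union_transcripts = length(all_ids),
         union_genes = length(unique(genes))),
    class = "overlap_summary"
  )
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("Overlap of", sum(grepl("&", x$regions$region, fixed = TRUE) == FALSE),
      "differential-expression lists\n")
  cat("Union:", x$union_transcripts, "transcripts /", x$union_genes, "genes\n")
  print(x$regions[c("region", "count")])
  invisible(x)
}
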