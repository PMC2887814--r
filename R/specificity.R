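#' Present/absent calls over a reference compendium
#'
#' For each gene the target-lineage reference level `L` is aggregated over
#' the target reference cells (mean by default, max available as an
#' option).  A non-target reference cell is called **present** when its
#' expression is strictly greater than `0.5 * L`, otherwise **absent**.
#' When `L = 0` every strictly positive value is present.
#'
#' @param reference Expression tibble of the reference compendium.
#' @param reference_sheet Sample sheet for the compendium (>= 1 target and
#'   >= 1 background cell).
#' @param level_stat How to aggregate the target cells into `L`.
#' @return Long tibble with columns `gene_id`, `sample_id`, `call`
#'   (`"present"`/`"absent"`), one row per gene and non-target cell.
#' @export
present_absent_calls <- function(reference, reference_sheet,
                                 level_stat = c("mean", "max")) {
  level_stat <- match.arg(level_stat)
  sheet <- validate_sample_sheet(reference_sheet, reference)
  target <- sheet$sample_id[sheet$lineage == "target"]
  non_target <- sheet$sample_id[sheet$lineage == "background"]
  if (length(target) == 0L) {
    abort("reference sheet has no target cell", class = "restrictr_usage_error")
  }
  m <- expr_matrix(reference)
  L <- if (level_stat == "mean") rowMeans(m[, target, drop = FALSE])
       else apply(m[, target, drop = FALSE], 1L, max)
  calls <- m[, non_target, drop = FALSE] > 0.5 * L
  tibble::tibble(
    gene_id = rep(reference$gene_id, times = length(non_target)),
    sample_id = rep(non_target, each = nrow(reference)),
    call = ifelse(as.vector(calls), "present", "absent")
  )
}

#' Enrichment score from present/absent calls
#'
#' The score of a gene is the fraction of non-target reference cells in
#' which it is called absent: `ecs = sum(A_i) / n` with `A_i + P_i = 1`.
#' A score of 1 means the gene is absent from every cell outside the
#' target lineage.
#'
#' @param calls Either the long tibble from [present_absent_calls()] or a
#'   character vector of `"present"`/`"absent"` calls for one gene.
#' @return For a tibble input, a tibble with `gene_id`, `ecs`; for a
#'   vector input, a single numeric score.
#' @export
enrichment_score <- function(calls) {
  if (is.character(calls)) {
    if (length(calls) == 0L) {
      abort("empty call vector", class = "restrictr_usage_error")
    }
    check_calls(calls)
    return(mean(calls == "absent"))
  }
  if (!is.data.frame(calls) || nrow(calls) == 0L) {
    abort("empty call table", class = "restrictr_usage_error")
  }
  check_calls(calls$call)
  calls |>
    dplyr::summarise(ecs = mean(.data$call == "absent"), .by = "gene_id")
}

check_calls <- function(x) {
  if (!all(x %in% c("present", "absent"))) {
    abort("calls must be 'present' or 'absent'", class = "restrictr_usage_error")
  }
}

#' Outlier analysis of per-gene expression across a sample panel
#'
#' For each gene the mean and sample (n-1) standard deviation are taken
#' over *all* samples; sample `k` is an outlier when
#' `|x_k - mean| > sd_mult * sd`.  The outlier set is classified as
#' `target_only` when it is non-empty, every outlier is a target-lineage
#' sample, and every outlier lies above the mean (restricted genes are
#' overexpressed in their lineage); any other non-empty outlier set —
#' including one containing a background sample or a below-mean target
#' sample — is `mixed`; an empty set (including the zero-variance case)
#' is `none`.
#'
#' @param expression Expression tibble.
#' @param sheet Sample sheet matching `expression` (>= 3 samples).
#' @param sd_mult Outlier cut-off in standard deviations.
#' @return Tibble with columns `gene_id`, `outlier_samples` (list-column of
#'   sample ids), `outlier_class` (`"target_only"`, `"mixed"`, `"none"`).
#' @export
outlier_analysis <- function(expression, sheet, sd_mult = 2) {
  sheet <- validate_sample_sheet(sheet, expression)
  m <- expr_matrix(expression)
  if (ncol(m) < 3L) {
    abort("outlier analysis needs at least 3 samples",
          class = "restrictr_usage_error")
  }
  is_target <- setNames(sheet$lineage == "target", sheet$sample_id)[colnames(m)]
  mu <- rowMeans(m)
  s <- sqrt(row_var(m, mu))
  out <- purrr::map(seq_len(nrow(m)), function(i) {
    if (s[i] == 0) return(character())
    colnames(m)[abs(m[i, ] - mu[i]) > sd_mult * s[i]]
  })
  cls <- purrr::map2_chr(out, seq_along(out), function(o, i) {
    if (length(o) == 0L) return("none")
    if (all(is_target[o]) && all(m[i, o] > mu[i])) "target_only" else "mixed"
  })
  tibble::tibble(gene_id = expression$gene_id,
                 outlier_samples = out,
                 outlier_class = cls)
}

#' Reference-compendium fold change (REF_FOLD)
#'
#' `ref_fold = mean(target reference cells) / max(mean(non-target cells), eps)`,
#' the compendium counterpart of the primary-set fold change.
#'
#' @inheritParams present_absent_calls
#' @param eps Denominator floor in signal units.
#' @return Tibble with columns `gene_id`, `ref_fold`.
#' @export
ref_fold <- function(reference, reference_sheet, eps = 1) {
  sheet <- validate_sample_sheet(reference_sheet, reference)
  out <- fold_change(reference,
                     sheet$sample_id[sheet$lineage == "target"],
                     sheet$sample_id[sheet$lineage == "background"],
                     eps = eps)
  dplyr::rename(out, ref_fold = "fc")
}

#' Composite rank score
#'
#' `rank = fc * ref_fold`: the product of the primary-experiment fold
#' change and the reference-compendium fold change.  Genes strongly
#' enriched in both datasets get the highest ranks.
#'
#' @param fc,ref_fold Positive numeric vectors (recycled as usual).
#' @return Numeric vector of rank scores.
#' @export
rank_score <- function(fc, ref_fold) {
  if (any(!is.finite(fc)) || any(!is.finite(ref_fold)) ||
      any(fc <= 0) || any(ref_fold <= 0)) {
    abort("fc and ref_fold must be positive and finite",
          class = "restrictr_usage_error")
  }
  fc * ref_fold
}

#' Build per-gene specificity records
#'
#' Combines the primary-set fold change (all target samples versus the
#' background pool), the present/absent enrichment score, the outlier
#' classification over the reference panel, the reference fold change and
#' the composite rank score into one table, for the genes of
#' `expression` (typically the union of the differential-expression
#' lists).
#'
#' @param expression Primary expression tibble (restricted to the genes of
#'   interest).
#' @param sheet Primary sample sheet.
#' @param reference,reference_sheet Reference compendium and its sheet.
#' @param eps Denominator floor for both fold changes.
#' @param level_stat Aggregator for the present/absent reference level.
#' @return Tibble with columns `gene_id`, `fc`, `ecs`, `outlier_class`,
#'   `outlier_samples`, `ref_fold`, `rank_score`.
#' @export
specificity_table <- function(expression, sheet, reference, reference_sheet,
                              eps = 1, level_stat = "mean") {
  if (nrow(expression) == 0L) {
    return(tibble::tibble(gene_id = character(), fc = numeric(),
                          ecs = numeric(), outlier_class = character(),
                          outlier_samples = list(), ref_fold = numeric(),
                          rank_score = numeric()))
  }
  sheet <- validate_sample_sheet(sheet, expression)
  keep <- reference$gene_id %in% expression$gene_id
  reference <- reference[keep, , drop = FALSE]
  missing <- setdiff(expression$gene_id, reference$gene_id)
  if (length(missing) > 0) {
    abort("reference compendium is missing genes from the primary set",
          class = "restrictr_consistency_error")
  }
  fc_tbl <- fold_change(expression,
                        sheet$sample_id[sheet$lineage == "target"],
                        sheet$sample_id[sheet$lineage == "background"],
                        eps = eps)
  ecs_tbl <- enrichment_score(
    present_absent_calls(reference, reference_sheet, level_stat))
  out_tbl <- outlier_analysis(reference, reference_sheet)
  rf_tbl <- ref_fold(reference, reference_sheet, eps = eps)
  fc_tbl |>
    dplyr::left_join(ecs_tbl, by = "gene_id") |>
    dplyr::left_join(out_tbl, by = "gene_id") |>
    dplyr::left_join(rf_tbl, by = "gene_id") |>
    dplyr::mutate(rank_score = rank_score(.data$fc, .data$ref_fold)) |>
    dplyr::select("gene_id", "fc", "ecs", "outlier_class", "outlier_samples",
                  "ref_fold", "rank_score")
}

#' Select the final restricted-gene table
#'
#' The candidate pool contains the records with `ecs == 1`, a
#' `target_only` outlier class, and `ref_fold >= min_ref_fold`.  The
#' `ceiling(top_fraction * pool size)` highest rank scores are kept (ties
#' broken by `gene_id`, ascending, for stability).  Deny-list removals and
#' allow-list retentions — the hooks for a manual curation step — are
#' applied last: denied genes are dropped from the kept set, allowed genes
#' that made the pool but fell below the top-fraction cut are retained.
#'
#' @param records Tibble from [specificity_table()].
#' @param top_fraction Fraction of the pool to keep, in `(0, 1]`.
#' @param min_ref_fold Minimum reference fold change (inclusive).
#' @param allowlist,denylist Optional character vectors of gene ids.
#' @return Tibble sorted by `rank_score` descending with columns
#'   `gene_id`, `fc`, `ref_fold`, `rank_score`, `ecs`, `outlier_class`,
#'   `selected` (all `TRUE`; kept for column-contract stability).
#' @export
select_restricted <- function(records, top_fraction = 0.60, min_ref_fold = 3,
                              allowlist = NULL, denylist = NULL) {
  if (top_fraction <= 0 || top_fraction > 1) {
    abort("top_fraction must be in (0, 1]", class = "restrictr_usage_error")
  }
  pool <- records |>
    dplyr::filter(.data$ecs == 1,
                  .data$outlier_class == "target_only",
                  .data$ref_fold >= min_ref_fold) |>
    dplyr::arrange(dplyr::desc(.data$rank_score), .data$gene_id)
  if (nrow(pool) == 0L) {
    warn("empty candidate pool; no restricted genes selected")
    return(dplyr::mutate(pool[0, ], selected = logical())[
      c("gene_id", "fc", "ref_fold", "rank_score", "ecs", "outlier_class",
        "selected")])
  }
  n_keep <- ceiling(top_fraction * nrow(pool))
  kept <- pool$gene_id[seq_len(n_keep)]
  if (!is.null(allowlist)) kept <- union(kept, intersect(pool$gene_id, allowlist))
  if (!is.null(denylist)) kept <- setdiff(kept, denylist)
  pool |>
    dplyr::filter(.data$gene_id %in% kept) |>
    dplyr::mutate(selected = TRUE) |>
    dplyr::select("gene_id", "fc", "ref_fold", "rank_score", "ecs",
                  "outlier_class", "selected")
}
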