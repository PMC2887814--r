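#' Run the full restricted-gene identification pipeline
#'
#' Executes the stages in order: per-subgroup differential expression
#' against the pooled background (LCB > `lcb_threshold`, permutation FDR <
#' `fdr_threshold`), union of the passing transcripts, specificity scoring
#' over the reference compendium (enrichment score, outlier class,
#' reference fold change, rank score), the top-fraction selection rule,
#' and expression-pattern clustering of the selected genes.  The run is
#' deterministic given `seed`.
#'
#' @param primary,primary_sheet Primary expression panel and sample sheet.
#' @param reference,reference_sheet Reference compendium and sample sheet.
#' @param lcb_threshold,fdr_threshold Differential-expression gates.
#' @param min_ref_fold,top_fraction Selection-rule parameters.
#' @param k Number of pattern clusters (patterns stage skipped when fewer
#'   selected genes than `k`).
#' @param n_perm Permutations for the FDR estimate.
#' @param eps Denominator floor for fold changes.
#' @param seed Master seed for permutations and clustering.
#' @param allowlist,denylist Curation hooks passed to [select_restricted()].
#' @return A `restriction_result` list with elements `table` (the ranked
#'   restricted-gene tibble), `records` (all specificity records),
#'   `de` (per-subgroup call tibble), `overlap` (an `overlap_summary`),
#'   `patterns` (pattern assignments or `NULL`), and `manifest` (stage
#'   counts and parameters).
#' @export
run_restriction_pipeline <- function(primary, primary_sheet,
                                     reference, reference_sheet,
                                     lcb_threshold = 3, fdr_threshold = 0.02,
                                     min_ref_fold = 3, top_fraction = 0.60,
                                     k = 4L, n_perm = 100L, eps = 1,
                                     seed = 1L,
                                     allowlist = NULL, denylist = NULL) {
  primary <- validate_expression(primary)
  primary_sheet <- validate_sample_sheet(primary_sheet, primary)
  reference <- validate_expression(reference)
  reference_sheet <- validate_sample_sheet(reference_sheet, reference)

  subgroups <- unique(primary_sheet$subgroup[primary_sheet$lineage == "target"])
  subgroups <- subgroups[!is.na(subgroups)]
  if (length(subgroups) == 0L) subgroups <- list(NULL)

  de <- purrr::imap_dfr(subgroups, function(sg, i) {
    call_de(primary, primary_sheet, sg,
            lcb_threshold = lcb_threshold, fdr_threshold = fdr_threshold,
            eps = eps, n_perm = n_perm, seed = derive_seed(seed, 10L + i))
  })
  de_lists <- de |>
    dplyr::filter(.data$passes) |>
    (\(d) split(d$gene_id, d$comparison))()
  union_ids <- sort(unique(unlist(de_lists, use.names = FALSE)))
  overlap <- if (length(de_lists) >= 2L) overlap_summary(de_lists) else NULL

  if (length(union_ids) == 0L) {
    warn("no transcripts passed differential expression")
    records <- specificity_table(primary[0, ], primary_sheet,
                                 reference, reference_sheet, eps = eps)
  } else {
    records <- specificity_table(
      primary[primary$gene_id %in% union_ids, , drop = FALSE],
      primary_sheet, reference, reference_sheet, eps = eps)
  }

  pool_n <- sum(records$ecs == 1 & records$outlier_class == "target_only" &
                  records$ref_fold >= min_ref_fold)
  table <- if (nrow(records) == 0L) {
    select_restricted(records[0, ], top_fraction, min_ref_fold)
  } else {
    select_restricted(records, top_fraction, min_ref_fold, allowlist, denylist)
  }

  patterns <- NULL
  if (nrow(table) >= k) {
    patterns <- kmeans_patterns(
      primary[match(table$gene_id, primary$gene_id), , drop = FALSE],
      primary_sheet, k = k, seed = derive_seed(seed, 20L))
  }

  de_stage_names <- if (length(de_lists) > 0) {
    paste0("de_pass:", names(de_lists))
  } else {
    character()
  }
  manifest <- tibble::tibble(
    stage = c("input_genes", de_stage_names,
              "de_union", "candidate_pool", "selected"),
    count = c(nrow(primary),
              as.integer(lengths(de_lists)),
              length(union_ids), pool_n, nrow(table))
  )
  structure(
    list(table = table, records = records, de = de, overlap = overlap,
         patterns = patterns, manifest = manifest,
         params = list(lcb_threshold = lcb_threshold,
                       fdr_threshold = fdr_threshold,
                       min_ref_fold = min_ref_fold,
                       top_fraction = top_fraction, k = k,
                       n_perm = n_perm, eps = eps, seed = seed)),
    class = "restriction_result"
  )
}

#' @export
print.restriction_result <- function(x, ...) {
  cat("Lineage-restricted gene identification\n")
  cat(sprintf("  %d genes in -> %d DE union -> %d candidates -> %d selected\n",
              x$manifest$count[x$manifest$stage == "input_genes"],
              x$manifest$count[x$manifest$stage == "de_union"],
              x$manifest$count[x$manifest$stage == "candidate_pool"],
              x$manifest$count[x$manifest$stage == "selected"]))
  print(head(x$table, 10))
  invisible(x)
}

#' Tidy a restriction result
#'
#' Returns the ranked restricted-gene table, one row per selected gene.
#'
#' @param x A `restriction_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy restriction_result
#' @export
tidy.restriction_result <- function(x, ...) x$table

#' One-row summary of a restriction result
#'
#' @param x A `restriction_result`.
#' @param ... Unused.
#' @return A one-row tibble with the stage counts of the filter cascade
#'   and the headline parameters.
#' @method glance restriction_result
#' @export
glance.restriction_result <- function(x, ...) {
  counts <- setNames(as.list(x$manifest$count), x$manifest$stage)
  tibble::tibble(
    n_genes = counts$input_genes,
    n_de_union = counts$de_union,
    n_candidate_pool = counts$candidate_pool,
    n_selected = counts$selected,
    top_rank = if (nrow(x$table) > 0) max(x$table$rank_score) else NA_real_,
    lcb_threshold = x$params$lcb_threshold,
    top_fraction = x$params$top_fraction,
    seed = x$params$seed
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the top-ranked restricted genes
#'
#' Lollipop chart of the rank score (log scale) of the top `n` genes in
#' the final table.
#'
#' @param object A `restriction_result`.
#' @param n Number of genes to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot restriction_result
#' @export
autoplot.restriction_result <- function(object, n = 20, ...) {
  d <- head(object$table, n)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$rank_score,
    y = stats::reorder(.data$gene_id, .data$rank_score))) +
    ggplot2::geom_segment(ggplot2::aes(xend = 1, yend = .data$gene_id),
                          colour = "grey60") +
    ggplot2::geom_point(colour = "#B2182B", size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "rank score (FC × REF_FOLD)", y = NULL,
                  title = "Top lineage-restricted genes") +
    ggplot2::theme_minimal()
}

#' Fold change versus lower confidence bound for one comparison
#'
#' @param de Tibble from [call_de()].
#' @param lcb_threshold Threshold line to draw.
#' @return A ggplot object.
#' @export
plot_de <- function(de, lcb_threshold = 3) {
  ggplot2::ggplot(de, ggplot2::aes(.data$fc, .data$lcb, colour = .data$passes)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(yintercept = lcb_threshold, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "#B2182B")) +
    ggplot2::facet_wrap(ggplot2::vars(.data$comparison)) +
    ggplot2::labs(x = "fold change", y = "90% LCB of fold change") +
    ggplot2::theme_minimal()
}

#' Stacked tissue-percentage bars
#'
#' @param percent_table Tibble from [tissue_percentages()].
#' @return A ggplot object.
#' @export
plot_tissue_percentages <- function(percent_table) {
  long <- percent_table |>
    dplyr::select(-dplyr::any_of("all_zero")) |>
    tidyr::pivot_longer(-"gene_id", names_to = "tissue", values_to = "percent")
  ggplot2::ggplot(long, ggplot2::aes(.data$percent, .data$gene_id,
                                     fill = .data$tissue)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "% of summed expression", y = NULL, fill = "tissue") +
    ggplot2::theme_minimal()
}

#' Write pipeline report files
#'
#' Emits the ranked restricted-gene table, the differential-expression
#' calls, the overlap regions, the pattern assignments, the manifest, and
#' a short human-readable summary (counts plus the top-10 ranked genes),
#' all as TSV/text with fixed column order.
#'
#' @param result A `restriction_result`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  w <- function(tbl, name) {
    path <- file.path(dir, name)
    readr::write_tsv(tbl, path, progress = FALSE)
    files <<- c(files, path)
  }
  w(result$table, "restricted_table.tsv")
  w(result$de, "de_calls.tsv")
  if (!is.null(result$overlap)) {
    w(result$overlap$regions[c("region", "count")], "overlap.tsv")
  }
  if (!is.null(result$patterns)) w(result$patterns, "patterns.tsv")
  w(result$manifest, "manifest.tsv")

  summary_path <- file.path(dir, "summary.txt")
  lines <- c(
    sprintf("%s: %d", result$manifest$stage, result$manifest$count),
    "",
    if (nrow(result$table) == 0) "zero genes selected" else
      c("top ranked genes:",
        sprintf("  %s  rank=%.4f (fc=%.2f, ref_fold=%.2f)",
                head(result$table$gene_id, 10),
                head(result$table$rank_score, 10),
                head(result$table$fc, 10),
                head(result$table$ref_fold, 10)))
  )
  writeLines(lines, summary_path)
  invisible(c(files, summary_path))
}
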