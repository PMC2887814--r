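#' One-tailed Fisher exact over-representation test
#'
#' Tests whether a gene set is over-represented in a study list drawn from
#' a finite background: the p-value is the upper hypergeometric tail of
#' the 2x2 table (overlap and larger).  Set members outside the background
#' are ignored; the study list must be a subset of the background.
#'
#' @param study_genes Character vector of study gene ids.
#' @param set_genes Character vector of gene-set members.
#' @param background_genes Character vector, the gene universe.
#' @return One-row tibble with `overlap`, `study_size`, `set_size`,
#'   `background_size`, `p_value`.
#' @export
fisher_overrepresentation <- function(study_genes, set_genes, background_genes) {
  background_genes <- unique(background_genes)
  if (length(background_genes) == 0L) {
    abort("empty background", class = "restrictr_usage_error")
  }
  study_genes <- unique(study_genes)
  if (!all(study_genes %in% background_genes)) {
    abort("study genes must be a subset of the background",
          class = "restrictr_usage_error")
  }
  set_genes <- intersect(unique(set_genes), background_genes)
  overlap <- length(intersect(study_genes, set_genes))
  tibble::tibble(
    overlap = overlap,
    study_size = length(study_genes),
    set_size = length(set_genes),
    background_size = length(background_genes),
    p_value = hyper_tail_p(overlap, length(set_genes),
                           length(background_genes), length(study_genes))
  )
}

# P(X >= a) for X ~ Hypergeometric(N, K, n)
hyper_tail_p <- function(a, K, N, n) {
  phyper(a - 1, K, N - K, n, lower.tail = FALSE)
}

#' Conservative EASE variant of the over-representation p-value
#'
#' Recomputes the Fisher over-representation p-value after removing one
#' study gene from the overlap (`overlap - 1`, `study_size - 1`), which
#' penalizes categories supported by few genes; a singleton overlap
#' collapses to `p = 1`.  Always at least as large as the Fisher p-value.
#'
#' @inheritParams fisher_overrepresentation
#' @return The EASE p-value (scalar).
#' @export
ease_score <- function(study_genes, set_genes, background_genes) {
  res <- fisher_overrepresentation(study_genes, set_genes, background_genes)
  if (res$overlap == 0L) return(1)
  hyper_tail_p(res$overlap - 1L, res$set_size, res$background_size,
               res$study_size - 1L)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; a thin validating wrapper
#' around [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]", class = "restrictr_usage_error")
  }
  p.adjust(p, method = "BH")
}

#' Gene-set over-representation across a GMT collection
#'
#' Runs [fisher_overrepresentation()] and [ease_score()] for every set in
#' the collection and adjusts the Fisher p-values across sets with
#' Benjamini-Hochberg.
#'
#' @param study_genes Character vector of study gene ids.
#' @param collection Tibble from [read_gmt()].
#' @param background_genes Character vector, the gene universe.
#' @return Tibble with one row per set: `set_id`, `overlap`, `study_size`,
#'   `set_size`, `background_size`, `p_value`, `ease_p`,
#'   `neg_log10_ease`, `adjusted_p`.
#' @export
gene_set_enrichment <- function(study_genes, collection, background_genes) {
  rows <- purrr::map2_dfr(collection$set_id, collection$genes, function(id, genes) {
    res <- fisher_overrepresentation(study_genes, genes, background_genes)
    res$set_id <- id
    res$ease_p <- ease_score(study_genes, genes, background_genes)
    res
  })
  rows |>
    dplyr::mutate(neg_log10_ease = -log10(.data$ease_p),
                  adjusted_p = bh_fdr(.data$p_value)) |>
    dplyr::select("set_id", "overlap", "study_size", "set_size",
                  "background_size", "p_value", "ease_p", "neg_log10_ease",
                  "adjusted_p") |>
    dplyr::arrange(.data$p_value, .data$set_id)
}

#' Yes/no promoter-site enrichment gate
#'
#' Compares the density of predicted binding-site hits between a "yes"
#' promoter set (e.g. promoters of restricted genes) and a "no" background
#' promoter set.  `ratio = (yes_hits/yes_promoters) / (no_hits/no_promoters)`;
#' the p-value is the one-tailed Fisher exact test on the 2x2 table of
#' hit versus non-hit promoters.  The gate passes when `p < p_threshold`
#' **and** `ratio > ratio_threshold`.  When the "no" density is zero the
#' ratio is infinite and the gate is decided by the p-value alone, with a
#' warning.
#'
#' @param yes_hits,no_hits Number of promoters with a site in each set.
#' @param yes_promoters,no_promoters Promoter counts (> 0) of each set.
#' @param p_threshold,ratio_threshold The gate thresholds.
#' @return One-row tibble with `yes_hits`, `yes_promoters`, `no_hits`,
#'   `no_promoters`, `ratio`, `p_value`, `passes_gate`.
#' @export
site_enrichment_gate <- function(yes_hits, yes_promoters, no_hits, no_promoters,
                                 p_threshold = 0.01, ratio_threshold = 1.2) {
  counts <- c(yes_hits, yes_promoters, no_hits, no_promoters)
  if (any(counts < 0) || yes_promoters == 0 || no_promoters == 0 ||
      yes_hits > yes_promoters || no_hits > no_promoters) {
    abort("invalid hit/promoter counts", class = "restrictr_usage_error")
  }
  density_yes <- yes_hits / yes_promoters
  density_no <- no_hits / no_promoters
  p <- fisher.test(matrix(c(yes_hits, yes_promoters - yes_hits,
                            no_hits, no_promoters - no_hits), 2L),
                   alternative = "greater")$p.value
  if (density_no == 0) {
    warn("zero hit density in the 'no' set; gate decided by p-value only")
    ratio <- Inf
    passes <- p < p_threshold
  } else {
    ratio <- density_yes / density_no
    passes <- p < p_threshold && ratio > ratio_threshold
  }
  tibble::tibble(yes_hits = yes_hits, yes_promoters = yes_promoters,
                 no_hits = no_hits, no_promoters = no_promoters,
                 ratio = ratio, p_value = p, passes_gate = passes)
}

#' Site enrichment over a table of hit counts
#'
#' Applies [site_enrichment_gate()] row-wise to a table with columns
#' `set_id`, `yes_hits`, `yes_n`, `no_hits`, `no_n` (e.g. one row per
#' transcription-factor matrix) and BH-adjusts the p-values.
#'
#' @param hit_table Tibble with the five columns above.
#' @inheritParams site_enrichment_gate
#' @return Tibble with one row per set, gate columns plus `adjusted_p`.
#' @export
site_enrichment <- function(hit_table, p_threshold = 0.01, ratio_threshold = 1.2) {
  rows <- purrr::pmap_dfr(hit_table, function(set_id, yes_hits, yes_n, no_hits, no_n, ...) {
    res <- site_enrichment_gate(yes_hits, yes_n, no_hits, no_n,
                                p_threshold, ratio_threshold)
    res$set_id <- set_id
    res
  })
  rows |>
    dplyr::mutate(adjusted_p = bh_fdr(.data$p_value)) |>
    dplyr::select("set_id", dplyr::everything()) |>
    dplyr::arrange(.data$p_value, .data$set_id)
}

#' Count microRNA seed matches in 3'UTR sequences
#'
#' A target site is the exact reverse complement of the miRNA seed
#' (positions `seed_span[1]`..`seed_span[2]` of the mature miRNA given
#' 5'->3'; default 2-8, the canonical 7-mer seed).  Occurrences in each
#' UTR are counted non-overlapping, greedily left to right (set
#' `allow_overlap = TRUE` to count every offset).  Sequences are
#' normalized to upper-case DNA, so matching is case- and U/T-insensitive.
#'
#' @param utrs Tibble with columns `id`, `sequence` (the UTRs; gene ids).
#' @param mirnas Tibble with columns `id`, `sequence` (mature miRNAs).
#' @param seed_span Integer pair, 1-based inclusive positions of the seed.
#' @param allow_overlap Count overlapping occurrences too?
#' @return Tibble with one row per (miRNA, UTR) pair that has at least one
#'   site: `mirna_id`, `gene_id`, `n_sites`, `site_positions` (list-column
#'   of 0-based start offsets).
#' @export
mirna_seed_match <- function(utrs, mirnas, seed_span = c(2L, 8L),
                             allow_overlap = FALSE) {
  if (seed_span[1] < 1L || seed_span[2] < seed_span[1]) {
    abort("invalid seed span", class = "restrictr_usage_error")
  }
  utr_seq <- normalize_sequence(utrs$sequence)
  mir_seq <- normalize_sequence(mirnas$sequence)
  if (any(nchar(mir_seq) < seed_span[2])) {
    abort("miRNA shorter than the seed span", class = "restrictr_usage_error")
  }
  sites <- vapply(mir_seq, function(s) {
    seed <- substr(s, seed_span[1], seed_span[2])
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seed)))
  }, character(1), USE.NAMES = FALSE)

  purrr::map2_dfr(mirnas$id, sites, function(mid, site) {
    hits <- purrr::map2_dfr(utrs$id, utr_seq, function(gid, utr) {
      pos <- find_sites(utr, site, allow_overlap)
      if (length(pos) == 0L) return(NULL)
      tibble::tibble(gene_id = gid, n_sites = length(pos),
                     site_positions = list(pos))
    })
    if (nrow(hits) == 0L) return(NULL)
    hits$mirna_id <- mid
    hits[c("mirna_id", "gene_id", "n_sites", "site_positions")]
  })
}

# 0-based start offsets of `site` in `seq`
find_sites <- function(seq, site, allow_overlap = FALSE) {
  if (nchar(seq) < nchar(site)) return(integer())
  if (allow_overlap) {
    starts <- seq_len(nchar(seq) - nchar(site) + 1L)
    hits <- starts[substring(seq, starts, starts + nchar(site) - 1L) == site]
    return(hits - 1L)
  }
  # gregexpr with fixed patterns is the non-overlapping greedy scan
  pos <- gregexpr(site, seq, fixed = TRUE)[[1]]
  if (pos[1] == -1L) return(integer())
  as.integer(pos) - 1L
}

#' Per-miRNA seed-match enrichment
#'
#' For each miRNA, compares the number of genes carrying at least one
#' seed site in the study set against the background set with a
#' one-tailed Fisher exact test (study genes are a subset of the
#' background universe), and BH-adjusts across miRNAs.
#'
#' @param study_hits Tibble with columns `mirna_id`, `n_genes_hit` for the
#'   study set (as produced by counting distinct `gene_id` per miRNA from
#'   [mirna_seed_match()]).
#' @param background_hits Same shape, for the background set (counts must
#'   include the study genes).
#' @param study_size,background_size Total gene counts of the two sets.
#' @return Tibble with `mirna_id`, `study_genes_hit`,
#'   `background_genes_hit`, `p_value`, `adjusted_p`.
#' @export
mirna_enrichment <- function(study_hits, background_hits,
                             study_size, background_size) {
  if (background_size < study_size) {
    abort("background_size must be at least study_size",
          class = "restrictr_usage_error")
  }
  all_mirnas <- union(study_hits$mirna_id, background_hits$mirna_id)
  s <- setNames(rep(0L, length(all_mirnas)), all_mirnas)
  s[study_hits$mirna_id] <- study_hits$n_genes_hit
  b <- setNames(rep(0L, length(all_mirnas)), all_mirnas)
  b[background_hits$mirna_id] <- background_hits$n_genes_hit
  if (any(s > b) || any(b > background_size) || any(s > study_size)) {
    abort("inconsistent hit counts (study must be contained in background)",
          class = "restrictr_usage_error")
  }
  tibble::tibble(
    mirna_id = all_mirnas,
    study_genes_hit = unname(s),
    background_genes_hit = unname(b),
    p_value = hyper_tail_p(unname(s), unname(b), background_size, study_size)
  ) |>
    dplyr::mutate(adjusted_p = bh_fdr(.data$p_value)) |>
    dplyr::arrange(.data$p_value, .data$mirna_id)
}

#' End-to-end miRNA seed-site enrichment from sequences
#'
#' Counts seed sites in the study and background UTR sets and runs
#' [mirna_enrichment()].  Both the number of genes with at least one site
#' and the total number of sites are reported (external tools disagree on
#' which of the two they print).
#'
#' @param study_utrs,background_utrs UTR tibbles (`id`, `sequence`); the
#'   background must contain every study UTR id.
#' @param mirnas miRNA tibble (`id`, `sequence`).
#' @inheritParams mirna_seed_match
#' @return Tibble with `mirna_id`, `study_genes_hit`, `study_sites_total`,
#'   `background_genes_hit`, `p_value`, `adjusted_p`.
#' @export
mirna_site_enrichment <- function(study_utrs, background_utrs, mirnas,
                                  seed_span = c(2L, 8L), allow_overlap = FALSE) {
  if (!all(study_utrs$id %in% background_utrs$id)) {
    abort("study UTRs must be contained in the background set",
          class = "restrictr_usage_error")
  }
  study_m <- mirna_seed_match(study_utrs, mirnas, seed_span, allow_overlap)
  bg_m <- mirna_seed_match(background_utrs, mirnas, seed_span, allow_overlap)
  count_hits <- function(mm) {
    if (nrow(mm) == 0L) {
      return(tibble::tibble(mirna_id = character(), n_genes_hit = integer(),
                            n_sites_total = integer()))
    }
    mm |>
      dplyr::summarise(n_genes_hit = dplyr::n_distinct(.data$gene_id),
                       n_sites_total = sum(.data$n_sites),
                       .by = "mirna_id")
  }
  sh <- count_hits(study_m)
  bh <- count_hits(bg_m)
  res <- mirna_enrichment(sh[c("mirna_id", "n_genes_hit")],
                          bh[c("mirna_id", "n_genes_hit")],
                          nrow(study_utrs), nrow(background_utrs))
  res |>
    dplyr::left_join(sh[c("mirna_id", "n_sites_total")], by = "mirna_id") |>
    dplyr::mutate(study_sites_total = dplyr::coalesce(.data$n_sites_total, 0L)) |>
    dplyr::select("mirna_id", "study_genes_hit", "study_sites_total",
                  "background_genes_hit", "p_value", "adjusted_p")
}
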