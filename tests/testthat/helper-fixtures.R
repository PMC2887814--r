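# Small in-code fixtures and independent oracles used across test files.

# expression tibble from a named list of per-sample value vectors
make_expr <- function(values, gene_ids = NULL) {
  n <- length(values[[1]])
  if (is.null(gene_ids)) gene_ids <- sprintf("g%02d", seq_len(n))
  tibble::tibble(gene_id = gene_ids, !!!values)
}

make_sheet <- function(sample_ids, lineage, cell_type = sample_ids,
                       subgroup = NA_character_, replicate = 1L) {
  tibble::tibble(sample_id = sample_ids, cell_type = cell_type,
                 lineage = lineage, subgroup = subgroup,
                 replicate = as.integer(replicate))
}

# 2 target + 2 background samples, constant-by-group values
two_group_expr <- function(target_vals, background_vals, gene_ids = NULL) {
  make_expr(list(t1 = target_vals[, 1], t2 = target_vals[, 2],
                 b1 = background_vals[, 1], b2 = background_vals[, 2]),
            gene_ids = gene_ids)
}

# hypergeometric upper tail P(X >= a) by direct summation of choose() terms;
# independent of stats::phyper / the package implementation
oracle_hyper_tail <- function(a, K, N, n) {
  lo <- max(a, 0, n - (N - K))
  hi <- min(K, n)
  if (lo > hi) return(0)
  ks <- lo:hi
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# brute-force Venn region counts by explicit intersection/setdiff
oracle_venn <- function(lists) {
  groups <- names(lists)
  ids <- unique(unlist(lists))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(groups)))
  names(combos) <- groups
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  counts <- apply(combos, 1L, function(sig) {
    inside <- ids
    for (g in groups[as.logical(sig)]) inside <- intersect(inside, lists[[g]])
    for (g in groups[!as.logical(sig)]) inside <- setdiff(inside, lists[[g]])
    length(inside)
  })
  region <- apply(combos, 1L, function(sig) {
    paste(groups[as.logical(sig)], collapse = "&")
  })
  setNames(as.integer(counts), region)
}

# exhaustive offset scan followed by greedy left-to-right selection
oracle_greedy_sites <- function(seq, site) {
  L <- nchar(site)
  if (nchar(seq) < L) return(integer())
  starts <- seq_len(nchar(seq) - L + 1L)
  all_hits <- starts[substring(seq, starts, starts + L - 1L) == site]
  kept <- integer()
  last_end <- 0L
  for (s in all_hits) {
    if (s > last_end) {
      kept <- c(kept, s)
      last_end <- s + L - 1L
    }
  }
  kept - 1L
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

small_sim_config <- function(...) {
  args <- utils::modifyList(list(n_genes = 200L, n_restricted = 10L),
                            list(...))
  do.call(sim_config, args)
}
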