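#' Expression-pattern clustering of restricted genes
#'
#' Each gene is summarized by its mean expression per cell type, z-scored
#' across cell types, and the profiles are clustered with k-means
#' (k-means++-style seeded initialization, Lloyd iterations, deterministic
#' farthest-point repair of empty clusters).  A cluster is labelled
#' `pan` when its centroid is high (z > 0) in every target cell type,
#' `subgroup_only:<label>` when it is high in the cell types of exactly
#' one target subgroup, and `other` otherwise.
#'
#' @param expression Expression tibble restricted to the genes to cluster.
#' @param sheet Sample sheet matching `expression`.
#' @param k Number of clusters (default 4; downstream promoter analysis
#'   only consumes the pan versus subgroup-only split).
#' @param seed Seed for the initialization.
#' @param max_iter Maximum Lloyd iterations.
#' @return Tibble with columns `gene_id`, `cluster_id` (1..k),
#'   `pattern_label`.  The within-cluster sum-of-squares trace is attached
#'   as attribute `wcss_trace`, the centroid matrix as `centers`.
#' @export
kmeans_patterns <- function(expression, sheet, k = 4L, seed = 1L,
                            max_iter = 100L) {
  sheet <- validate_sample_sheet(sheet, expression)
  if (nrow(expression) < k) {
    abort("fewer genes than clusters", class = "restrictr_usage_error")
  }
  m <- expr_matrix(expression)
  type_of <- setNames(sheet$cell_type, sheet$sample_id)[colnames(m)]
  types <- unique(sheet$cell_type)
  prof <- vapply(types, function(ct) {
    rowMeans(m[, type_of == ct, drop = FALSE])
  }, numeric(nrow(m)))
  prof <- matrix(prof, nrow = nrow(m), dimnames = list(rownames(m), types))
  # z-score each gene's profile; constant profiles become all-zero
  mu <- rowMeans(prof)
  s <- apply(prof, 1L, sd)
  z <- (prof - mu) / ifelse(s > 0, s, 1)

  fit <- lloyd_kmeans(z, k, seed, max_iter)

  tgt_types <- unique(sheet$cell_type[sheet$lineage == "target"])
  sub_of <- sheet |>
    dplyr::filter(.data$lineage == "target") |>
    dplyr::distinct(.data$cell_type, .data$subgroup)
  labels <- apply(fit$centers, 1L, function(ctr) {
    high <- names(ctr)[ctr > 0]
    if (all(tgt_types %in% high)) return("pan")
    high_sub <- unique(sub_of$subgroup[sub_of$cell_type %in% high])
    low_sub <- unique(sub_of$subgroup[!sub_of$cell_type %in% high &
                                        sub_of$cell_type %in% tgt_types])
    if (length(high_sub) == 1L && !high_sub %in% low_sub) {
      return(paste0("subgroup_only:", high_sub))
    }
    "other"
  })

  out <- tibble::tibble(
    gene_id = expression$gene_id,
    cluster_id = fit$cluster,
    pattern_label = labels[fit$cluster]
  )
  attr(out, "wcss_trace") <- fit$wcss_trace
  attr(out, "centers") <- fit$centers
  out
}

# k-means++ seeding + Lloyd with farthest-point repair of empty clusters
lloyd_kmeans <- function(x, k, seed, max_iter) {
  set.seed(seed)
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x), dimnames = list(NULL, colnames(x)))
  centers[1, ] <- x[sample.int(n, 1L), ]
  for (j in seq_len(k - 1L)) {
    d2 <- apply(x, 1L, function(row) {
      min(rowSums((centers[seq_len(j), , drop = FALSE] -
                     matrix(row, j, ncol(x), byrow = TRUE))^2))
    })
    if (all(d2 == 0)) {
      # degenerate input: fewer distinct points than clusters
      centers[j + 1L, ] <- x[sample.int(n, 1L), ]
    } else {
      centers[j + 1L, ] <- x[sample.int(n, 1L, prob = d2 / sum(d2)), ]
    }
  }

  assign_clusters <- function(centers) {
    d <- vapply(seq_len(k), function(j) {
      rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
    }, numeric(n))
    list(cluster = max.col(-d, ties.method = "first"),
         mind = d[cbind(seq_len(n), max.col(-d, ties.method = "first"))])
  }

  wcss_trace <- numeric()
  cluster <- integer(n)
  for (it in seq_len(max_iter)) {
    a <- assign_clusters(centers)
    empty <- setdiff(seq_len(k), unique(a$cluster))
    for (j in empty) {
      centers[j, ] <- x[which.max(a$mind), ]
      a <- assign_clusters(centers)
    }
    wcss_trace <- c(wcss_trace, sum(a$mind))
    if (identical(a$cluster, cluster) && it > 1L) break
    cluster <- a$cluster
    for (j in seq_len(k)) {
      members <- cluster == j
      if (any(members)) centers[j, ] <- colMeans(x[members, , drop = FALSE])
    }
  }
  list(cluster = cluster, centers = centers, wcss_trace = wcss_trace)
}

#' Correlation-based hierarchical clustering of samples
#'
#' Distance between two samples is `1 - Pearson correlation` of their
#' expression columns; the tree is built with average linkage.  A
#' zero-variance sample has no defined correlation and is placed at
#' distance 1 from every other sample, with a warning.
#'
#' @param expression Expression tibble (>= 2 samples).
#' @return An object of class `hclust`.  Use [as_newick()] to export the
#'   topology.
#' @export
correlation_cluster <- function(expression) {
  m <- expr_matrix(expression)
  if (ncol(m) < 2L) {
    abort("correlation clustering needs at least 2 samples",
          class = "restrictr_usage_error")
  }
  sds <- apply(m, 2L, sd)
  cc <- suppressWarnings(cor(m))
  if (any(sds == 0)) {
    warn("zero-variance sample column(s); treated as distance 1 to all")
    cc[sds == 0, ] <- 0
    cc[, sds == 0] <- 0
    diag(cc) <- 1
  }
  hclust(as.dist(1 - cc), method = "average")
}

#' Export a sample-clustering tree as a Newick string
#'
#' @param tree An `hclust` object from [correlation_cluster()].
#' @param path Optional path; when given the Newick string is also written
#'   to the file.
#' @return The Newick string, invisibly when `path` is given.
#' @export
as_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(tree)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Relative tissue-percentage table
#'
#' Converts a genes-by-tissues expression table into row percentages:
#' `percent_ij = 100 * x_ij / sum_j x_ij`.  Rows with all-zero input are
#' returned as zeros and flagged.
#'
#' @param tissue_expression Tibble with `gene_id` plus non-negative numeric
#'   tissue columns.
#' @return Tibble with `gene_id`, the tissue columns as percentages, and a
#'   logical `all_zero` flag.
#' @export
tissue_percentages <- function(tissue_expression) {
  tissue_expression <- validate_expression(tissue_expression)
  m <- expr_matrix(tissue_expression)
  totals <- rowSums(m)
  zero <- totals == 0
  pct <- 100 * m / ifelse(zero, 1, totals)
  out <- tibble::as_tibble(as.data.frame(pct))
  dplyr::bind_cols(tibble::tibble(gene_id = tissue_expression$gene_id),
                   out,
                   tibble::tibble(all_zero = unname(zero)))
}
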