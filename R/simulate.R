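#' Simulation configuration for synthetic expression panels
#'
#' Describes the study design the generators emulate: a replicated primary
#' panel of target-lineage cell types (default five endothelial-like types,
#' two replicates each, split into microvascular / venous / arterial
#' subgroups) against pooled background cell types, plus a reference
#' compendium of primary cells in which restricted genes are elevated only
#' in the target cells.
#'
#' Expression is log-normal: gene baselines are drawn once per gene
#' (`baseline_log_mean`, `baseline_log_sd`, natural-log scale) and shared
#' across samples, restricted genes are multiplied by a planted fold in
#' target samples, and replicate noise is multiplicative log-normal with
#' standard deviation `noise_log_sd` (0.15 corresponds to roughly 15%
#' replicate CV, typical of replicated normalized array signals).
#'
#' @param n_genes Total number of genes.
#' @param n_restricted Number of planted lineage-restricted genes.
#' @param target_cell_types Data frame with columns `cell_type`, `subgroup`,
#'   `n_rep` describing the target panel.
#' @param background_cell_types Data frame with columns `cell_type`, `n_rep`.
#' @param n_reference_cells Number of cells in the reference compendium.
#' @param n_reference_target How many reference cells are target-lineage.
#' @param baseline_log_mean,baseline_log_sd Location and spread of per-gene
#'   baselines on the natural-log scale.
#' @param fold_range Planted folds are drawn log-uniformly from this range.
#' @param noise_log_sd Replicate noise (natural-log scale sd); may be 0.
#' @param pattern_mix Fraction of planted genes restricted to a single
#'   subgroup only (the remainder are elevated in all target cell types).
#' @param subgroup_only_label Which subgroup carries the subgroup-only genes.
#' @param seed Master seed; each generator derives its own stream from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 1000L,
                       n_restricted = 50L,
                       target_cell_types = default_target_panel(),
                       background_cell_types = default_background_panel(),
                       n_reference_cells = 30L,
                       n_reference_target = 1L,
                       baseline_log_mean = log(100),
                       baseline_log_sd = 1,
                       fold_range = c(3, 200),
                       noise_log_sd = 0.15,
                       pattern_mix = 0.2,
                       subgroup_only_label = "microvascular",
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_restricted = as.integer(n_restricted),
    target_cell_types = tibble::as_tibble(target_cell_types),
    background_cell_types = tibble::as_tibble(background_cell_types),
    n_reference_cells = as.integer(n_reference_cells),
    n_reference_target = as.integer(n_reference_target),
    baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd,
    fold_range = fold_range,
    noise_log_sd = noise_log_sd,
    pattern_mix = pattern_mix,
    subgroup_only_label = subgroup_only_label,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_target_panel <- function() {
  tibble::tibble(
    cell_type = c("HMVEC", "HUVEC", "HPAEC", "HAEC", "HCAEC"),
    subgroup = c("microvascular", "venous", "venous", "arterial", "arterial"),
    n_rep = 2L
  )
}

#' @rdname sim_config
#' @export
default_background_panel <- function() {
  tibble::tibble(
    cell_type = c("HASMC", "TCELL", "BCELL"),
    n_rep = 2L
  )
}

validate_sim_config <- function(cfg) {
  ok <- cfg$n_genes >= 1L &&
    cfg$n_restricted >= 0L &&
    cfg$n_restricted <= cfg$n_genes &&
    cfg$baseline_log_sd > 0 &&
    cfg$noise_log_sd >= 0 &&
    length(cfg$fold_range) == 2L &&
    all(cfg$fold_range > 1) &&
    cfg$fold_range[2] >= cfg$fold_range[1] &&
    cfg$pattern_mix >= 0 && cfg$pattern_mix <= 1 &&
    cfg$n_reference_cells >= 2L &&
    cfg$n_reference_target >= 1L &&
    cfg$n_reference_target < cfg$n_reference_cells
  if (!ok) abort("invalid simulation configuration", class = "restrictr_config_error")
  if (!all(c("cell_type", "subgroup", "n_rep") %in% names(cfg$target_cell_types)) ||
      !all(c("cell_type", "n_rep") %in% names(cfg$background_cell_types))) {
    abort("invalid simulation cell-type panels", class = "restrictr_config_error")
  }
  invisible(cfg)
}

# per-generator streams split off the master seed (kept below 2^31)
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7L + offset) %% 2147483629)
}

gene_ids_for <- function(n) sprintf("G%05d", seq_len(n))

# truth and baselines are drawn from the master stream so that the primary
# and reference generators agree on which genes are planted
draw_truth <- function(config) {
  set.seed(derive_seed(config$seed, 0L))
  ids <- gene_ids_for(config$n_genes)
  restricted <- sort(sample.int(config$n_genes, config$n_restricted))
  n_sub <- round(config$pattern_mix * config$n_restricted)
  sub_only <- if (n_sub > 0) sort(sample(restricted, n_sub)) else integer()
  folds <- exp(runif(config$n_restricted,
                     log(config$fold_range[1]), log(config$fold_range[2])))
  truth <- tibble::tibble(
    gene_id = ids,
    is_restricted = FALSE,
    programmed_fold = 1,
    pattern = NA_character_,
    subgroup = NA_character_
  )
  truth$is_restricted[restricted] <- TRUE
  truth$programmed_fold[restricted] <- folds
  truth$pattern[restricted] <- "pan"
  truth$pattern[sub_only] <- "subgroup_only"
  truth$subgroup[sub_only] <- config$subgroup_only_label
  truth
}

primary_sheet_for <- function(config) {
  tgt <- config$target_cell_types
  bg <- config$background_cell_types
  rows <- dplyr::bind_rows(
    tidyr::uncount(
      tibble::tibble(cell_type = tgt$cell_type, subgroup = tgt$subgroup,
                     lineage = "target", n = tgt$n_rep),
      .data$n, .id = "replicate"),
    tidyr::uncount(
      tibble::tibble(cell_type = bg$cell_type, subgroup = NA_character_,
                     lineage = "background", n = bg$n_rep),
      .data$n, .id = "replicate")
  )
  rows$replicate <- as.integer(rows$replicate)
  rows$sample_id <- paste0(rows$cell_type, "_r", rows$replicate)
  rows[c("sample_id", "cell_type", "lineage", "subgroup", "replicate")]
}

lognormal_panel <- function(baselines, fold_matrix, noise_log_sd) {
  n <- length(baselines)
  m <- ncol(fold_matrix)
  noise <- matrix(exp(rnorm(n * m, 0, noise_log_sd)), n, m)
  baselines * fold_matrix * noise
}

#' Generate a synthetic primary expression panel with planted truth
#'
#' Background genes share one log-normal baseline across all samples;
#' planted restricted genes are multiplied by their programmed fold in all
#' target samples ("pan" pattern) or only in the samples of one subgroup
#' ("subgroup_only"); multiplicative replicate noise is applied on top.
#' Deterministic given the configuration seed.
#'
#' @param config A [sim_config()].
#' @return A list with elements `expression` (tibble, `gene_id` plus sample
#'   columns), `samples` (sample sheet tibble) and `truth` (tibble with
#'   `gene_id`, `is_restricted`, `programmed_fold`, `pattern`, `subgroup`).
#' @export
generate_primary_dataset <- function(config) {
  validate_sim_config(config)
  truth <- draw_truth(config)
  sheet <- primary_sheet_for(config)

  set.seed(derive_seed(config$seed, 1L))
  baselines <- rlnorm(config$n_genes, config$baseline_log_mean, config$baseline_log_sd)

  fold_m <- matrix(1, config$n_genes, nrow(sheet))
  is_target <- sheet$lineage == "target"
  pan <- which(truth$pattern %in% "pan")
  fold_m[pan, is_target] <- truth$programmed_fold[pan]
  sub <- which(truth$pattern %in% "subgroup_only")
  for (i in sub) {
    cols <- is_target & sheet$subgroup %in% truth$subgroup[i]
    fold_m[i, cols] <- truth$programmed_fold[i]
  }

  vals <- lognormal_panel(baselines, fold_m, config$noise_log_sd)
  expression <- tibble::as_tibble(
    cbind(tibble::tibble(gene_id = truth$gene_id),
          as.data.frame(`colnames<-`(vals, sheet$sample_id)))
  )
  list(expression = validate_expression(expression),
       samples = validate_sample_sheet(sheet, expression),
       truth = truth)
}

#' Generate a synthetic reference compendium matching planted truth
#'
#' Emulates a compendium of primary cells (default 30) in which planted
#' restricted genes are elevated only in the target-lineage reference
#' cells and background genes are expressed comparably everywhere.
#' Per-gene baselines are redrawn (the compendium plays the role of an
#' independently normalized external dataset) but the planted folds come
#' from `truth`.
#'
#' @param config A [sim_config()].
#' @param truth Truth tibble from [generate_primary_dataset()].
#' @return A list with elements `expression` and `samples`.
#' @export
generate_reference_compendium <- function(config, truth) {
  validate_sim_config(config)
  if (!identical(truth$gene_id, gene_ids_for(config$n_genes))) {
    abort("truth does not match configuration gene set",
          class = "restrictr_consistency_error")
  }
  n_ref <- config$n_reference_cells
  n_tgt <- config$n_reference_target
  sheet <- tibble::tibble(
    sample_id = c(sprintf("EC_REF_%d", seq_len(n_tgt)),
                  sprintf("REF_CELL_%02d", seq_len(n_ref - n_tgt))),
    cell_type = c(rep("EC", n_tgt), sprintf("REF_CELL_%02d", seq_len(n_ref - n_tgt))),
    lineage = c(rep("target", n_tgt), rep("background", n_ref - n_tgt)),
    subgroup = NA_character_,
    replicate = 1L
  )

  set.seed(derive_seed(config$seed, 2L))
  baselines <- rlnorm(config$n_genes, config$baseline_log_mean, config$baseline_log_sd)
  fold_m <- matrix(1, config$n_genes, n_ref)
  planted <- which(truth$is_restricted)
  fold_m[planted, seq_len(n_tgt)] <- truth$programmed_fold[planted]

  vals <- lognormal_panel(baselines, fold_m, config$noise_log_sd)
  expression <- tibble::as_tibble(
    cbind(tibble::tibble(gene_id = truth$gene_id),
          as.data.frame(`colnames<-`(vals, sheet$sample_id)))
  )
  list(expression = validate_expression(expression),
       samples = validate_sample_sheet(sheet, expression))
}

#' Generate a null dataset with no planted lineage effect
#'
#' Requires `n_restricted = 0`; target/background labels are exchangeable
#' by construction, which is what the permutation FDR assumes under the
#' null.
#'
#' @param config A [sim_config()] with `n_restricted = 0`.
#' @return A list with elements `expression` and `samples`.
#' @export
generate_null_dataset <- function(config) {
  validate_sim_config(config)
  if (config$n_restricted != 0L) {
    abort("null dataset requires n_restricted = 0", class = "restrictr_config_error")
  }
  out <- generate_primary_dataset(config)
  out[c("expression", "samples")]
}
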