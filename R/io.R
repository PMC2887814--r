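#' Read a genes-by-samples expression matrix from TSV
#'
#' The expected dialect is UTF-8, tab-separated, with a header row whose
#' first cell is literally `gene_id` followed by the sample ids, and one row
#' per gene.  Signals are normalized, complete and non-negative; missing
#' values are not permitted.
#'
#' @param path Path to a TSV file.
#' @return A tibble with a `gene_id` character column followed by one
#'   numeric column per sample.
#' @export
read_expression_tsv <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[1] != "gene_id") {
    abort("expression TSV must start with a 'gene_id' header column",
          class = "restrictr_format_error")
  }
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids)) {
    abort("duplicate sample ids in expression TSV header",
          class = "restrictr_format_error")
  }
  tbl <- readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_id = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  validate_expression(tbl)
}

#' Write an expression tibble to TSV
#'
#' @param expression Expression tibble as returned by [read_expression_tsv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expression, path) {
  validate_expression(expression)
  readr::write_tsv(expression, path, progress = FALSE)
  invisible(path)
}

#' Validate an expression tibble
#'
#' Checks the invariants every downstream stage assumes: a `gene_id` column
#' with no duplicates, unique sample columns, and finite non-negative
#' values with no missing entries.
#'
#' @param expression Tibble with `gene_id` plus numeric sample columns.
#' @return The validated tibble, invisibly usable in pipes.
#' @export
validate_expression <- function(expression) {
  if (!is.data.frame(expression) || !"gene_id" %in% names(expression)) {
    abort("expression must be a data frame with a 'gene_id' column",
          class = "restrictr_format_error")
  }
  if (anyDuplicated(expression$gene_id)) {
    abort("duplicate gene ids in expression matrix",
          class = "restrictr_format_error")
  }
  samples <- setdiff(names(expression), "gene_id")
  if (length(samples) == 0L) {
    abort("expression matrix has no sample columns",
          class = "restrictr_format_error")
  }
  if (anyDuplicated(samples)) {
    abort("duplicate sample ids in expression matrix",
          class = "restrictr_format_error")
  }
  vals <- as.matrix(expression[samples])
  if (!is.numeric(vals) || anyNA(vals) || any(!is.finite(vals))) {
    abort("expression values must be finite and complete",
          class = "restrictr_value_error")
  }
  if (any(vals < 0)) {
    abort("expression values must be non-negative",
          class = "restrictr_value_error")
  }
  tibble::as_tibble(expression)
}

# genes x samples numeric matrix with gene_id rownames
expr_matrix <- function(expression) {
  samples <- setdiff(names(expression), "gene_id")
  m <- as.matrix(expression[samples])
  rownames(m) <- expression$gene_id
  m
}

#' Read a sample sheet from TSV
#'
#' Columns: `sample_id`, `cell_type`, `lineage` (one of `target`,
#' `background`), `subgroup` (optional label, may be empty), `replicate`
#' (integer >= 1).
#'
#' @param path Path to a TSV file.
#' @return A tibble with the five columns above.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(
    path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      cell_type = readr::col_character(),
      lineage = readr::col_character(),
      subgroup = readr::col_character(),
      replicate = readr::col_integer()
    ),
    progress = FALSE
  )
  validate_sample_sheet(sheet)
}

#' Write a sample sheet to TSV
#'
#' @param sheet Sample-sheet tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  readr::write_tsv(sheet, path, progress = FALSE)
  invisible(path)
}

#' Validate a sample sheet, optionally against an expression matrix
#'
#' @param sheet Sample-sheet tibble.
#' @param expression Optional expression tibble; when given, the sheet must
#'   describe exactly the matrix's sample columns.
#' @return The validated tibble.
#' @export
validate_sample_sheet <- function(sheet, expression = NULL) {
  required <- c("sample_id", "cell_type", "lineage", "replicate")
  if (!is.data.frame(sheet) || !all(required %in% names(sheet))) {
    abort(paste("sample sheet needs columns:", paste(required, collapse = ", ")),
          class = "restrictr_format_error")
  }
  if (!"subgroup" %in% names(sheet)) sheet$subgroup <- NA_character_
  if (anyDuplicated(sheet$sample_id)) {
    abort("duplicate sample ids in sample sheet", class = "restrictr_format_error")
  }
  if (!all(sheet$lineage %in% c("target", "background"))) {
    abort("lineage must be 'target' or 'background'", class = "restrictr_format_error")
  }
  if (!any(sheet$lineage == "target") || !any(sheet$lineage == "background")) {
    abort("sample sheet needs at least one target and one background sample",
          class = "restrictr_format_error")
  }
  if (anyNA(sheet$replicate) || any(sheet$replicate < 1L)) {
    abort("replicate must be an integer >= 1", class = "restrictr_format_error")
  }
  if (!is.null(expression)) {
    samples <- setdiff(names(expression), "gene_id")
    if (!setequal(sheet$sample_id, samples) ||
        length(sheet$sample_id) != length(samples)) {
      abort("sample sheet does not match expression matrix columns",
            class = "restrictr_format_error")
    }
  }
  tibble::as_tibble(sheet)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, `set_id TAB description TAB member...`.
#' Duplicate members within one set are removed with a warning.
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `set_id`, `description`, and a `genes`
#'   list-column of member character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(set_id = character(), description = character(),
                          genes = list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad)) {
    abort(sprintf("GMT line %d has fewer than 3 fields", which(bad)[1]),
          class = "restrictr_format_error")
  }
  genes <- purrr::map(fields, function(f) {
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warn("duplicate members within a gene set were removed")
      members <- unique(members)
    }
    if (length(members) == 0L) {
      abort("gene set with no members", class = "restrictr_format_error")
    }
    members
  })
  tibble::tibble(
    set_id = purrr::map_chr(fields, 1L),
    description = purrr::map_chr(fields, 2L),
    genes = genes
  )
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection Tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- purrr::pmap_chr(collection, function(set_id, description, genes, ...) {
    paste(c(set_id, description, genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Sequences are upper-cased and RNA `U` is normalized to `T` so that all
#' downstream comparisons work in a single DNA alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      abort(paste("failed to parse FASTA:", conditionMessage(e)),
            class = "restrictr_format_error")
    }
  )
  seqs <- normalize_sequence(as.character(set))
  if (any(!nzchar(seqs))) {
    abort("FASTA record with empty sequence", class = "restrictr_format_error")
  }
  # keep first whitespace-delimited token of the header, FASTA convention
  ids <- sub("\\s.*$", "", names(set))
  tibble::tibble(id = ids, sequence = unname(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param records Tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# uppercase, U -> T, validate alphabet
normalize_sequence <- function(x) {
  out <- chartr("u", "T", toupper(x))
  out <- chartr("U", "T", out)
  bad <- grepl("[^ACGTN]", out)
  if (any(bad)) {
    abort("sequence contains characters outside {A,C,G,T,U,N}",
          class = "restrictr_value_error")
  }
  out
}
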