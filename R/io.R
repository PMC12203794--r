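#' Read a probe manifest
#'
#' Reads a tab-separated probe manifest describing Infinium-style CpG probes:
#' columns `probe_id`, `chrom`, `pos` (1-based bp position of the interrogated
#' CpG), `strand` (`+`, `-` or `.`), `gene` and `region_class`. A probe
#' annotated to several genes carries semicolon-joined parallel lists in
#' `gene` and `region_class` (e.g. gene `"A;B"`, class `"TSS200;Body"`).
#' Intergenic probes leave `gene` empty.
#'
#' @param path path to a manifest TSV with a header line.
#' @return A tibble with one row per (probe, gene, region_class) annotation
#'   pair (intergenic probes keep a single row with `NA` gene), sorted by
#'   `(chrom, pos)` with a stable order on ties.
#' @export
read_probe_manifest <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(),
    chrom = readr::col_character(),
    pos = readr::col_double(),
    strand = readr::col_character(),
    gene = readr::col_character(),
    region_class = readr::col_character()
  ), progress = FALSE, na = character())
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0("malformed manifest row at line ", probs$row[1] + 1L,
                 ": ", probs$expected[1]))
  }
  need <- c("probe_id", "chrom", "pos", "strand", "gene", "region_class")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("manifest is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (anyNA(raw$pos) || any(raw$pos < 1)) {
    bad <- which(is.na(raw$pos) | raw$pos < 1)[1]
    abort(paste0("manifest position must be >= 1 (line ", bad + 1L, ")"))
  }
  if (anyDuplicated(raw$probe_id)) {
    dup <- raw$probe_id[duplicated(raw$probe_id)][1]
    abort(paste0("duplicate probe_id in manifest: ", dup))
  }
  if (!all(raw$strand %in% c("+", "-", "."))) {
    abort("manifest strand must be one of '+', '-', '.'")
  }
  long <- expand_manifest_annotations(raw)
  bad_class <- setdiff(unique(long$region_class[!is.na(long$region_class)]),
                       region_classes())
  if (length(bad_class) > 0) {
    abort(paste0("unknown region_class values: ", paste(bad_class, collapse = ", ")))
  }
  dplyr::arrange(long, .data$chrom, .data$pos)
}

region_classes <- function() {
  c("TSS200", "TSS1500", "5UTR", "1stExon", "Body", "3UTR")
}

#' Promoter/5'UTR region classes used for gene assignment
#'
#' The probe classes treated as promoter-proximal when assigning DMRs to genes
#' and when averaging promoter methylation.
#' @return Character vector of region classes.
#' @export
promoter_classes <- function() {
  c("TSS200", "TSS1500", "5UTR")
}

expand_manifest_annotations <- function(raw) {
  genes <- strsplit(raw$gene, ";", fixed = TRUE)
  classes <- strsplit(raw$region_class, ";", fixed = TRUE)
  n_g <- lengths(genes)
  n_c <- lengths(classes)
  # empty gene field -> intergenic probe, one row with NA annotation
  inter <- raw$gene == "" | is.na(raw$gene)
  if (any(n_g[!inter] != n_c[!inter])) {
    bad <- which(!inter & n_g != n_c)[1]
    abort(paste0("gene/region_class lists differ in length (line ", bad + 1L, ")"))
  }
  n_g[inter] <- 1L
  genes[inter] <- list(NA_character_)
  classes[inter] <- list(NA_character_)
  idx <- rep.int(seq_len(nrow(raw)), n_g)
  tibble::tibble(
    probe_id = raw$probe_id[idx],
    chrom = raw$chrom[idx],
    pos = raw$pos[idx],
    strand = raw$strand[idx],
    gene = unlist(genes, use.names = FALSE),
    region_class = unlist(classes, use.names = FALSE)
  )
}

#' Write a probe manifest
#'
#' Inverse of [read_probe_manifest()]: collapses annotation pairs per probe
#' back to semicolon-joined parallel lists.
#' @param manifest long-format manifest tibble.
#' @param path output path.
#' @export
write_probe_manifest <- function(manifest, path) {
  wide <- manifest |>
    dplyr::group_by(.data$probe_id, .data$chrom, .data$pos, .data$strand) |>
    dplyr::summarise(
      gene = paste(ifelse(is.na(.data$gene), "", .data$gene), collapse = ";"),
      region_class = paste(ifelse(is.na(.data$region_class), "", .data$region_class),
                           collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$pos)
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read a numeric probe or gene matrix
#'
#' Reads a TSV whose first column holds row identifiers (probe ids for
#' methylation, gene symbols for expression) and whose remaining columns are
#' samples. `"NA"` cells denote missing values.
#'
#' @param path path to the TSV.
#' @param kind `"beta"` enforces values in \eqn{[0,1]} (missing allowed);
#'   `"expression"` enforces complete non-negative values on the
#'   \eqn{\log_2(1+x)} scale.
#' @return A numeric matrix with row and column names.
#' @export
read_matrix <- function(path, kind = c("beta", "expression")) {
  kind <- match.arg(kind)
  hdr <- strsplit(readr::read_lines(path, n_max = 1), "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 2) abort("matrix file must have an id column and >= 1 sample")
  spec <- do.call(readr::cols, c(
    setNames(list(readr::col_character()), hdr[1]),
    list(.default = readr::col_double())
  ))
  raw <- readr::read_tsv(path, col_types = spec, progress = FALSE)
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0("ragged or non-numeric matrix row at line ", probs$row[1] + 1L))
  }
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate row identifier: ", ids[duplicated(ids)][1]))
  }
  mat <- as.matrix(raw[, -1, drop = FALSE])
  rownames(mat) <- ids
  validate_matrix(mat, kind)
  mat
}

validate_matrix <- function(mat, kind) {
  if (kind == "beta") {
    bad <- which(!is.na(mat) & (mat < 0 | mat > 1), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      abort(paste0("beta value outside [0,1] at probe '",
                   rownames(mat)[bad[1, 1]], "', sample '",
                   colnames(mat)[bad[1, 2]], "': ", mat[bad[1, , drop = FALSE]]))
    }
  } else {
    if (anyNA(mat)) {
      bad <- which(is.na(mat), arr.ind = TRUE)
      abort(paste0("expression matrices must be complete; NA at gene '",
                   rownames(mat)[bad[1, 1]], "', sample '",
                   colnames(mat)[bad[1, 2]], "'"))
    }
    if (any(mat < 0)) {
      bad <- which(mat < 0, arr.ind = TRUE)
      abort(paste0("negative expression value at gene '",
                   rownames(mat)[bad[1, 1]], "'"))
    }
  }
  invisible(mat)
}

#' Write a numeric matrix as TSV
#'
#' Round-trips with [read_matrix()]: identical row/column order and values to
#' full printed precision (15 significant digits).
#' @param mat numeric matrix with dimnames.
#' @param path output path.
#' @param id_col name of the identifier column in the header.
#' @export
write_matrix <- function(mat, path, id_col = "id") {
  df <- tibble::as_tibble(mat, rownames = id_col)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a GMT gene set collection
#'
#' Standard MSigDB dialect: one set per line,
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a set
#' are deduplicated preserving first occurrence.
#'
#' @param path path to a `.gmt` file.
#' @param collection optional collection label (e.g. `"H"`, `"C2"`).
#' @return Named list of character vectors with attribute `collection`.
#' @export
read_gmt <- function(path, collection = NA_character_) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(paste0("GMT line ", i, " has fewer than 3 fields"))
    }
    genes <- fields[-c(1, 2)]
    genes <- genes[nzchar(genes)]
    genes <- genes[!duplicated(genes)]
    if (length(genes) == 0) {
      abort(paste0("GMT set '", fields[1], "' is empty"))
    }
    nms[i] <- fields[1]
    sets[[i]] <- genes
  }
  names(sets) <- nms
  attr(sets, "collection") <- collection
  sets
}

#' Write a GMT gene set collection
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read mutation records
#'
#' Minimal MAF-like TSV with header columns `sample`, `gene`, `consequence`.
#' Consequence terms are normalised to `lower_snake_case` so cBioPortal-style
#' and Sequence-Ontology-style spellings match one classifier
#' (`"Frameshift Variant"` becomes `"frameshift_variant"`).
#'
#' @param path path to the TSV.
#' @return Tibble with columns `sample_id`, `gene`, `consequence`.
#' @export
read_mutations <- function(path) {
  raw <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  need <- c("sample", "gene", "consequence")
  if (!all(need %in% names(raw))) {
    abort("mutation table must have columns sample, gene, consequence")
  }
  if (any(!nzchar(raw$sample) | !nzchar(raw$gene) | !nzchar(raw$consequence)) ||
      anyNA(raw[need])) {
    abort("mutation table has empty fields")
  }
  tibble::tibble(
    sample_id = raw$sample,
    gene = raw$gene,
    consequence = normalise_consequence(raw$consequence)
  )
}

#' Normalise a consequence term to lower_snake_case
#' @param x character vector of consequence terms.
#' @return Normalised character vector.
#' @export
normalise_consequence <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[ \\-]+", "_", x)
  gsub("_+", "_", x)
}

#' Read gene-level copy-number records
#'
#' TSV with header columns `sample`, `gene`, `category`; categories are the
#' usual five-level calls (-2 deep deletion, -1 shallow loss, 0 neutral,
#' 1 gain, 2 amplification).
#' @param path path to the TSV.
#' @return Tibble with columns `sample_id`, `gene`, `category`.
#' @export
read_cnas <- function(path) {
  raw <- readr::read_tsv(path, col_types = "ccd", progress = FALSE)
  need <- c("sample", "gene", "category")
  if (!all(need %in% names(raw))) {
    abort("CNA table must have columns sample, gene, category")
  }
  if (anyNA(raw$category) || !all(raw$category %in% -2:2)) {
    bad <- raw$category[is.na(raw$category) | !(raw$category %in% -2:2)][1]
    abort(paste0("CNA category outside {-2..2}: ", bad))
  }
  tibble::tibble(
    sample_id = raw$sample,
    gene = raw$gene,
    category = as.integer(raw$category)
  )
}

#' Write called DMRs as BED6+
#'
#' Emits 0-based half-open intervals with `start = min(pos) - 1`,
#' `end = max(pos)`; score column is `-log10(p_sidak)` (capped at 300), strand
#' `"."`, plus extra columns `n_probes`, `p_combined`, `direction`, `genes`.
#' @param dmrs a DMR tibble as returned by [call_dmrs()]`$dmrs`.
#' @param path output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  genes <- vapply(dmrs$genes %||% replicate(nrow(dmrs), character(0), simplify = FALSE),
                  function(g) paste(g, collapse = ","), character(1))
  bed <- tibble::tibble(
    chrom = dmrs$chrom,
    start = dmrs$start,
    end = dmrs$end,
    name = sprintf("dmr_%d", seq_len(nrow(dmrs))),
    score = round(pmin(300, -log10(pmax(dmrs$p_sidak, 1e-300))), 4),
    strand = ".",
    n_probes = dmrs$n_probes,
    p_combined = dmrs$p_combined,
    direction = dmrs$direction,
    genes = genes
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
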