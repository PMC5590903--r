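# Readers and writers for every tabular artifact: count matrices, sample
# designs, DE tables (including the dialects of the supplementary CSV
# exports), gene sets, term maps, and the JSON run report. TSV is the default
# dialect; CSV is auto-detected.

detect_sep <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  if (length(line) == 0) return("\t")
  ntab <- lengths(regmatches(line, gregexpr("\t", line, fixed = TRUE)))
  ncom <- lengths(regmatches(line, gregexpr(",", line, fixed = TRUE)))
  if (ntab >= ncom) "\t" else ","
}

GENE_ID_ALIASES <- c("gene_id", "gene", "geneid", "id", "gene_name", "x")

#' Read a gene x sample count table
#'
#' Accepts comma- or tab-delimited text (auto-detected). Gene identifiers are
#' taken from a column recognizable as a gene-id column (`gene_id`, `gene`,
#' `id`, ... case-insensitively), from an unnamed first column, or from the
#' first column if it is non-numeric. Values within 1e-9 of an integer are
#' rounded; anything else is rejected with the offending location.
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) auto-detects.
#' @param gene_col name of the gene-id column, overriding detection.
#' @param normalize_ids if `TRUE`, strip a trailing `_Tnn`/`.nn` transcript
#'   version suffix from gene ids (off by default; ids are opaque strings).
#' @return validated integer matrix, genes x samples.
#' @export
read_count_table <- function(path, sep = NULL, gene_col = NULL,
                             normalize_ids = FALSE) {
  if (!file.exists(path)) stop_pz("no such file: %s", path)
  sep <- sep %||% detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "", fill = FALSE)
  if (ncol(df) < 1) {
    stop_pz("count table needs a gene-id column plus >= 1 sample column")
  }
  ids <- NULL
  if (!is.null(gene_col)) {
    if (!gene_col %in% names(df)) stop_pz("no column '%s' in %s", gene_col, path)
    ids <- as.character(df[[gene_col]])
    df[[gene_col]] <- NULL
  } else if (!is.character(attr(df, "row.names"))) {
    # no implicit rownames from a short header: locate the id column
    cand <- which(tolower(names(df)) %in% GENE_ID_ALIASES |
                    names(df) == "" |
                    !vapply(df, is.numeric, logical(1)))
    if (length(cand) == 0) {
      stop_pz("cannot locate a gene-id column in %s", path)
    }
    ids <- as.character(df[[cand[1]]])
    df[[cand[1]]] <- NULL
  } else {
    ids <- rownames(df)
  }
  if (normalize_ids) ids <- sub("(_T[0-9]+|\\.[0-9]+)$", "", ids)
  if (anyDuplicated(ids)) {
    stop_pz("duplicate gene id '%s' in %s", ids[duplicated(ids)][1], path)
  }
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      stop_pz("non-numeric values in sample column '%s' of %s",
              names(df)[j], path)
    }
  }
  m <- as.matrix(df)
  rownames(m) <- ids
  bad <- which(abs(m - round(m)) > 1e-9, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_pz("non-integer count at row '%s' (sample '%s') in %s",
            ids[bad[1, 1]], colnames(m)[bad[1, 2]], path)
  }
  if (any(is.na(m)) || any(m < 0)) {
    bad <- which(is.na(m) | m < 0, arr.ind = TRUE)
    stop_pz("negative or missing count at row '%s' in %s", ids[bad[1, 1]], path)
  }
  validate_count_matrix(round(m))
  round(m)
}

#' Write a count matrix as delimited text
#' @param counts gene x sample matrix.
#' @param path output path.
#' @param sep field separator (tab default).
#' @export
write_count_table <- function(counts, path, sep = "\t") {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample design table
#' @param path file path.
#' @return data.frame with sample_id, taxon, group, condition.
#' @export
read_sample_design <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  validate_sample_design(df)
  df
}

#' @rdname read_sample_design
#' @param design design data.frame.
#' @export
write_sample_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (deduplicated on construction).
#' @param background character vector of background gene ids.
#' @return list of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, background) {
  if (length(background) == 0) stop_pz("background must be non-empty")
  if (is.null(names(sets)) && length(sets) > 0) {
    stop_pz("sets must be named")
  }
  out <- list(sets = lapply(sets, unique), background = unique(background))
  class(out) <- "gene_set_collection"
  out
}

#' Read gene sets from files
#'
#' Two dialects: (1) a named character vector of paths, each file one gene id
#' per line, producing one set per file; (2) a single two-column membership
#' file (gene, set-name). Sets are deduplicated; empty files yield empty sets
#' with a warning.
#'
#' @param paths named character vector of one-id-per-line files, or a single
#'   path to a two-column file.
#' @param background background gene ids for the collection.
#' @return a [gene_set_collection()].
#' @export
read_gene_sets <- function(paths, background) {
  if (length(paths) == 1L && is.null(names(paths))) {
    sep <- detect_sep(paths)
    df <- utils::read.table(paths, sep = sep, header = TRUE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop_pz("membership file %s needs 2 columns", paths)
    sets <- split(as.character(df[[1]]), df[[2]])
  } else {
    if (is.null(names(paths))) stop_pz("multiple set files must be named")
    sets <- lapply(paths, function(p) {
      x <- readLines(p, warn = FALSE)
      x <- trimws(x)
      x <- x[nzchar(x)]
      if (length(x) == 0) warn_pz("empty gene-set file: %s", p)
      x
    })
  }
  gene_set_collection(sets, background)
}

#' Write a gene-set collection as a two-column membership TSV
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @export
write_gene_sets <- function(collection, path) {
  rows <- do.call(rbind, lapply(names(collection$sets), function(nm) {
    data.frame(gene_id = collection$sets[[nm]], set = nm,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a gene-to-term annotation map (two-column TSV)
#' @param path file path.
#' @export
read_term_map <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  names(df)[1:2] <- c("gene_id", "term")
  unique(df[c("gene_id", "term")])
}

#' @rdname read_term_map
#' @param term_map data.frame (gene_id, term).
#' @export
write_term_map <- function(term_map, path) {
  utils::write.table(term_map[c("gene_id", "term")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Alias map for columns of externally produced DE tables. Keys are
# canonicalized header names (lower case, punctuation stripped).
DE_COLUMN_ALIASES <- list(
  base_mean = c("basemean", "base_mean", "mean_expression", "aveexpr",
                "meanexpr", "mean"),
  lfc = c("lfc", "log2foldchange", "log2fc", "logfc", "log2_fold_change"),
  lfc_se = c("lfcse", "lfc_se", "se"),
  wald_stat = c("stat", "wald_stat", "waldstat", "t", "z"),
  p_value = c("pvalue", "p_value", "pval", "p"),
  p_adj = c("padj", "p_adj", "adjp", "adjpval", "fdr", "qvalue", "adj_p_val")
)

canon_name <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Read a per-gene differential-expression table in a foreign dialect
#'
#' Recognizes, case-insensitively and ignoring punctuation, the column names
#' used by standard DE tools for mean expression, log2 fold change, standard
#' error, test statistic, p-value and adjusted p-value; unrecognized columns
#' are preserved as-is. Extend `aliases` to support further dialects.
#'
#' @param path file path (CSV or TSV, auto-detected).
#' @param aliases alias map, `list(canonical = c(aliases...))`; merged over
#'   the built-in map.
#' @return data.frame with canonical columns `gene_id`, `base_mean`, `lfc`,
#'   `lfc_se`, `wald_stat`, `p_value`, `p_adj` where present, plus any extra
#'   columns.
#' @export
read_de_table <- function(path, aliases = list()) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  amap <- DE_COLUMN_ALIASES
  for (nm in names(aliases)) amap[[nm]] <- union(aliases[[nm]], amap[[nm]])
  if (is.character(attr(df, "row.names"))) {
    df <- data.frame(gene_id = rownames(df), df, check.names = FALSE,
                     stringsAsFactors = FALSE)
    rownames(df) <- NULL
  }
  nm <- names(df)
  cn <- canon_name(nm)
  # gene id column: alias match, else first non-numeric column
  gi <- which(cn %in% GENE_ID_ALIASES)
  if (length(gi) == 0) gi <- which(!vapply(df, is.numeric, logical(1)))[1]
  if (length(gi) == 0 || is.na(gi[1])) stop_pz("no gene-id column in %s", path)
  names(df)[gi[1]] <- "gene_id"
  nm <- names(df); cn <- canon_name(nm)
  for (canonical in names(amap)) {
    hit <- which(cn %in% canon_name(amap[[canonical]]) & nm != "gene_id")
    if (length(hit) > 0) names(df)[hit[1]] <- canonical
    nm <- names(df); cn <- canon_name(nm)
  }
  if (anyDuplicated(df$gene_id)) stop_pz("duplicate gene ids in %s", path)
  front <- intersect(c("gene_id", "base_mean", "lfc", "lfc_se", "wald_stat",
                       "p_value", "p_adj"), names(df))
  df[c(front, setdiff(names(df), front))]
}

#' Write a DE result table with stable column names
#' @param de DE result data.frame.
#' @param path output path.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a run summary as JSON
#' @param report named list.
#' @param path output path.
#' @export
write_run_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
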