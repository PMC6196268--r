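#' Read an expression matrix from tab-separated text
#'
#' First column holds feature ids, the header row sample ids (or the
#' transpose with `orientation = "samples"`). An optional first-line
#' directive `# scale: log2` (or `linear`) declares the scale; an explicit
#' `scale` argument wins.
#'
#' @param path file path.
#' @param orientation `"features"` (features in rows, the default) or
#'   `"samples"` (transposed file).
#' @param scale `"linear"`, `"log2"`, or `NULL` to use the file directive
#'   (defaulting to `"log2"` when absent).
#' @return an [expr_matrix()].
#' @export
read_expression_tsv <- function(path, orientation = c("features", "samples"),
                                scale = NULL) {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  if (!length(lines)) stop("empty expression file: ", path)
  file_scale <- NULL
  if (grepl("^#", lines[1])) {
    m <- regmatches(lines[1], regexec("scale:\\s*(log2|linear)", lines[1]))[[1]]
    if (length(m) == 2) file_scale <- m[2]
    lines <- lines[-1]
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- trimws(fields[[1]])
  body <- fields[-1]
  ids <- vapply(body, function(f) trimws(f[1]), "")
  ncol_expect <- length(header) - 1L
  vals <- matrix(NA_real_, length(body), ncol_expect)
  for (i in seq_along(body)) {
    f <- body[[i]]
    if (length(f) != length(header))
      stop("row ", i + 1L, " has ", length(f), " fields, expected ",
           length(header))
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop("non-numeric value '", f[j + 1L], "' at row ", i + 1L,
           ", column ", j + 1L)
    }
    vals[i, ] <- v
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated ids in first column: ", paste(dup, collapse = ", "))
  rownames(vals) <- ids
  colnames(vals) <- header[-1]
  if (orientation == "samples") vals <- t(vals)
  sc <- scale %||% file_scale %||% "log2"
  expr_matrix(vals, scale = sc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an expression matrix as tab-separated text
#'
#' Values are written with 6 significant digits and a `# scale:` directive,
#' so that write-then-read round-trips ids, ordering and values within text
#' precision.
#'
#' @param mat an [expr_matrix()].
#' @param path output path.
#' @export
write_expression_tsv <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# scale: ", expr_scale(mat)), con)
  writeLines(paste(c("feature", colnames(mat)), collapse = "\t"), con)
  body <- apply(format(unclass(mat), digits = 6, trim = TRUE,
                       scientific = FALSE), 1, paste, collapse = "\t")
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}

#' Read a GEO series-matrix file
#'
#' Parses the self-describing tab-delimited GEO distribution format:
#' metadata lines prefixed `!`, expression values between
#' `!series_matrix_table_begin` and `!series_matrix_table_end`. Sample
#' characteristics mentioning CD56bright/CD56dim phenotypes are mapped to
#' group labels best-effort (`CD56bright` + `CD16dim`/`CD16+` ->
#' `bright_cd16dim`, else `bright`; `CD56dim` -> `dim`); a
#' `batch: <id>` characteristic populates `batch_id`. Unparsed
#' characteristics are preserved verbatim in a `characteristics` column.
#' An explicit metadata table should always override this best-effort
#' extraction.
#'
#' @param path file path.
#' @param scale scale tag for the value matrix (GEO deposits processed,
#'   typically log2, values; default `"log2"`).
#' @return list with elements `matrix` (an [expr_matrix()]) and `metadata`
#'   (data frame: sample_id, group, batch_id, characteristics).
#' @export
read_series_matrix <- function(path, scale = "log2") {
  lines <- readLines(path)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg)
    stop("not a series-matrix file: missing table delimiters in ", path)
  tab <- lines[(beg + 1L):(end - 1L)]
  tab <- tab[nzchar(tab)]
  tc <- textConnection(tab)
  on.exit(close(tc))
  df <- utils::read.delim(tc, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  ids <- gsub('^"|"$', "", as.character(df[[1]]))
  rownames(vals) <- ids
  colnames(vals) <- gsub('^"|"$', "", colnames(vals))
  mat <- expr_matrix(vals, scale = scale)

  meta_lines <- lines[seq_len(beg - 1L)]
  get_fields <- function(key) {
    ln <- grep(paste0("^!", key, "\\b"), meta_lines, value = TRUE)
    lapply(ln, function(l) {
      f <- strsplit(l, "\t", fixed = TRUE)[[1]][-1]
      gsub('^"|"$', "", f)
    })
  }
  titles <- get_fields("Sample_geo_accession")
  if (!length(titles)) titles <- get_fields("Sample_title")
  sample_ids <- if (length(titles)) titles[[1]] else colnames(vals)
  chars <- get_fields("Sample_characteristics_ch1")
  char_txt <- if (length(chars))
    apply(do.call(rbind, chars), 2, paste, collapse = "; ")
  else rep("", length(sample_ids))
  group <- vapply(char_txt, .parse_group, "", USE.NAMES = FALSE)
  batch <- vapply(char_txt, function(s) {
    m <- regmatches(s, regexec("batch[^:]*:\\s*([^;]+)", s,
                               ignore.case = TRUE))[[1]]
    if (length(m) == 2) trimws(m[2]) else NA_character_
  }, "", USE.NAMES = FALSE)
  md <- data.frame(sample_id = colnames(vals), group = group,
                   batch_id = batch, characteristics = char_txt,
                   stringsAsFactors = FALSE)
  list(matrix = mat, metadata = md)
}

.parse_group <- function(s) {
  sl <- tolower(gsub("[^a-z0-9+/-]", "", tolower(s)))
  if (grepl("cd56bright", sl)) {
    if (grepl("cd16dim|cd16\\+", sl)) "bright_cd16dim" else "bright"
  } else if (grepl("cd56dim", sl)) "dim" else NA_character_
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then member identifiers,
#' tab-separated. Duplicate members within a line are dropped.
#'
#' @param path GMT file path.
#' @return list of class `gene_sets`: named list of character vectors, with
#'   a `description` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- trimws(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (length(f) < 3)
      stop("GMT line ", i, " has fewer than 3 fields")
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop("GMT line ", i, ": empty member set")
    sets[[f[1]]] <- members
    desc[f[1]] <- f[2]
  }
  structure(sets, description = desc, class = c("gene_sets", "list"))
}

#' Write a differential-expression signature table
#'
#' Writes the columns `feature`, `median_log2_bright`, `median_log2_dim`,
#' `delta_log2`, `fold_change`, `p`, `p_adj`, `status`, ordered by adjusted
#' p then feature id, as tab-separated text.
#'
#' @param results a data frame as returned by [differential_expression()].
#' @param path output path.
#' @export
write_signature_tsv <- function(results, path) {
  cols <- c("feature", "median_log2_bright", "median_log2_dim", "delta_log2",
            "fold_change", "p", "p_adj", "status")
  if (!all(cols %in% names(results)))
    stop("results missing columns: ",
         paste(setdiff(cols, names(results)), collapse = ", "))
  out <- results[order(results$p_adj, results$feature), cols]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read miRNA target-prediction tables
#'
#' Consumes plain tables (one per prediction tool, or one combined) with
#' columns `mirna`, `gene`, and optionally `tool`; identifier whitespace is
#' trimmed, case preserved, and duplicated (mirna, gene, tool) rows dropped.
#'
#' @param path TSV path with a header row.
#' @param tool tool name used when the file has no `tool` column.
#' @return data frame with columns mirna, gene, tool.
#' @export
read_target_table <- function(path, tool = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("mirna", "gene") %in% names(df)))
    stop("target table needs columns 'mirna' and 'gene'")
  if (is.null(df$tool)) {
    if (is.null(tool)) stop("no 'tool' column; supply a tool name")
    df$tool <- tool
  }
  df$mirna <- trimws(df$mirna); df$gene <- trimws(df$gene)
  df <- df[, c("mirna", "gene", "tool")]
  unique(df)
}
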