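#' Expression matrix container
#'
#' An expression matrix is an ordinary numeric matrix (features in rows,
#' samples in columns, dimnames mandatory) carrying a `scale` attribute that
#' records whether values are linear-scale light units (LU) or log2 LU. All
#' statistical operations in the package require the log2 scale; the
#' preprocessing chain ([floor_threshold()], [log2_transform()]) moves a raw
#' linear matrix onto it.
#'
#' @param values numeric matrix, features x samples, with unique non-empty
#'   rownames (feature ids) and colnames (sample ids).
#' @param scale either `"linear"` or `"log2"`.
#' @return an object of class `expr_matrix` (a matrix with a `scale`
#'   attribute).
#' @examples
#' m <- expr_matrix(matrix(1:6, 3, 2,
#'   dimnames = list(paste0("mir", 1:3), c("s1", "s2"))), scale = "linear")
#' expr_scale(m)
#' @export
expr_matrix <- function(values, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  fid <- rownames(values); sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stop("expression matrix needs rownames (features) and colnames (samples)")
  if (anyNA(values))
    stop("expression matrix contains missing values")
  dup <- unique(fid[duplicated(fid)])
  if (length(dup))
    stop("duplicated feature ids: ", paste(dup, collapse = ", "))
  dup <- unique(sid[duplicated(sid)])
  if (length(dup))
    stop("duplicated sample ids: ", paste(dup, collapse = ", "))
  if (any(!nzchar(fid)) || any(!nzchar(sid)))
    stop("empty feature or sample id")
  structure(values, scale = scale, class = c("expr_matrix", class(values)))
}

#' @rdname expr_matrix
#' @param x an `expr_matrix`.
#' @export
expr_scale <- function(x) {
  sc <- attr(x, "scale")
  if (is.null(sc)) "log2" else sc
}

`expr_scale<-` <- function(x, value) {
  attr(x, "scale") <- value
  x
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples (%s scale)\n",
              nrow(x), ncol(x), expr_scale(x)))
  n <- min(5L, nrow(x)); m <- min(5L, ncol(x))
  print(unclass(x)[seq_len(n), seq_len(m), drop = FALSE])
  if (nrow(x) > n || ncol(x) > m) cat("...\n")
  invisible(x)
}

# keep class/scale through subsetting
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, scale = expr_scale(x),
                     class = c("expr_matrix", class(out)))
  out
}

.assert_log2 <- function(x, what) {
  if (!identical(expr_scale(x), "log2"))
    stop(what, " requires a log2-scale matrix; run floor_threshold() and ",
         "log2_transform() first")
  invisible(TRUE)
}

#' Validate sample metadata against an expression matrix
#'
#' Metadata is a data frame with columns `sample_id`, `group`
#' (one of `"bright"`, `"dim"`, `"bright_cd16dim"`), and optionally
#' `donor_id` and `batch_id`. Every sample of the matrix must have exactly
#' one metadata row.
#'
#' @param mat an [expr_matrix()].
#' @param metadata data frame as above.
#' @param require_batch require a `batch_id` column.
#' @return the metadata reordered to match `colnames(mat)` (invisibly checked).
#' @export
check_metadata <- function(mat, metadata, require_batch = FALSE) {
  if (!is.data.frame(metadata) ||
      !all(c("sample_id", "group") %in% names(metadata)))
    stop("metadata must be a data frame with columns sample_id and group")
  metadata$sample_id <- as.character(metadata$sample_id)
  if (anyDuplicated(metadata$sample_id))
    stop("duplicated sample_id in metadata")
  missing <- setdiff(colnames(mat), metadata$sample_id)
  if (length(missing))
    stop("samples without metadata: ", paste(missing, collapse = ", "))
  ok <- c("bright", "dim", "bright_cd16dim")
  bad <- setdiff(unique(as.character(metadata$group)), c(ok, NA))
  if (length(bad))
    stop("unknown group labels: ", paste(bad, collapse = ", "))
  if (require_batch && is.null(metadata$batch_id))
    stop("metadata must contain a batch_id column for this operation")
  metadata[match(colnames(mat), metadata$sample_id), , drop = FALSE]
}

# two-group helper: returns list(bright = idx, dim = idx) or the two groups
# present, erroring unless exactly two non-empty groups
.two_groups <- function(mat, metadata) {
  md <- check_metadata(mat, metadata)
  g <- as.character(md$group)
  tab <- table(g)
  if (length(tab) != 2L)
    stop("exactly two groups required, found: ",
         paste(names(tab), collapse = ", "))
  split(seq_along(g), g)
}
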