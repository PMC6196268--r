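#' Hypergeometric over-representation of a gene signature in gene sets
#'
#' For each gene set: k = |signature ∩ set|, K = |set ∩ reference|,
#' n = |signature ∩ reference|, N = |reference|; the enrichment ratio is
#' (k/n)/(K/N) and the raw p-value the upper hypergeometric tail
#' P[X >= k] of drawing n genes from a reference of N containing K set
#' members. Sets with fewer than `min_genes` signature hits are excluded
#' both from the results and from the Bonferroni multiplicity count m;
#' p_adj = min(1, m * p_raw), flagged significant at `alpha`.
#'
#' Signature and sets are intersected with the reference before counting;
#' set members outside the reference are dropped with a warning.
#'
#' @param signature_genes character vector of gene identifiers.
#' @param gene_sets a [read_gmt()] collection (or named list of character
#'   vectors).
#' @param reference character vector: the gene universe.
#' @param min_genes minimum overlap to test a set (default 3).
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return data frame of class `enrichment_result`: set, k, K, n, N,
#'   ratio, p_raw, p_adj, score (-log10 p_adj), significant, overlap
#'   (semicolon-joined gene list), ordered by p_adj then set name.
#' @export
hypergeometric_enrichment <- function(signature_genes, gene_sets,
                                      reference, min_genes = 3L,
                                      alpha = 0.05) {
  if (!length(reference)) stop("empty reference set")
  reference <- unique(reference)
  sig <- intersect(unique(signature_genes), reference)
  if (length(signature_genes) && !length(sig))
    stop("signature is disjoint from the reference set")
  N <- length(reference); n <- length(sig)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- unique(gene_sets[[nm]])
    outside <- setdiff(members, reference)
    if (length(outside))
      warning("set '", nm, "': ", length(outside),
              " members outside the reference dropped")
    members <- intersect(members, reference)
    K <- length(members)
    ov <- intersect(sig, members)
    k <- length(ov)
    if (k < min_genes) return(NULL)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N,
               ratio = (k / n) / (K / N), p_raw = p,
               overlap = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    out <- data.frame(set = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), ratio = numeric(),
                      p_raw = numeric(), p_adj = numeric(),
                      score = numeric(), significant = logical(),
                      overlap = character(), stringsAsFactors = FALSE)
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  m <- nrow(out)
  out$p_adj <- pmin(1, m * out$p_raw)
  out$score <- -log10(out$p_adj)
  out$significant <- out$p_adj <= alpha
  out <- out[order(out$p_adj, out$set),
             c("set", "k", "K", "n", "N", "ratio", "p_raw", "p_adj",
               "score", "significant", "overlap")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Pool target predictions across tools
#'
#' Takes one or more (mirna, gene, tool) prediction tables and returns the
#' union of pairs with the number of distinct supporting tools, optionally
#' filtered by a minimum support.
#'
#' @param tables a data frame or list of data frames with columns `mirna`,
#'   `gene`, `tool` (see [read_target_table()]).
#' @param min_support keep pairs predicted by at least this many tools
#'   (default 1).
#' @return data frame mirna, gene, n_tools, tools (semicolon-joined),
#'   ordered by mirna then gene.
#' @export
aggregate_targets <- function(tables, min_support = 1L) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (!length(tables)) stop("at least one prediction table required")
  all <- do.call(rbind, lapply(tables, function(df) {
    if (!all(c("mirna", "gene", "tool") %in% names(df)))
      stop("each table needs columns mirna, gene, tool")
    df[, c("mirna", "gene", "tool")]
  }))
  all$mirna <- trimws(all$mirna); all$gene <- trimws(all$gene)
  all <- unique(all)
  key <- paste(all$mirna, all$gene, sep = "\r")
  tools <- tapply(all$tool, key, function(t) sort(unique(t)))
  parts <- strsplit(names(tools), "\r", fixed = TRUE)
  out <- data.frame(mirna = vapply(parts, `[`, "", 1),
                    gene = vapply(parts, `[`, "", 2),
                    n_tools = lengths(tools),
                    tools = vapply(tools, paste, "", collapse = ";"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[out$n_tools >= min_support, ]
  out <- out[order(out$mirna, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Gene-by-direction pivot of aggregated targets
#'
#' Emits a table of target genes against the miRNAs predicted to regulate
#' them, split by the direction of miRNA regulation (which phenotype group
#' the miRNA is up-regulated in) — the layout used to scan for surface
#' markers under opposite-direction miRNA control.
#'
#' @param targets an [aggregate_targets()] result.
#' @param mirna_direction named character vector mapping each miRNA to a
#'   direction label (e.g. `"up_dim"` / `"up_bright"`).
#' @return data frame gene x direction, cells = semicolon-joined miRNAs.
#' @export
target_pivot <- function(targets, mirna_direction) {
  known <- targets[targets$mirna %in% names(mirna_direction), ]
  if (!nrow(known))
    return(data.frame(gene = character(), stringsAsFactors = FALSE))
  known$direction <- unname(mirna_direction[known$mirna])
  genes <- sort(unique(known$gene))
  dirs <- sort(unique(known$direction))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (d in dirs) {
    out[[d]] <- vapply(genes, function(g) {
      m <- sort(unique(known$mirna[known$gene == g & known$direction == d]))
      paste(m, collapse = ";")
    }, "")
  }
  out
}

#' Shared and list-specific significant gene sets
#'
#' Partitions the sets called significant (p_adj <= alpha) in two
#' enrichment results over the same collection into those shared and those
#' specific to each list.
#'
#' @param results_a,results_b [hypergeometric_enrichment()] results built
#'   from the same gene-set collection.
#' @param alpha significance level (default 0.05).
#' @return list with `shared`, `specific_a`, `specific_b` (set names).
#' @export
shared_specific_partition <- function(results_a, results_b, alpha = 0.05) {
  tested_a <- results_a$set; tested_b <- results_b$set
  # same-collection sanity: a set present in both results must have the
  # same K and N
  common <- intersect(tested_a, tested_b)
  if (length(common)) {
    ka <- results_a$K[match(common, tested_a)]
    kb <- results_b$K[match(common, tested_b)]
    na_ <- results_a$N[match(common, tested_a)]
    nb_ <- results_b$N[match(common, tested_b)]
    if (any(ka != kb) || any(na_ != nb_))
      stop("results come from different gene-set collections")
  }
  sig_a <- results_a$set[results_a$p_adj <= alpha]
  sig_b <- results_b$set[results_b$p_adj <= alpha]
  list(shared = sort(intersect(sig_a, sig_b)),
       specific_a = sort(setdiff(sig_a, sig_b)),
       specific_b = sort(setdiff(sig_b, sig_a)))
}
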