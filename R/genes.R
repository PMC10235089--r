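# Gene-expression association with niche composition: Pearson correlation
# against cluster counts / risk scores, the 50%-of-max activation-gene
# rule, and hypergeometric gene-set enrichment with BH-FDR control.

#' Correlate gene expression with cluster counts and risk scores
#'
#' Pearson correlation of every gene against every target column (cluster
#' counts, and optionally the OSRS). Genes with zero expression variance
#' are flagged missing (NA) rather than reported as correlations.
#'
#' @param expr genes x patients matrix (rownames = gene ids).
#' @param targets patients x targets data frame / matrix (e.g. the cluster
#'   count matrix, optionally with an \code{OSRS} column).
#' @return object of class \code{gene_cluster_correlation}: the genes x
#'   targets correlation matrix with attributes \code{n} (observations per
#'   entry) and \code{flagged} (constant genes).
#' @export
correlate_expression <- function(expr, targets) {
  expr <- as.matrix(expr)
  targets <- as.matrix(targets)
  if (ncol(expr) != nrow(targets)) {
    rlang::abort("expr (genes x patients) and targets (patients x k) disagree on patients")
  }
  gene_sd <- apply(expr, 1L, stats::sd)
  flagged <- rownames(expr)[gene_sd < 1e-12]
  r <- suppressWarnings(stats::cor(t(expr), targets))
  r[gene_sd < 1e-12, ] <- NA_real_
  tgt_sd <- apply(targets, 2L, stats::sd)
  r[, tgt_sd < 1e-12] <- NA_real_
  structure(r, n = ncol(expr), flagged = flagged,
            class = c("gene_cluster_correlation", class(r)))
}

#' Select activation genes by the 50%-of-max rule
#'
#' Per target, the threshold is half the maximum absolute correlation over
#' genes; genes whose absolute correlation exceeds the threshold are
#' selected ("activation genes"). Sign is retained in the correlation
#' object; selection uses magnitude.
#'
#' @param corr a [correlate_expression()] result (or plain matrix).
#' @return named list (one element per target) of selected gene-id vectors.
#' @export
select_activation_genes <- function(corr) {
  m <- unclass(corr)
  lapply(stats::setNames(seq_len(ncol(m)), colnames(m)), function(j) {
    a <- abs(m[, j])
    mx <- suppressWarnings(max(a, na.rm = TRUE))
    if (!is.finite(mx) || mx == 0) return(character(0))
    rownames(m)[!is.na(a) & a > 0.5 * mx]
  })
}

#' Hypergeometric gene-set over-representation with BH adjustment
#'
#' One-sided hypergeometric test of over-representation of the selected
#' genes in each gene set (both intersected with the universe), with
#' Benjamini-Hochberg adjustment across sets. Significance is convention-
#' ally read at FDR q < 0.05.
#'
#' @param selected character vector of selected gene ids.
#' @param gene_sets named list of gene-id vectors, or a path to a GMT file.
#' @param universe character vector of all testable gene ids.
#' @return tibble with \code{set}, \code{k} (overlap), \code{m} (set size),
#'   \code{s} (selection size), \code{U} (universe size), \code{p},
#'   \code{q}, ordered by p.
#' @export
enrich <- function(selected, gene_sets, universe) {
  if (is.character(gene_sets) && length(gene_sets) == 1L) {
    gene_sets <- read_gmt(gene_sets)
  }
  universe <- unique(universe)
  sel <- intersect(selected, universe)
  s <- length(sel)
  U <- length(universe)
  rows <- purrr::imap_dfr(gene_sets, function(genes, nm) {
    set <- intersect(genes, universe)
    m <- length(set)
    k <- length(intersect(sel, set))
    p <- stats::phyper(k - 1, m, U - m, s, lower.tail = FALSE)
    tibble::tibble(set = nm, k = k, m = m, s = s, U = U, p = p)
  })
  rows$q <- stats::p.adjust(rows$p, method = "BH")
  dplyr::arrange(rows, .data$p)
}

#' Read a GMT gene-set file
#'
#' One gene set per line: name, description, then gene ids (tab-separated).
#'
#' @param path GMT file path.
#' @return named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(pp) pp[-(1:2)]),
                  vapply(parts, `[[`, character(1), 1L))
}

#' Write a GMT gene-set file
#'
#' @param gene_sets named list of gene-id vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(gene_sets, path, description = "na") {
  lines <- purrr::imap_chr(gene_sets, function(genes, nm) {
    paste(c(nm, description, genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}
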