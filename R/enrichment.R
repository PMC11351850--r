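#' Hypergeometric GO over-representation
#'
#' For each GO term with at least `min_bg` annotated genes in the
#' background, the upper-tail probability `P(X >= k)` of drawing `k`
#' study-set hits in `n` draws from a background of `N` genes of which `K`
#' carry the term; BH adjustment is applied within each GO namespace
#' (configurable to global).
#'
#' @param study Character vector of study gene ids (must be a subset of the
#'   background).
#' @param background Character vector of background gene ids (the
#'   expressed, annotated universe).
#' @param go GO annotation table (`gene_id`, `go_id`, `go_namespace`).
#' @param category_map Optional go_id -> category map carried into the
#'   output.
#' @param min_bg Minimum background hits for a term to be tested
#'   (default 3).
#' @param adjust_within `"namespace"` (default) or `"global"` BH scope.
#' @return Data frame with `go_id`, `category`, `namespace`, `k`, `n`, `K`,
#'   `N`, `p`, `adj_p`, `fold`.
#' @export
hypergeom_enrich <- function(study, background, go, category_map = NULL,
                             min_bg = 3,
                             adjust_within = c("namespace", "global")) {
  adjust_within <- match.arg(adjust_within)
  bad <- setdiff(study, background)
  if (length(bad))
    stop("study genes absent from background: ",
         paste(head(bad, 10), collapse = ", "),
         if (length(bad) > 10) ", ...")
  study <- unique(study); background <- unique(background)
  go <- go[go$gene_id %in% background, , drop = FALSE]
  N <- length(background); n <- length(study)
  if (!nrow(go))
    return(data.frame(go_id = character(0), category = character(0),
                      namespace = character(0), k = integer(0),
                      n = integer(0), K = integer(0), N = integer(0),
                      p = numeric(0), adj_p = numeric(0), fold = numeric(0),
                      stringsAsFactors = FALSE))
  Kt <- table(go$go_id)
  kt <- table(go$go_id[go$gene_id %in% study])
  terms <- names(Kt)[Kt >= min_bg]
  K <- as.integer(Kt[terms])
  k <- as.integer(ifelse(is.na(kt[terms]), 0L, kt[terms]))
  ns <- go$go_namespace[match(terms, go$go_id)]
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(go_id = terms,
                    category = if (is.null(category_map)) NA_character_
                    else ifelse(is.na(category_map[terms]), "other",
                                category_map[terms]),
                    namespace = ns, k = k, n = n, K = K, N = N, p = p,
                    stringsAsFactors = FALSE)
  out$adj_p <- if (adjust_within == "namespace")
    stats::ave(out$p, out$namespace, FUN = adjust_bh)
  else adjust_bh(out$p)
  out$fold <- ifelse(K > 0 & n > 0, (k / n) / (K / N), 0)
  out <- out[order(out$p, out$go_id), ]
  rownames(out) <- NULL
  out
}

#' Fold-change-stratified enrichment of significant genes
#'
#' Builds one study set per log2 fold-change window over the significant
#' genes of a DE table (e.g. `FC <= -5` strongly day-upregulated,
#' `FC >= 5` strongly night-upregulated, `FC >= 2`) and runs
#' [hypergeom_enrich()] on each; empty strata yield an empty result with a
#' message rather than an error.
#'
#' @param de DE result table (ids must live in the background universe; use
#'   collapsed tables for reference-gene annotations).
#' @param strata Named list of length-2 numeric windows (inclusive) on
#'   log2FC.
#' @param background Background gene ids.
#' @param go,category_map,min_bg,adjust_within Passed to
#'   [hypergeom_enrich()].
#' @return Named list per stratum: `study` (gene ids) and `enrichment`
#'   (result table).
#' @export
stratified_enrich <- function(de, strata, background, go,
                              category_map = NULL, min_bg = 3,
                              adjust_within = "namespace") {
  id_col <- if ("reference_gene" %in% names(de)) "reference_gene" else "gene_id"
  out <- list()
  for (nm in names(strata)) {
    w <- strata[[nm]]
    sel <- de$significant & de$log2fc >= w[1] & de$log2fc <= w[2]
    study <- intersect(unique(de[[id_col]][sel]), background)
    if (!length(study)) {
      message("stratum '", nm, "' is empty")
      enr <- hypergeom_enrich(character(0), background, go, category_map,
                              min_bg, adjust_within)[0, ]
    } else {
      enr <- hypergeom_enrich(study, background, go, category_map, min_bg,
                              adjust_within)
    }
    out[[nm]] <- list(study = study, enrichment = enr)
  }
  out
}

#' Tag genes with their screened functional categories
#'
#' The union of the categories of a gene's GO terms under the category map;
#' genes with no category-mapped term are tagged `"other"`.
#'
#' @param genes Character vector of gene ids.
#' @param go GO annotation table.
#' @param category_map Named character vector go_id -> category.
#' @return Named list, gene id -> character vector of categories.
#' @export
tag_functional_categories <- function(genes, go, category_map) {
  ann <- go[go$gene_id %in% genes, , drop = FALSE]
  ann$category <- ifelse(is.na(category_map[ann$go_id]), "other",
                         category_map[ann$go_id])
  ann <- ann[ann$category != "other", , drop = FALSE]
  by_gene <- split(ann$category, ann$gene_id)
  out <- lapply(stats::setNames(genes, genes), function(g) {
    x <- unique(by_gene[[g]])
    if (is.null(x) || !length(x)) "other" else sort(x)
  })
  out
}
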