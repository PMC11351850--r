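#' Construct a validated count matrix
#'
#' Bundles an integer gene (or transcript) by sample count matrix with its
#' sample design table and optional feature lengths. This is the common input
#' container for every downstream stage: normalization, differential
#' expression, and co-expression.
#'
#' @param counts Integer matrix, genes in rows (rownames are gene ids),
#'   samples in columns (colnames are sample ids). Non-negative.
#' @param design Data frame with columns `sample_id`, `species`, `diel_phase`
#'   (`"day"`/`"night"`), `activity_niche` (`"diurnal"`/`"nocturnal"`), and
#'   `replicate`. Must describe exactly the samples in `counts`; columns of
#'   `counts` are reordered to the design order.
#' @param lengths Optional named numeric vector of feature lengths in bp,
#'   aligned 1:1 with the rownames of `counts`. Required for TPM computation.
#' @param allow_fractional If `TRUE`, fractional counts are rounded
#'   half-to-even instead of rejected.
#' @return An object of class `count_matrix`: a list with elements `counts`,
#'   `design`, `lengths`.
#' @export
count_matrix <- function(counts, design, lengths = NULL,
                         allow_fractional = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (is.null(colnames(counts))) stop("counts must have sample ids as colnames")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup)) stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != floor(counts))) {
    if (allow_fractional) counts[] <- round(counts)
    else stop("non-integer counts found; set allow_fractional = TRUE to round half-to-even")
  }
  design <- validate_design(design)
  missing_in_design <- setdiff(colnames(counts), design$sample_id)
  missing_in_counts <- setdiff(design$sample_id, colnames(counts))
  if (length(missing_in_design) || length(missing_in_counts)) {
    stop("samples in counts and design do not reconcile; ",
         if (length(missing_in_design))
           paste0("in counts only: ", paste(missing_in_design, collapse = ", "), "; "),
         if (length(missing_in_counts))
           paste0("in design only: ", paste(missing_in_counts, collapse = ", ")))
  }
  counts <- counts[, design$sample_id, drop = FALSE]
  storage.mode(counts) <- "double"
  if (!is.null(lengths)) {
    if (is.null(names(lengths))) {
      if (length(lengths) != nrow(counts))
        stop("lengths must align 1:1 with gene ids")
      names(lengths) <- rownames(counts)
    }
    if (!setequal(names(lengths), rownames(counts)) ||
        length(lengths) != nrow(counts))
      stop("lengths must align 1:1 with gene ids")
    lengths <- lengths[rownames(counts)]
    if (any(lengths <= 0)) stop("lengths must be positive")
  }
  structure(list(counts = counts, design = design, lengths = lengths),
            class = "count_matrix")
}

#' Validate a sample design table
#'
#' @param design Data frame; see [count_matrix()].
#' @return The validated design with character columns, row names dropped.
#' @export
validate_design <- function(design) {
  req <- c("sample_id", "species", "diel_phase", "activity_niche", "replicate")
  miss <- setdiff(req, names(design))
  if (length(miss)) stop("design is missing column(s): ", paste(miss, collapse = ", "))
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  for (cc in c("sample_id", "species", "diel_phase", "activity_niche"))
    design[[cc]] <- as.character(design[[cc]])
  design$replicate <- as.integer(design$replicate)
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample_id in design: ",
         paste(unique(design$sample_id[duplicated(design$sample_id)]), collapse = ", "))
  if (!all(design$diel_phase %in% c("day", "night")))
    stop("diel_phase must be 'day' or 'night'")
  if (!all(design$activity_niche %in% c("diurnal", "nocturnal")))
    stop("activity_niche must be 'diurnal' or 'nocturnal'")
  if (any(design$replicate < 1)) stop("replicate must be a positive integer")
  for (sp in unique(design$species)) {
    niches <- unique(design$activity_niche[design$species == sp])
    if (length(niches) != 1)
      stop("activity_niche must be constant within species (violated for ", sp, ")")
  }
  rownames(design) <- NULL
  design
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts), "samples\n")
  cat("  species:", paste(unique(x$design$species), collapse = ", "),
      "| phases:", paste(unique(x$design$diel_phase), collapse = ", "), "\n")
  cat("  lengths:", if (is.null(x$lengths)) "absent" else "present", "\n")
  invisible(x)
}

#' Read a count matrix and its sample design from TSV files
#'
#' The counts file has a `gene_id` first column and one column per sample;
#' the design file has columns `sample_id`, `species`, `diel_phase`,
#' `activity_niche`, `replicate`. Sample columns are reordered to match the
#' design order. An optional lengths file maps `gene_id` to `length`.
#'
#' @param path Path to the counts TSV.
#' @param design_path Path to the sample design TSV.
#' @param lengths_path Optional path to a two-column `gene_id`/`length` TSV.
#' @param allow_fractional Passed to [count_matrix()].
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, design_path, lengths_path = NULL,
                        allow_fractional = FALSE) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene_id")
    stop("counts file must have 'gene_id' as its first column")
  dup <- tab$gene_id[duplicated(tab$gene_id)]
  if (length(dup)) {
    line <- which(duplicated(tab$gene_id))[1] + 1L  # +1 for header line
    stop("duplicate gene id '", dup[1], "' at line ", line, " of ", path)
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene_id
  if (!is.numeric(m)) stop("non-numeric count value in ", path)
  if (any(m != floor(m)) && !allow_fractional)
    stop("non-integer count value in ", path,
         "; set allow_fractional = TRUE to round half-to-even")
  design <- read.delim(design_path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
  lengths <- NULL
  if (!is.null(lengths_path)) {
    lt <- read.delim(lengths_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    lengths <- stats::setNames(as.numeric(lt$length), lt$gene_id)
  }
  count_matrix(m, design, lengths = lengths,
               allow_fractional = allow_fractional)
}

#' Write a count matrix and its design to TSV files
#'
#' @param m A [count_matrix()].
#' @param path Output counts TSV path.
#' @param design_path Output design TSV path.
#' @param lengths_path Optional output lengths TSV path.
#' @return Invisibly, `m`.
#' @export
write_counts <- function(m, path, design_path, lengths_path = NULL) {
  tab <- data.frame(gene_id = rownames(m$counts), m$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(m$design, design_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(lengths_path)) {
    if (is.null(m$lengths)) stop("no lengths to write")
    write.table(data.frame(gene_id = names(m$lengths), length = m$lengths),
                lengths_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(m)
}

#' Transcripts-per-million expression values
#'
#' Per sample `s`: `tpm[g, s] = (counts[g, s] / length[g]) /
#' sum_h(counts[h, s] / length[h]) * 1e6`, so each sample column sums to one
#' million.
#'
#' @param m A [count_matrix()] with lengths present.
#' @param zero_sample_policy What to do with an all-zero sample column:
#'   `"error"` (default) or `"zero"` (return an all-zero TPM column).
#' @return Numeric matrix of TPM values, genes x samples.
#' @export
compute_tpm <- function(m, zero_sample_policy = c("error", "zero")) {
  zero_sample_policy <- match.arg(zero_sample_policy)
  if (is.null(m$lengths))
    stop("compute_tpm requires feature lengths")
  rate <- m$counts / m$lengths[rownames(m$counts)]
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    if (zero_sample_policy == "error")
      stop("all-zero sample column(s): ",
           paste(colnames(m$counts)[zero], collapse = ", "))
    tot[zero] <- 1  # yields an all-zero TPM column
  }
  sweep(rate, 2, tot, "/") * 1e6
}

#' Drop genes below a TPM expression floor
#'
#' A gene is retained when its TPM is at or above `tpm_threshold` (inclusive)
#' in at least `min_samples` samples; by default a gene is dropped only when
#' it fails the threshold in every sample, which keeps phase-specific genes
#' expressed in a single condition.
#'
#' @param m A [count_matrix()] with lengths.
#' @param tpm_threshold Positive TPM floor (default 1).
#' @param min_samples Minimum number of samples meeting the floor (default 1).
#' @param zero_sample_policy Passed to [compute_tpm()].
#' @return The filtered [count_matrix()] (row order preserved) with attribute
#'   `"removed_genes"` listing dropped gene ids.
#' @export
filter_low_expression <- function(m, tpm_threshold = 1.0, min_samples = 1,
                                  zero_sample_policy = "error") {
  if (!is.numeric(tpm_threshold) || tpm_threshold <= 0)
    stop("tpm_threshold must be a positive number")
  tpm <- compute_tpm(m, zero_sample_policy = zero_sample_policy)
  keep <- rowSums(tpm >= tpm_threshold) >= min_samples
  removed <- rownames(m$counts)[!keep]
  out <- count_matrix(m$counts[keep, , drop = FALSE], m$design,
                      lengths = if (is.null(m$lengths)) NULL else m$lengths[keep])
  attr(out, "removed_genes") <- removed
  out
}

#' Read a gene-to-GO annotation table
#'
#' @param path TSV with columns `gene_id`, `go_id`, `go_namespace`.
#' @return Data frame with unique `(gene_id, go_id)` pairs.
#' @export
read_go_table <- function(path) {
  go <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  validate_go_table(go)
}

#' @rdname read_go_table
#' @param go Data frame to validate in place of a file.
#' @export
validate_go_table <- function(go) {
  req <- c("gene_id", "go_id", "go_namespace")
  miss <- setdiff(req, names(go))
  if (length(miss)) stop("GO table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(go[, c("gene_id", "go_id")]))
    stop("duplicate (gene_id, go_id) pair in GO table")
  bad <- !grepl("^GO:[0-9]{7}$", go$go_id)
  if (any(bad)) stop("malformed GO id(s): ", paste(unique(go$go_id[bad]), collapse = ", "))
  go
}

#' Read a GO-to-functional-category map
#'
#' Maps GO ids onto the six functional groups used for candidate screening
#' (vision, smell, hearing, circadian, behaviour, brain) plus `other`.
#'
#' @param path TSV with columns `go_id`, `category`.
#' @return Named character vector `go_id -> category`.
#' @export
read_category_map <- function(path) {
  cm <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  validate_category_map(stats::setNames(cm$category, cm$go_id))
}

#' @rdname read_category_map
#' @param category_map Named character vector to validate in place of a file.
#' @export
validate_category_map <- function(category_map) {
  bad <- !grepl("^GO:[0-9]{7}$", names(category_map))
  if (any(bad))
    stop("malformed GO id(s) in category map: ",
         paste(names(category_map)[bad], collapse = ", "))
  allowed <- c(functional_categories(), "other")
  unknown <- setdiff(unique(category_map), allowed)
  if (length(unknown))
    stop("unknown categor(ies): ", paste(unknown, collapse = ", "))
  category_map
}

#' The six screened functional categories
#'
#' @return Character vector of the functional categories used for candidate
#'   gene screening.
#' @export
functional_categories <- function() {
  c("vision", "smell", "hearing", "circadian", "behaviour", "brain")
}
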