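msa_matrix <- function(msa) {
  lens <- nchar(msa)
  if (length(unique(lens)) != 1)
    stop("aligned sequences must all have the same length")
  m <- do.call(rbind, strsplit(toupper(msa), "", fixed = TRUE))
  rownames(m) <- names(msa)
  m
}

#' Per-column conservation profile of a protein alignment
#'
#' Per column, the Shannon entropy `H` (natural log) of the non-gap residue
#' frequencies gives a raw score `(1 - H / ln 20)`, optionally multiplied
#' by `(1 - gap_fraction)`; all-gap columns score 0. The entropy is always
#' normalized by `ln 20` so the scale is fixed across columns. Scores are
#' smoothed with a centered moving mean (window `window`, truncated at the
#' edges) and graded into noniles of the smoothed score (9 = most
#' conserved). When a reference sequence is named, a map from alignment
#' columns to its ungapped positions is included.
#'
#' @param msa Named character vector of aligned sequences (gaps `-`).
#' @param gap_penalty Multiply by the non-gap fraction (default `TRUE`).
#' @param window Smoothing window width (default 5).
#' @param reference_id Optional name of the reference sequence.
#' @return List of class `conservation_profile`: `columns` data frame
#'   (`column`, `raw`, `smoothed`, `gap_fraction`, `grade`,
#'   `reference_position`), `n_sequences`, `reference_id`, and `blocks`
#'   (filled by [find_blocks()]).
#' @export
column_conservation <- function(msa, gap_penalty = TRUE, window = 5,
                                reference_id = NULL) {
  if (length(msa) < 3)
    stop("conservation is undefined for fewer than 3 sequences")
  m <- msa_matrix(msa)
  nseq <- nrow(m); L <- ncol(m)
  gapfrac <- colMeans(m == "-")
  raw <- numeric(L)
  for (j in seq_len(L)) {
    res <- m[, j]
    res <- res[res != "-"]
    if (!length(res)) { raw[j] <- 0; next }
    f <- table(res) / length(res)
    H <- -sum(f * log(f))
    raw[j] <- (1 - H / log(20)) * (if (gap_penalty) 1 - gapfrac[j] else 1)
  }
  half <- (window - 1) %/% 2
  smoothed <- vapply(seq_len(L), function(j) {
    mean(raw[max(1, j - half):min(L, j + half)])
  }, 0)
  grade <- pmin(9L, pmax(1L, ceiling(9 * rank(smoothed, ties.method = "min") / L)))
  refpos <- rep(NA_integer_, L)
  if (!is.null(reference_id)) {
    if (!reference_id %in% rownames(m))
      stop("reference sequence '", reference_id, "' is not in the alignment")
    nong <- m[reference_id, ] != "-"
    refpos[nong] <- cumsum(nong)[nong]
  }
  structure(list(columns = data.frame(column = seq_len(L), raw = raw,
                                      smoothed = smoothed,
                                      gap_fraction = gapfrac, grade = grade,
                                      reference_position = refpos),
                 n_sequences = nseq, reference_id = reference_id,
                 blocks = NULL),
            class = "conservation_profile")
}

#' Detect conserved blocks in a conservation profile
#'
#' Maximal runs of at least `min_block` consecutive columns whose smoothed
#' conservation score is at or above `tau`. Intervals are 1-based and
#' inclusive.
#'
#' @param profile A `conservation_profile` from [column_conservation()].
#' @param tau Smoothed-score threshold (default 0.8).
#' @param min_block Minimum block length in columns (default 30).
#' @return Data frame with `start`, `end`, `length`, `mean_score`; also
#'   stored on the returned profile when assigned back.
#' @export
find_blocks <- function(profile, tau = 0.8, min_block = 30) {
  s <- profile$columns$smoothed >= tau
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_block
  blocks <- data.frame(start = as.integer(starts[keep]),
                       end = as.integer(ends[keep]))
  blocks$length <- blocks$end - blocks$start + 1
  blocks$mean_score <- vapply(seq_len(nrow(blocks)), function(i)
    mean(profile$columns$smoothed[blocks$start[i]:blocks$end[i]]), 0)
  rownames(blocks) <- NULL
  blocks
}

in_any_block <- function(cols, blocks) {
  if (is.null(blocks) || !nrow(blocks)) return(rep(FALSE, length(cols)))
  vapply(cols, function(j) any(j >= blocks$start & j <= blocks$end), TRUE)
}

#' Mutations between two focal sequences and their conserved-block overlap
#'
#' Mutated columns are those where both focal residues are non-gap and
#' differ; columns where exactly one focal residue is a gap are reported
#' separately as indel sites. Each mutation is annotated with the
#' reference position (via the profile's column map), its conservation
#' grade, and whether it falls inside a conserved block.
#'
#' @param msa Named character vector of aligned sequences.
#' @param focal_a,focal_b Names of the two focal sequences.
#' @param profile `conservation_profile` for the alignment.
#' @param blocks Block table from [find_blocks()].
#' @return List with `mutations` (data frame: `column`, `residue_a`,
#'   `residue_b`, `reference_position`, `in_block`, `grade`), `n_total`,
#'   `n_in_block`, and `indel_sites` (columns with a gap in exactly one
#'   focal sequence).
#' @export
focal_mutations <- function(msa, focal_a, focal_b, profile, blocks = NULL) {
  m <- msa_matrix(msa)
  for (id in c(focal_a, focal_b))
    if (!id %in% rownames(m))
      stop("focal sequence '", id, "' is not in the alignment")
  a <- m[focal_a, ]; b <- m[focal_b, ]
  mut <- which(a != "-" & b != "-" & a != b)
  indel <- which(xor(a == "-", b == "-"))
  inb <- in_any_block(mut, blocks)
  mutations <- data.frame(column = mut, residue_a = a[mut],
                          residue_b = b[mut],
                          reference_position =
                            profile$columns$reference_position[mut],
                          in_block = inb,
                          grade = profile$columns$grade[mut],
                          stringsAsFactors = FALSE)
  rownames(mutations) <- NULL
  list(mutations = mutations, n_total = length(mut),
       n_in_block = sum(inb), indel_sites = indel,
       focal_a = focal_a, focal_b = focal_b)
}

#' Shared versus lineage-specific conserved blocks between two orthologs
#'
#' Maps each conserved block onto the ungapped coordinates of a reference
#' and a second (often shorter) ortholog. A block is `shared` when at least
#' `cover_frac` of its columns are non-gap in both sequences and
#' `lineage_specific` when it is covered in the reference but mostly
#' gapped in the other sequence — the signature of a conserved region
#' absent from the shorter ortholog.
#'
#' @param msa Named character vector of aligned sequences.
#' @param ref_id,other_id Names of the two sequences to compare.
#' @param blocks Block table from [find_blocks()].
#' @param cover_frac Minimum non-gap fraction for a block to count as
#'   covered (default 0.5).
#' @return Data frame per block with coverage fractions, ungapped spans in
#'   each sequence, and `status` in
#'   `{shared, lineage_specific, uncovered}`.
#' @export
compare_ortholog_lengths <- function(msa, ref_id, other_id, blocks,
                                     cover_frac = 0.5) {
  m <- msa_matrix(msa)
  for (id in c(ref_id, other_id))
    if (!id %in% rownames(m))
      stop("sequence '", id, "' is not in the alignment")
  ungapped <- function(seqrow) {
    nong <- seqrow != "-"
    pos <- rep(NA_integer_, length(seqrow))
    pos[nong] <- cumsum(nong)[nong]
    pos
  }
  pr <- ungapped(m[ref_id, ]); po <- ungapped(m[other_id, ])
  out <- lapply(seq_len(nrow(blocks)), function(i) {
    cols <- blocks$start[i]:blocks$end[i]
    cov_r <- mean(!is.na(pr[cols])); cov_o <- mean(!is.na(po[cols]))
    status <- if (cov_r >= cover_frac && cov_o >= cover_frac) "shared"
    else if (cov_r >= cover_frac) "lineage_specific"
    else "uncovered"
    data.frame(start = blocks$start[i], end = blocks$end[i],
               cover_ref = cov_r, cover_other = cov_o,
               ref_from = suppressWarnings(min(pr[cols], na.rm = TRUE)),
               ref_to = suppressWarnings(max(pr[cols], na.rm = TRUE)),
               other_from = suppressWarnings(min(po[cols], na.rm = TRUE)),
               other_to = suppressWarnings(max(po[cols], na.rm = TRUE)),
               status = status, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$ref_from[!is.finite(res$ref_from)] <- NA
  res$ref_to[!is.finite(res$ref_to)] <- NA
  res$other_from[!is.finite(res$other_from)] <- NA
  res$other_to[!is.finite(res$other_to)] <- NA
  rownames(res) <- NULL
  res
}
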