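blosum62_env <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(blosum62_env$mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum62_env$mat <- e$BLOSUM62
  }
  blosum62_env$mat
}

sw_batch <- function(a, b, gap_open = 11, gap_ext = 1) {
  S <- blosum62()
  sw_batch_cpp(as.character(a), as.character(b), S, rownames(S),
               gap_open, gap_ext)
}

#' Smith-Waterman local alignment score and identity
#'
#' Local alignment with BLOSUM62 and affine gap costs (a gap of length `k`
#' costs `gap_open + k * gap_ext`). Identity is the number of identical
#' residues divided by the number of aligned columns (gap columns
#' included).
#'
#' @param a,b Protein sequences (character scalars).
#' @param gap_open,gap_ext Gap opening and per-residue extension penalties
#'   (defaults 11 and 1).
#' @return List with `score` and `identity`.
#' @export
pairwise_score <- function(a, b, gap_open = 11, gap_ext = 1) {
  r <- sw_batch(a, b, gap_open, gap_ext)
  list(score = unname(r[1, "score"]),
       identity = if (r[1, "columns"] > 0) unname(r[1, "matches"] / r[1, "columns"]) else 0)
}

# unique k-mers per sequence as (id, kmer) pairs
kmer_pairs <- function(seqs, k) {
  lens <- nchar(seqs)
  nk <- pmax(lens - k + 1L, 0L)
  id <- rep.int(seq_along(seqs), nk)
  start <- sequence(nk)
  km <- substring(rep.int(unname(seqs), nk), start, start + k - 1L)
  keep <- !duplicated(paste0(id, "\r", km))
  list(id = id[keep], km = km[keep])
}

# candidate (a, b) index pairs sharing at least `min_shared` k-mers
candidate_pairs <- function(A, B, k = 5, min_shared = 3) {
  ta <- kmer_pairs(A, k)
  tb <- kmer_pairs(B, k)
  by_km <- split(tb$id, tb$km)
  idx <- match(ta$km, names(by_km))
  hit <- which(!is.na(idx))
  if (!length(hit)) return(cbind(a = integer(0), b = integer(0)))
  bl <- by_km[idx[hit]]
  pa <- rep.int(ta$id[hit], lengths(bl))
  pb <- unlist(bl, use.names = FALSE)
  key <- pa * (length(B) + 1) + pb
  o <- order(key)
  r <- rle(key[o])
  keep <- r$values[r$lengths >= min_shared]
  if (!length(keep)) return(cbind(a = integer(0), b = integer(0)))
  cbind(a = as.integer(keep %/% (length(B) + 1)),
        b = as.integer(keep %% (length(B) + 1)))
}

# score all (a_idx, b_idx) pairs; returns data frame with ids
score_pairs <- function(A, B, pairs, gap_open = 11, gap_ext = 1) {
  if (!nrow(pairs))
    return(data.frame(a = character(0), b = character(0),
                      score = numeric(0), identity = numeric(0),
                      stringsAsFactors = FALSE))
  r <- sw_batch(A[pairs[, 1]], B[pairs[, 2]], gap_open, gap_ext)
  data.frame(a = names(A)[pairs[, 1]], b = names(B)[pairs[, 2]],
             score = r[, "score"],
             identity = ifelse(r[, "columns"] > 0,
                               r[, "matches"] / r[, "columns"], 0),
             stringsAsFactors = FALSE)
}

# all scored pairs between two proteomes, exhaustive or k-mer prescreened
all_scores <- function(A, B, prescreen = c("auto", "none", "kmer"),
                       exhaustive_limit = 40000) {
  prescreen <- match.arg(prescreen)
  if (prescreen == "auto")
    prescreen <- if (length(A) * length(B) <= exhaustive_limit) "none" else "kmer"
  pairs <- if (prescreen == "none")
    as.matrix(expand.grid(a = seq_along(A), b = seq_along(B)))
  else candidate_pairs(A, B)
  score_pairs(A, B, pairs)
}

# deterministic best hit per query: max score, ties by identity then id
best_per <- function(scores, query_col, hit_col) {
  if (!nrow(scores))
    return(scores[, c(query_col, hit_col, "score", "identity")])
  o <- order(scores[[query_col]], -scores$score, -scores$identity,
             scores[[hit_col]])
  s <- scores[o, ]
  s[!duplicated(s[[query_col]]), c(query_col, hit_col, "score", "identity")]
}

#' Reciprocal best hits between two proteomes
#'
#' A pair `(a, b)` is reported when `b` is `a`'s top-scoring hit in `B` and
#' `a` is `b`'s top-scoring hit in `A` under Smith-Waterman/BLOSUM62 scores;
#' score ties are broken deterministically by higher identity, then
#' lexicographically smaller id. For large proteomes an exact shared-k-mer
#' prescreen restricts which pairs are aligned; sequences sharing too few
#' k-mers with everything are left unpaired.
#'
#' @param A,B Named character vectors of protein sequences.
#' @param prescreen `"auto"` (default; exhaustive below
#'   `exhaustive_limit` pairwise comparisons, k-mer prescreen above),
#'   `"none"`, or `"kmer"`.
#' @param exhaustive_limit Pair-count threshold for the auto switch.
#' @return Data frame with columns `a`, `b`, `score`, `identity`.
#' @export
reciprocal_best_hits <- function(A, B, prescreen = "auto",
                                 exhaustive_limit = 40000) {
  if (!length(A) || !length(B)) {
    warning("empty proteome; no reciprocal best hits")
    return(data.frame(a = character(0), b = character(0),
                      score = numeric(0), identity = numeric(0),
                      stringsAsFactors = FALSE))
  }
  sc <- all_scores(A, B, prescreen, exhaustive_limit)
  sc <- sc[sc$score > 0, , drop = FALSE]
  ba <- best_per(sc, "a", "b")
  bb <- best_per(sc, "b", "a")
  key_ab <- paste0(ba$a, "\r", ba$b)
  key_ba <- paste0(bb$a, "\r", bb$b)
  keep <- key_ab %in% key_ba
  out <- ba[keep, , drop = FALSE]
  out <- out[order(out$a), ]
  rownames(out) <- NULL
  out
}

# union-find over character node ids
uf_new <- function() new.env(parent = emptyenv())
uf_find <- function(uf, x) {
  r <- x
  while (!is.null(p <- uf[[r]]) && p != r) r <- p
  if (is.null(uf[[r]])) uf[[r]] <- r
  while (uf[[x]] != r) { nx <- uf[[x]]; uf[[x]] <- r; x <- nx }
  r
}
uf_union <- function(uf, x, y) {
  rx <- uf_find(uf, x); ry <- uf_find(uf, y)
  if (rx != ry) uf[[ry]] <- rx
  invisible(NULL)
}

#' Build reference-anchored orthogroups from proteomes
#'
#' Computes reciprocal best hits between each species proteome and the
#' reference, and between every pair of species proteomes; connected
#' components of the resulting graph that contain exactly one reference
#' gene become orthogroups, components with several reference genes are
#' split by assigning each member to its best-scoring reference (logged),
#' and reference-free components are retained as direct cross-species
#' pairwise links. One representative per species per group is selected
#' with [select_representative()].
#'
#' @param ref Named character vector: the reference proteome.
#' @param species_proteomes Named list of species proteomes.
#' @param prescreen,exhaustive_limit Passed to [reciprocal_best_hits()].
#' @param tie_tol,order Passed to [select_representative()].
#' @return List with `groups` (long data frame: group_id, reference_gene,
#'   species, transcript_id, identity, length, is_representative), `map`
#'   (species, transcript_id, reference_gene), and `pairwise_links`
#'   (reference-free cross-species transcript pairs).
#' @export
build_orthogroups <- function(ref, species_proteomes, prescreen = "auto",
                              exhaustive_limit = 40000, tie_tol = 0.01,
                              order = c("similarity", "length")) {
  order <- match.arg(order)
  spp <- names(species_proteomes)
  uf <- uf_new()
  node <- function(kind, sp, id) paste0(kind, "\r", sp, "\r", id)
  edges <- list()
  for (sp in spp) {
    rb <- reciprocal_best_hits(species_proteomes[[sp]], ref, prescreen,
                               exhaustive_limit)
    if (nrow(rb))
      edges[[paste0(sp, ":ref")]] <-
        data.frame(n1 = node("t", sp, rb$a), n2 = node("r", "", rb$b),
                   stringsAsFactors = FALSE)
  }
  if (length(spp) > 1) {
    for (i in seq_len(length(spp) - 1)) for (j in (i + 1):length(spp)) {
      rb <- reciprocal_best_hits(species_proteomes[[spp[i]]],
                                 species_proteomes[[spp[j]]],
                                 prescreen, exhaustive_limit)
      if (nrow(rb))
        edges[[paste0(spp[i], ":", spp[j])]] <-
          data.frame(n1 = node("t", spp[i], rb$a),
                     n2 = node("t", spp[j], rb$b),
                     score = rb$score, identity = rb$identity,
                     stringsAsFactors = FALSE)
    }
  }
  for (e in edges) for (k in seq_len(nrow(e))) uf_union(uf, e$n1[k], e$n2[k])

  nodes <- unique(unlist(lapply(edges, function(e) c(e$n1, e$n2))))
  if (is.null(nodes)) nodes <- character(0)
  comp <- vapply(nodes, function(x) uf_find(uf, x), "")
  parts <- if (length(nodes)) do.call(rbind, strsplit(nodes, "\r", fixed = TRUE))
  else matrix(character(0), 0, 3)
  info <- data.frame(node = nodes, comp = unname(comp),
                     kind = parts[, 1], species = parts[, 2], id = parts[, 3],
                     stringsAsFactors = FALSE)
  comp_of <- stats::setNames(info$comp, info$node)
  nrefs <- table(factor(info$comp[info$kind == "r"],
                        levels = unique(info$comp)))

  # reference-free components: their cross-species RBH edges become links
  links <- list()
  for (e in edges) {
    if (!all(c("score", "identity") %in% names(e))) next
    inn <- nrefs[comp_of[e$n1]] == 0
    if (any(inn)) {
      p1 <- do.call(rbind, strsplit(e$n1[inn], "\r", fixed = TRUE))
      p2 <- do.call(rbind, strsplit(e$n2[inn], "\r", fixed = TRUE))
      links[[length(links) + 1]] <-
        data.frame(species_a = p1[, 2], transcript_a = p1[, 3],
                   species_b = p2[, 2], transcript_b = p2[, 3],
                   score = e$score[inn], identity = e$identity[inn],
                   stringsAsFactors = FALSE)
    }
  }

  # reference-anchored components: assign every member transcript to a
  # reference gene (unique within component, or best-scoring on collision)
  split_log <- character(0)
  memb <- info[info$kind == "t" & nrefs[info$comp] > 0, , drop = FALSE]
  ref_by_comp <- split(info$id[info$kind == "r"], info$comp[info$kind == "r"])
  single_ref <- vapply(ref_by_comp, function(r) length(r) == 1, TRUE)
  assign_ref <- rep(NA_character_, nrow(memb))
  is_single <- single_ref[memb$comp]
  assign_ref[is_single] <- vapply(ref_by_comp[memb$comp[is_single]], `[`, "", 1)
  multi <- which(!is_single)
  if (length(multi)) {
    for (i in multi) {
      refs <- sort(ref_by_comp[[memb$comp[i]]])
      mseq <- species_proteomes[[memb$species[i]]][[memb$id[i]]]
      sc <- sw_batch(rep(mseq, length(refs)), ref[refs])
      assign_ref[i] <- refs[order(-sc[, "score"], refs)[1]]
    }
    for (cc in unique(memb$comp[multi]))
      split_log <- c(split_log,
                     paste0("component with references ",
                            paste(sort(ref_by_comp[[cc]]), collapse = "+"),
                            " split by best-hit assignment"))
  }
  if (nrow(memb)) {
    mseqs <- vapply(seq_len(nrow(memb)), function(i)
      species_proteomes[[memb$species[i]]][[memb$id[i]]], "")
    sc <- sw_batch(mseqs, unname(ref[assign_ref]))
    groups <- data.frame(reference_gene = assign_ref,
                         species = memb$species,
                         transcript_id = memb$id,
                         identity = ifelse(sc[, "columns"] > 0,
                                           sc[, "matches"] / sc[, "columns"],
                                           0),
                         length = nchar(mseqs), stringsAsFactors = FALSE)
  } else {
    groups <- data.frame(reference_gene = character(0),
                         species = character(0),
                         transcript_id = character(0), identity = numeric(0),
                         length = integer(0), stringsAsFactors = FALSE)
  }
  groups <- groups[order(groups$reference_gene, groups$species,
                         groups$transcript_id), , drop = FALSE]
  groups$group_id <- paste0("OG_", groups$reference_gene)
  groups$is_representative <- FALSE
  if (nrow(groups)) {
    key <- paste0(groups$group_id, "\r", groups$species)
    if (order == "similarity") {
      maxid <- tapply(groups$identity, key, max)
      cand <- which(groups$identity >= maxid[key] - tie_tol)
      o <- cand[base::order(key[cand], -groups$length[cand],
                            groups$transcript_id[cand])]
    } else {
      maxlen <- tapply(groups$length, key, max)
      cand <- which(groups$length == maxlen[key])
      o <- cand[base::order(key[cand], -groups$identity[cand],
                            groups$transcript_id[cand])]
    }
    groups$is_representative[o[!duplicated(key[o])]] <- TRUE
  }
  rownames(groups) <- NULL
  links <- if (length(links)) unique(do.call(rbind, links))
  else data.frame(species_a = character(0), transcript_a = character(0),
                  species_b = character(0), transcript_b = character(0),
                  score = numeric(0), identity = numeric(0),
                  stringsAsFactors = FALSE)
  rownames(links) <- NULL
  map <- groups[, c("species", "transcript_id", "reference_gene")]
  rownames(map) <- NULL
  if (length(split_log)) message(paste(split_log, collapse = "\n"))
  list(groups = groups[, c("group_id", "reference_gene", "species",
                           "transcript_id", "identity", "length",
                           "is_representative")],
       map = map, pairwise_links = links, split_log = split_log)
}

#' Select one representative transcript per species in an orthogroup
#'
#' Default order (`"similarity"`): maximize identity to the reference;
#' members within `tie_tol` of the best identity are tied and the longest
#' wins; remaining ties go to the lexicographically smallest id. With
#' `order = "length"` the precedence is reversed (longest first, identity
#' as tie-break).
#'
#' @param g Data frame of group members with columns `species`,
#'   `transcript_id`, `identity`, `length`.
#' @param tie_tol Identity tolerance within which members count as tied
#'   (default 0.01).
#' @param order Ranking precedence, `"similarity"` (default) or
#'   `"length"`.
#' @return Character vector of selected transcript ids (one per species).
#' @export
select_representative <- function(g, tie_tol = 0.01,
                                  order = c("similarity", "length")) {
  order <- match.arg(order)
  out <- character(0)
  for (sp in sort(unique(g$species))) {
    m <- g[g$species == sp, , drop = FALSE]
    if (order == "similarity") {
      cand <- m[m$identity >= max(m$identity) - tie_tol, , drop = FALSE]
      cand <- cand[cand$length == max(cand$length), , drop = FALSE]
    } else {
      cand <- m[m$length == max(m$length), , drop = FALSE]
      cand <- cand[cand$identity == max(cand$identity), , drop = FALSE]
    }
    out <- c(out, sort(cand$transcript_id)[1])
  }
  out
}
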