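#' Collapse transcript-level DE results onto reference genes
#'
#' Attaches each transcript's result to its reference-anchored ortholog;
#' when several transcripts of one species map to the same reference gene,
#' the record with the smallest adjusted p-value is kept (ties: largest
#' |log2FC|, then lexicographically smallest transcript id). With
#' `collapse = "any"` a gene is additionally flagged when ANY of its
#' transcripts is significant, which preserves isoform-level signals.
#'
#' @param de DE result data frame for one species (transcript-level
#'   `gene_id`s).
#' @param map Data frame with columns `transcript_id`, `reference_gene`
#'   (optionally `species`).
#' @param species Optional species label used to subset `map`.
#' @param collapse `"best"` (default) or `"any"`.
#' @return Data frame keyed by `reference_gene` carrying the representative
#'   transcript's statistics plus `n_transcripts` and (for `"any"`)
#'   `any_significant`; attributes `n_unmapped` (transcripts with no
#'   reference hit) and `multiplicity` (transcript-per-gene table).
#' @export
collapse_to_reference <- function(de, map, species = NULL,
                                  collapse = c("best", "any")) {
  collapse <- match.arg(collapse)
  if (!is.null(species) && "species" %in% names(map))
    map <- map[map$species == species, , drop = FALSE]
  ref <- map$reference_gene[match(de$gene_id, map$transcript_id)]
  unmapped <- sum(is.na(ref))
  d <- de[!is.na(ref), , drop = FALSE]
  d$reference_gene <- ref[!is.na(ref)]
  o <- order(d$reference_gene, d$adj_p, -abs(d$log2fc), d$gene_id)
  d <- d[o, , drop = FALSE]
  first <- !duplicated(d$reference_gene)
  out <- d[first, , drop = FALSE]
  mult <- table(d$reference_gene)
  out$n_transcripts <- as.integer(mult[out$reference_gene])
  if (collapse == "any") {
    anysig <- tapply(d$significant, d$reference_gene, any)
    out$any_significant <- as.logical(anysig[out$reference_gene])
  }
  names(out)[names(out) == "gene_id"] <- "transcript_id"
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- unmapped
  attr(out, "n_mapped") <- nrow(d)
  attr(out, "multiplicity") <- mult
  out
}

#' Join two species' collapsed DE tables on the reference gene
#'
#' @param coll Named list of two collapsed tables from
#'   [collapse_to_reference()], names are species labels.
#' @return Wide data frame with per-species `log2fc_`, `adj_p_`,
#'   `significant_` columns over the union of reference genes.
#' @export
cross_species_table <- function(coll) {
  stopifnot(length(coll) == 2, !is.null(names(coll)))
  spp <- names(coll)
  genes <- sort(unique(c(coll[[1]]$reference_gene, coll[[2]]$reference_gene)))
  out <- data.frame(reference_gene = genes, stringsAsFactors = FALSE)
  for (sp in spp) {
    i <- match(genes, coll[[sp]]$reference_gene)
    out[[paste0("log2fc_", sp)]] <- coll[[sp]]$log2fc[i]
    out[[paste0("adj_p_", sp)]] <- coll[[sp]]$adj_p[i]
    out[[paste0("significant_", sp)]] <-
      ifelse(is.na(i), FALSE, coll[[sp]]$significant[i])
  }
  out
}

#' Classify cross-species day-night expression patterns
#'
#' Both species significant with the same fold-change sign gives
#' `concordant_night` (both positive) or `concordant_day` (both negative);
#' opposite signs give `flipped`; significance in exactly one species with
#' `|log2FC| >= strong_lfc` gives `single_species_strong`; anything else is
#' `not_shared`.
#'
#' @param tbl Wide table from [cross_species_table()].
#' @param species The two species labels (defaults to those in `tbl`).
#' @param strong_lfc Threshold for a strong single-species signal
#'   (default 5, the FC >= 5 / <= -5 stratum).
#' @return `tbl` with a `pattern` column appended.
#' @export
classify_pattern <- function(tbl, species = NULL, strong_lfc = 5.0) {
  if (is.null(species))
    species <- sub("^log2fc_", "", grep("^log2fc_", names(tbl), value = TRUE))
  stopifnot(length(species) == 2)
  l1 <- tbl[[paste0("log2fc_", species[1])]]
  l2 <- tbl[[paste0("log2fc_", species[2])]]
  s1 <- tbl[[paste0("significant_", species[1])]]
  s2 <- tbl[[paste0("significant_", species[2])]]
  pat <- rep("not_shared", nrow(tbl))
  both <- s1 & s2 & !is.na(l1) & !is.na(l2)
  pat[both & sign(l1) > 0 & sign(l2) > 0] <- "concordant_night"
  pat[both & sign(l1) < 0 & sign(l2) < 0] <- "concordant_day"
  pat[both & sign(l1) * sign(l2) < 0] <- "flipped"
  one1 <- s1 & !s2 & !is.na(l1) & abs(l1) >= strong_lfc
  one2 <- s2 & !s1 & !is.na(l2) & abs(l2) >= strong_lfc
  pat[one1 | one2] <- "single_species_strong"
  tbl$pattern <- pat
  tbl
}

#' Diel coincidence of a cross-species expression pattern
#'
#' A record is diel-coincident when each species' fold change matches its
#' activity phase: negative (day-overexpressed) in the diurnal species and
#' positive (night-overexpressed) in the nocturnal species. Records with a
#' missing or zero fold change in either species are not coincident and are
#' annotated `"undefined"`.
#'
#' @param tbl Table with `log2fc_<species>` columns (and optionally
#'   `pattern`).
#' @param niches Named character vector, species -> `"diurnal"`/
#'   `"nocturnal"`.
#' @return `tbl` with `diel_coincident` (logical) and `coincidence_note`
#'   columns appended.
#' @export
diel_coincidence <- function(tbl, niches) {
  spp <- names(niches)
  stopifnot(length(spp) == 2, all(c("diurnal", "nocturnal") %in% niches))
  di <- spp[niches == "diurnal"][1]
  no <- spp[niches == "nocturnal"][1]
  ld <- tbl[[paste0("log2fc_", di)]]
  ln <- tbl[[paste0("log2fc_", no)]]
  undef <- is.na(ld) | is.na(ln) | ld == 0 | ln == 0
  tbl$diel_coincident <- !undef & ld < 0 & ln > 0
  tbl$coincidence_note <- ifelse(undef, "undefined", "")
  tbl
}

#' Flip records from direct differentially-expressed ortholog pairs
#'
#' For every direct cross-species transcript pair (reference-free links
#' from [build_orthogroups()]) in which both transcripts are significant,
#' emits a record without requiring a reference-gene anchor, then unions it
#' with the reference-collapse records, de-duplicating by reference gene
#' where both transcripts map to the same one.
#'
#' @param deA,deB Transcript-level DE results for the two species.
#' @param links Pairwise-link data frame (`transcript_a`, `transcript_b`,
#'   `species_a`, `species_b`).
#' @param map Optional transcript -> reference map used for de-duplication.
#' @param reference_records Optional records from the reference collapse
#'   (with a `source` column) to union with.
#' @param species Species labels `c(A, B)` for the output columns.
#' @return Data frame of records with `source` in
#'   `{reference_collapse, ortholog_pair, both}`.
#' @export
ortholog_pair_de <- function(deA, deB, links, map = NULL,
                             reference_records = NULL, species = c("A", "B")) {
  ia <- match(links$transcript_a, deA$gene_id)
  ib <- match(links$transcript_b, deB$gene_id)
  ok <- !is.na(ia) & !is.na(ib) & deA$significant[ia] & deB$significant[ib]
  rec <- data.frame(record_id = if (any(ok))
    paste0(links$transcript_a[ok], "|", links$transcript_b[ok])
    else character(0),
    reference_gene = rep(NA_character_, sum(ok)),
    stringsAsFactors = FALSE)
  rec[[paste0("log2fc_", species[1])]] <- deA$log2fc[ia][ok]
  rec[[paste0("adj_p_", species[1])]] <- deA$adj_p[ia][ok]
  rec[[paste0("significant_", species[1])]] <- rep(TRUE, sum(ok))
  rec[[paste0("log2fc_", species[2])]] <- deB$log2fc[ib][ok]
  rec[[paste0("adj_p_", species[2])]] <- deB$adj_p[ib][ok]
  rec[[paste0("significant_", species[2])]] <- rep(TRUE, sum(ok))
  rec$source <- rep("ortholog_pair", sum(ok))
  if (!is.null(map)) {
    ra <- map$reference_gene[match(links$transcript_a[ok], map$transcript_id)]
    rb <- map$reference_gene[match(links$transcript_b[ok], map$transcript_id)]
    same <- !is.na(ra) & !is.na(rb) & ra == rb
    rec$reference_gene[same] <- ra[same]
  }
  if (is.null(reference_records)) return(rec)
  rr <- reference_records
  if (!"record_id" %in% names(rr)) rr$record_id <- rr$reference_gene
  if (!"source" %in% names(rr)) rr$source <- "reference_collapse"
  dupe <- !is.na(rec$reference_gene) &
    rec$reference_gene %in% rr$reference_gene
  rr$source[rr$reference_gene %in% rec$reference_gene[dupe]] <- "both"
  common <- intersect(names(rr), names(rec))
  out <- rbind(rr[, common, drop = FALSE],
               rec[!dupe, common, drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Score and rank diel-niche candidate genes
#'
#' Evaluates the three candidate criteria per record: (i) significant
#' differential expression in both species, (ii) diel coincidence of the
#' fold-change directions with each species' activity phase, and (iii) a
#' GO annotation in one of the screened functional categories (vision,
#' smell, hearing, circadian, behaviour, brain). The score is the number of
#' criteria met; records are ranked by score (descending) then by the
#' smaller of the two adjusted p-values (ascending), with the reference
#' gene id as a deterministic final tie-break. The full ranked table is
#' returned, not only the top hits.
#'
#' @param records Flip-record table (from [classify_pattern()] +
#'   [diel_coincidence()], optionally unioned with ortholog-pair records).
#' @param go GO annotation table (gene_id = reference gene).
#' @param category_map Named character vector go_id -> category.
#' @return `records` sorted with `de_in_both`, `functional_hit`,
#'   `categories`, `score`, `min_adj_p` columns appended.
#' @export
rank_candidates <- function(records, go, category_map) {
  spp <- sub("^log2fc_", "", grep("^log2fc_", names(records), value = TRUE))
  s1 <- records[[paste0("significant_", spp[1])]]
  s2 <- records[[paste0("significant_", spp[2])]]
  records$de_in_both <- s1 & s2
  cats <- tag_functional_categories(records$reference_gene, go, category_map)
  hit <- vapply(cats, function(x) any(x %in% functional_categories()), TRUE)
  hit[is.na(records$reference_gene)] <- FALSE
  records$functional_hit <- hit
  records$categories <- vapply(cats, paste, "", collapse = ",")
  records$score <- as.integer(records$de_in_both) +
    as.integer(records$diel_coincident) + as.integer(records$functional_hit)
  records$min_adj_p <- pmin(records[[paste0("adj_p_", spp[1])]],
                            records[[paste0("adj_p_", spp[2])]], na.rm = TRUE)
  key <- if ("record_id" %in% names(records)) records$record_id
  else records$reference_gene
  o <- order(-records$score, records$min_adj_p, key)
  out <- records[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
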