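mk_de <- function(ids, lfc, adj_p, sig = NULL) {
  data.frame(gene_id = ids, log2fc = lfc, mean_expr = 10,
             p = adj_p / 2, adj_p = adj_p, method = "wald",
             significant = sig %||% (adj_p < 0.05 & abs(lfc) >= 2),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("reference collapse keeps the best transcript and tallies", {
  map <- data.frame(species = "AN",
                    transcript_id = c("t1", "t2", "t3", "t4", "t5", "t6"),
                    reference_gene = c("G1", "G1", "G2", "G2", "G3", "G3"))
  de <- mk_de(c("t1", "t2", "t3", "t4", "t5", "t6", "t9"),
              lfc = c(3, -5, 2.5, 2.5, 1, 1, 4),
              adj_p = c(0.01, 0.04, 0.02, 0.02, 0.5, 0.5, 0.001))
  coll <- collapse_to_reference(de, map, species = "AN")
  expect_identical(coll$reference_gene, c("G1", "G2", "G3"))
  # smallest adj_p wins (G1 -> t1); adj_p tie: equal |lfc| -> smaller id
  expect_identical(coll$transcript_id, c("t1", "t3", "t5"))
  expect_identical(unname(coll$n_transcripts), c(2L, 2L, 2L))
  expect_identical(attr(coll, "n_unmapped"), 1L)
  # adj_p tie broken by larger |lfc| before id
  de2 <- mk_de(c("t1", "t2"), lfc = c(2, -6), adj_p = c(0.03, 0.03))
  coll2 <- collapse_to_reference(de2, map, species = "AN")
  expect_identical(coll2$transcript_id, "t2")
  # collapse = "any" exposes isoform-level significance
  coll3 <- collapse_to_reference(de, map, species = "AN", collapse = "any")
  expect_identical(unname(coll3$any_significant), c(TRUE, TRUE, FALSE))
})

test_that("pattern classification covers flips, concordance and strength", {
  tbl <- data.frame(reference_gene = paste0("G", 1:6),
                    log2fc_AN = c(-3.1, 3, 2.2, -6, -1, NA),
                    adj_p_AN = c(0.01, 0.01, 0.01, 0.01, 0.8, NA),
                    significant_AN = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
                    log2fc_DR = c(2.6, 4, 2.0, NA, 2.4, 3),
                    adj_p_DR = c(0.01, 0.01, 0.01, NA, 0.01, 0.01),
                    significant_DR = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  out <- classify_pattern(tbl)
  expect_identical(out$pattern,
                   c("flipped", "concordant_night", "concordant_night",
                     "single_species_strong", "not_shared", "not_shared"))
  # concordant negatives
  neg <- tbl[1, ]
  neg$log2fc_AN <- -3; neg$log2fc_DR <- -2.5
  expect_identical(classify_pattern(neg)$pattern, "concordant_day")
  # swapping the species labels maps day <-> night and preserves flips
  swapped <- tbl
  names(swapped) <- sub("_AN$", "_XX", names(swapped))
  names(swapped) <- sub("_DR$", "_AN", names(swapped))
  names(swapped) <- sub("_XX$", "_DR", names(swapped))
  out2 <- classify_pattern(swapped, species = c("AN", "DR"))
  expect_identical(out2$pattern[1], "flipped")
  expect_identical(out2$pattern[2], "concordant_night")
})

test_that("diel coincidence follows the activity-phase sign rule", {
  niches <- c(AN = "diurnal", DR = "nocturnal")
  tbl <- data.frame(log2fc_AN = c(-3, 3, -3, 0),
                    log2fc_DR = c(3, -3, -2, 3))
  out <- diel_coincidence(tbl, niches)
  expect_identical(out$diel_coincident, c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(out$coincidence_note, c("", "", "", "undefined"))
  # invariant under consistent relabeling of species and niche
  rev_tbl <- data.frame(log2fc_DR = tbl$log2fc_AN,
                        log2fc_AN = tbl$log2fc_DR)
  out2 <- diel_coincidence(rev_tbl, c(DR = "diurnal", AN = "nocturnal"))
  expect_identical(out2$diel_coincident, out$diel_coincident)
})

test_that("ortholog-pair records merge with the reference collapse", {
  links <- data.frame(species_a = "AN", transcript_a = c("t1", "t7"),
                      species_b = "DR", transcript_b = c("u1", "u7"))
  deA <- mk_de(c("t1", "t7"), c(-4, -3), c(0.01, 0.01))
  deB <- mk_de(c("u1", "u7"), c(3, 2.5), c(0.02, 0.02))
  map <- data.frame(species = c("AN", "DR"),
                    transcript_id = c("t1", "u1"),
                    reference_gene = c("G1", "G1"))
  rr <- data.frame(record_id = "G1", reference_gene = "G1",
                   log2fc_AN = -4, adj_p_AN = 0.01, significant_AN = TRUE,
                   log2fc_DR = 3, adj_p_DR = 0.02, significant_DR = TRUE,
                   source = "reference_collapse")
  out <- ortholog_pair_de(deA, deB, links, map = map,
                          reference_records = rr, species = c("AN", "DR"))
  # t1|u1 de-duplicates onto G1; t7|u7 is a new reference-free record
  expect_identical(nrow(out), 2L)
  expect_identical(out$source[out$record_id == "G1"], "both")
  expect_true(any(is.na(out$reference_gene)))
  # nothing significant -> no pair records
  deB0 <- deB; deB0$significant <- FALSE
  out0 <- ortholog_pair_de(deA, deB0, links, species = c("AN", "DR"))
  expect_identical(nrow(out0), 0L)
})

test_that("candidate scoring counts criteria and ranks deterministically", {
  go <- data.frame(gene_id = c("G1", "G2", "G3"),
                   go_id = c("GO:0000001", "GO:0000002", "GO:0000009"),
                   go_namespace = "BP")
  cmap <- c("GO:0000001" = "circadian", "GO:0000002" = "vision",
            "GO:0000009" = "other")
  rec <- data.frame(reference_gene = c("G1", "G2", "G3", "G4"),
                    log2fc_AN = c(-3, -4, -5, -2.5),
                    adj_p_AN = c(1e-8, 1e-4, 1e-3, 1e-9),
                    significant_AN = TRUE,
                    log2fc_DR = c(3, 4, 5, 2.5),
                    adj_p_DR = c(1e-6, 1e-5, 1e-2, 1e-7),
                    significant_DR = c(TRUE, TRUE, TRUE, FALSE),
                    pattern = c("flipped", "flipped", "flipped",
                                "single_species_strong"),
                    diel_coincident = c(TRUE, TRUE, TRUE, FALSE))
  out <- rank_candidates(rec, go, cmap)
  expect_identical(out$reference_gene[1:2], c("G1", "G2"))  # score 3 by adj_p
  expect_identical(out$score[out$reference_gene == "G3"], 2L)  # GO 'other'
  expect_identical(out$score[out$reference_gene == "G4"], 0L)
  # the score always equals the recomputed criteria sum
  expect_identical(out$score,
                   as.integer(out$de_in_both) +
                     as.integer(out$diel_coincident) +
                     as.integer(out$functional_hit))
  expect_identical(out$rank, 1:4)
})
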