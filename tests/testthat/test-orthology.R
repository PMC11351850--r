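test_that("Smith-Waterman scores match BLOSUM62 lookups and the oracle", {
  r <- pairwise_score("ACDE", "ACDE")
  expect_identical(r$score, 24)      # 4 + 9 + 6 + 5 on the diagonal
  expect_identical(r$identity, 1)
  expect_identical(pairwise_score("ACDE", "")$score, 0)
  expect_identical(pairwise_score("", "ACDE")$identity, 0)
  # symmetry over random pairs
  set.seed(12)
  for (i in 1:25) {
    a <- random_protein(sample(10:60, 1))
    b <- random_protein(sample(10:60, 1))
    expect_identical(pairwise_score(a, b)$score, pairwise_score(b, a)$score)
  }
  # independent oracle: Biostrings local alignment with the same costs
  set.seed(13)
  for (i in 1:12) {
    a <- random_protein(40)
    b <- mutate_protein_str(a, 0.2)
    want <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE)
    expect_identical(pairwise_score(a, b)$score, want)
  }
})

test_that("reciprocal best hits pair mutated copies and stay symmetric", {
  set.seed(3)
  A <- stats::setNames(vapply(1:30, function(i) random_protein(60), ""),
                       sprintf("a%02d", 1:30))
  B <- stats::setNames(vapply(A, mutate_protein_str, "", rate = 0.05),
                       sprintf("b%02d", 1:30))
  rb <- reciprocal_best_hits(A, B)
  expect_identical(nrow(rb), 30L)
  expect_identical(sub("a", "b", rb$a), rb$b)
  # identical proteomes pair by identity
  rb2 <- reciprocal_best_hits(A, stats::setNames(A, names(A)))
  expect_identical(rb2$a, rb2$b)
  expect_true(all(rb2$identity == 1))
  # a protein missing from B stays unpaired
  rb3 <- reciprocal_best_hits(A, B[-5])
  expect_false("a05" %in% rb3$a)
  # symmetric in its arguments
  rb4 <- reciprocal_best_hits(B, A)
  expect_identical(rb4[order(rb4$b), ]$b, rb[order(rb$a), ]$a)
  # the k-mer prescreen agrees with the exhaustive search here
  rbk <- reciprocal_best_hits(A, B, prescreen = "kmer")
  expect_identical(rbk[, c("a", "b")], rb[, c("a", "b")])
  expect_warning(reciprocal_best_hits(A, character(0)), "empty")
})

test_that("planted one-to-one orthology is recovered at >= 99%", {
  cfg <- sim_config(seed = 6, n_ref_genes = 300, n_flipped = 10,
                    n_concordant = 10, n_single_species = 10, n_modules = 0)
  o <- simulate_orthology(cfg)
  og <- build_orthogroups(o$proteomes$ref, o$proteomes[cfg$species])
  truth11 <- o$classes$reference_gene[o$classes$orthology_class == "one_to_one"]
  for (sp in cfg$species) {
    tm <- o$map[o$map$species == sp & o$map$reference_gene %in% truth11, ]
    got <- og$map[og$map$species == sp, ]
    hit <- got$reference_gene[match(tm$transcript_id, got$transcript_id)]
    expect_gte(mean(!is.na(hit) & hit == tm$reference_gene), 0.99)
  }
})

test_that("representative selection ranks similarity, then length, then id", {
  g <- data.frame(species = "AN",
                  transcript_id = c("t1", "t2"),
                  identity = c(0.90, 0.95), length = c(900, 200))
  expect_identical(select_representative(g), "t2")
  g2 <- data.frame(species = "AN",
                   transcript_id = c("t1", "t2"),
                   identity = c(0.95, 0.949), length = c(200, 900))
  expect_identical(select_representative(g2), "t2")
  expect_identical(select_representative(g2, order = "length"), "t2")
  g3 <- data.frame(species = "AN",
                   transcript_id = c("tb", "ta"),
                   identity = c(0.9, 0.9), length = c(100, 100))
  expect_identical(select_representative(g3), "ta")
  # deterministic under member order permutation
  expect_identical(select_representative(g3[2:1, ]), "ta")
})

test_that("orthogroups anchor one reference gene and split collisions", {
  set.seed(44)
  base <- vapply(1:10, function(i) random_protein(80), "")
  ref <- stats::setNames(base, sprintf("R%02d", 1:10))
  mk <- function(prefix, rate = 0.03)
    stats::setNames(vapply(base, mutate_protein_str, "", rate = rate),
                    sprintf("%s%02d", prefix, 1:10))
  og <- build_orthogroups(ref, list(AN = mk("a"), DR = mk("d")))
  expect_identical(sort(unique(og$groups$reference_gene)), names(ref))
  per <- table(og$groups$group_id, og$groups$species)
  expect_true(all(per == 1))
  expect_true(all(og$groups$is_representative))
  # species-specific protein lands in no group and no pairwise link
  lone <- c(mk("a"), LONE = random_protein(80))
  og2 <- build_orthogroups(ref, list(AN = lone, DR = mk("d")))
  expect_false("LONE" %in% og2$groups$transcript_id)
  expect_false("LONE" %in% c(og2$pairwise_links$transcript_a,
                             og2$pairwise_links$transcript_b))
  # two similar references: the component splits by best-hit assignment
  r1 <- random_protein(100)
  r2 <- mutate_protein_str(r1, 0.06)
  a1 <- mutate_protein_str(r1, 0.02)
  b1 <- mutate_protein_str(r2, 0.02)
  expect_message(
    og3 <- build_orthogroups(c(R1 = r1, R2 = r2),
                             list(AN = c(a1 = a1), DR = c(b1 = b1))),
    "split")
  got <- og3$map
  expect_identical(got$reference_gene[got$transcript_id == "a1"], "R1")
  expect_identical(got$reference_gene[got$transcript_id == "b1"], "R2")
})
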