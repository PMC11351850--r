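test_that("the generator is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 7, n_ref_genes = 120, n_flipped = 5,
                    n_concordant = 4, n_single_species = 4,
                    n_modules = 1, module_size = 10)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$counts$AN$counts, b$counts$AN$counts)
  expect_identical(a$counts$DR$counts, b$counts$DR$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(a$orthology$proteomes, b$orthology$proteomes)
  expect_identical(a$go, b$go)
  expect_identical(a$family$msa, b$family$msa)
})

test_that("planted class counts match the configuration exactly", {
  cfg <- sim_config(seed = 3, n_ref_genes = 400, n_flipped = 50,
                    n_flipped_anti = 7, n_concordant = 12,
                    n_single_species = 9, n_modules = 2, module_size = 15)
  sim <- simulate_counts(cfg)
  tab <- table(sim$truth$de_class)
  expect_identical(as.integer(tab[["flipped_coincident"]]), 50L)
  expect_identical(as.integer(tab[["flipped_anticoincident"]]), 7L)
  expect_identical(as.integer(tab[["concordant_day"]] +
                                tab[["concordant_night"]]), 12L)
  expect_identical(as.integer(tab[["single_species"]]), 9L)
  expect_identical(sum(!is.na(sim$truth$module_id)), 30L)
  expect_identical(sum(sim$truth$is_key_gene), 1L)
  # key gene is flipped-coincident with the doubled effect size
  key <- sim$truth[sim$truth$is_key_gene, ]
  expect_identical(key$de_class, "flipped_coincident")
  expect_identical(abs(key$true_lfc_AN), cfg$key_gene_lfc / 2)
  # flipped-coincident genes: day-up in the diurnal, night-up in the nocturnal
  fl <- sim$truth[sim$truth$de_class == "flipped_coincident", ]
  expect_true(all(fl$true_lfc_AN < 0 & fl$true_lfc_DR > 0))
  # infeasible planting is refused
  expect_error(sim_config(n_ref_genes = 100, n_flipped = 90), "infeasible")
})

test_that("null-gene counts match the NB mean and are overdispersed", {
  cfg <- sim_config(seed = 11, n_ref_genes = 2000)
  sim <- simulate_counts(cfg)
  tr <- sim$truth
  nulls <- tr$reference_gene[tr$de_class == "null" & is.na(tr$module_id) &
                               tr$orthology_class == "one_to_one"]
  map <- sim$orthology$map
  for (sp in cfg$species) {
    m <- sim$counts[[sp]]
    sm <- map[map$species == sp & map$reference_gene %in% nulls, ]
    mu <- outer(sim$params$q[sm$reference_gene],
                sim$params$lib[[sp]][colnames(m$counts)])
    y <- m$counts[sm$transcript_id, ]
    v <- mu + cfg$dispersion * mu^2
    z <- (y - mu) / sqrt(v)
    # standardized residuals: mean within 3 standard errors of 0
    expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
    # overdispersion: pooled squared residuals exceed the Poisson scale
    expect_gt(mean((y - mu)^2 / mu), 1.5)
  }
})

test_that("orthology classes control transcript multiplicity", {
  cfg1 <- sim_config(seed = 2, n_ref_genes = 100, frac_one_to_one = 1,
                     frac_many_to_one = 0, frac_species_specific = 0,
                     n_flipped = 5, n_concordant = 0, n_single_species = 0,
                     n_modules = 0)
  o1 <- simulate_orthology(cfg1)
  for (sp in cfg1$species)
    expect_identical(sum(o1$map$species == sp), 100L)
  cfg2 <- sim_config(seed = 2, n_ref_genes = 200, frac_one_to_one = 0.5,
                     frac_many_to_one = 0.2, frac_species_specific = 0.3,
                     n_flipped = 5, n_concordant = 0, n_single_species = 0,
                     n_modules = 0)
  o2 <- simulate_orthology(cfg2)
  cls <- o2$classes
  # species-specific genes appear in exactly one species
  ssg <- cls$reference_gene[cls$orthology_class == "species_specific"]
  hits <- table(factor(o2$map$reference_gene[o2$map$reference_gene %in% ssg],
                       levels = ssg))
  expect_true(all(hits == 1))
  # many-to-one genes appear twice per species
  mg <- cls$reference_gene[cls$orthology_class == "many_to_one"][1]
  expect_identical(sum(o2$map$reference_gene == mg), 4L)
})

test_that("GO planting enriches circadian terms among flipped genes", {
  cfg <- sim_config(seed = 5, n_ref_genes = 2000, enrich_factor = 10,
                    go_base_rate = 0.02)
  sim <- simulate_counts(cfg)
  goset <- simulate_go(cfg, sim$truth)
  expect_true(all(grepl("^GO:[0-9]{7}$", goset$go$go_id)))
  circ_terms <- names(goset$category_map)[goset$category_map == "circadian"]
  flip <- sim$truth$reference_gene[sim$truth$de_class == "flipped_coincident"]
  bg <- sim$truth$reference_gene[sim$truth$de_class == "null"]
  rate_in <- function(genes)
    nrow(goset$go[goset$go$gene_id %in% genes &
                    goset$go$go_id %in% circ_terms, ]) /
    (length(genes) * length(circ_terms))
  # planted rate 0.2 vs background 0.02 (binomial error at n = 50 x 3 terms)
  expect_gt(rate_in(flip), 0.1)
  expect_lt(rate_in(bg), 0.04)
  # no planting when the factor is 1
  cfg1 <- sim_config(seed = 5, n_ref_genes = 2000, enrich_factor = 1,
                     plant_key_gene = FALSE)
  g1 <- simulate_go(cfg1, simulate_counts(cfg1)$truth)
  r_flip <- nrow(g1$go[g1$go$gene_id %in% flip &
                         g1$go$go_id %in% circ_terms, ]) /
    (length(flip) * length(circ_terms))
  expect_lt(abs(r_flip - cfg1$go_base_rate), 0.05)
})

test_that("protein family planting controls focal mutations and blocks", {
  cfg <- sim_config(seed = 9)
  fam <- simulate_protein_family(cfg)
  expect_length(fam$msa, cfg$protein$n_species + 2)
  a <- strsplit(fam$msa[["FOCAL_A"]], "")[[1]]
  b <- strsplit(fam$msa[["FOCAL_B"]], "")[[1]]
  diff <- which(a != b)
  expect_identical(length(diff), 23L)
  expect_identical(sum(fam$in_block[diff]), 3L)
  expect_identical(sort(diff), sort(fam$focal_columns))
  # zero in-block substitution rate freezes block columns across species
  cfg0 <- sim_config(seed = 9, protein = list(in_block_sub_rate = 0))
  fam0 <- simulate_protein_family(cfg0)
  m <- do.call(rbind, strsplit(fam0$msa[setdiff(names(fam0$msa),
                                                c("FOCAL_A", "FOCAL_B"))], ""))
  blockcols <- which(fam0$in_block)
  expect_true(all(apply(m[, blockcols, drop = FALSE], 2,
                        function(x) length(unique(x)) == 1)))
  # infeasible focal mutation budget is refused
  expect_error(sim_config(protein = list(focal_mut_in_block = 10000)),
               "exceeds")
})
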