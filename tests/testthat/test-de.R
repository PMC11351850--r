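test_that("TMM factors match the closed form and the symmetry cases", {
  base <- matrix(c(10, 20, 30, 40), 4, 4)
  cm <- tiny_cm(base, n_rep = 2)
  f <- normalize_tmm(cm)
  expect_equal(as.numeric(f), rep(1, 4))
  expect_equal(prod(f), 1)
  # doubled counts absorb into the factor: closed form (1/sqrt(2), sqrt(2))
  two <- cbind(c(10, 20, 30, 40), 2 * c(10, 20, 30, 40))
  cm2 <- count_matrix(
    matrix(two, 4, 2, dimnames = list(paste0("g", 1:4), c("A", "B"))),
    data.frame(sample_id = c("A", "B"), species = "SP",
               diel_phase = c("day", "night"), activity_niche = "diurnal",
               replicate = 1L))
  f2 <- normalize_tmm(cm2)
  expect_equal(as.numeric(f2), c(1 / sqrt(2), sqrt(2)))
  one <- count_matrix(matrix(5:6, 2, 1,
                             dimnames = list(c("g1", "g2"), "A")),
                      data.frame(sample_id = "A", species = "SP",
                                 diel_phase = "day",
                                 activity_niche = "diurnal",
                                 replicate = 1L))
  expect_error(normalize_tmm(one), "2 samples")
  # agrees with the established TMM implementation up to the library-size
  # component the factors absorb
  skip_if_not_installed("edgeR")
  set.seed(1)
  cts <- matrix(rnbinom(400 * 6, mu = 50, size = 5), 400)
  cm3 <- tiny_cm(cts, n_rep = 3)
  ours <- normalize_tmm(cm3)
  ed <- edgeR::calcNormFactors(cts, method = "TMM")
  lib <- colSums(cts)
  ref <- ed * lib
  ref <- ref / exp(mean(log(ref)))
  expect_equal(as.numeric(ours), unname(ref), tolerance = 0.05)
})

test_that("median-of-ratios factors are proportional to library scale", {
  base <- matrix(c(10, 20, 30, 40), 4, 4)
  expect_equal(as.numeric(normalize_median_ratio(tiny_cm(base, n_rep = 2))),
               rep(1, 4))
  tri <- base
  tri[, 2] <- 3 * base[, 2]
  f <- normalize_median_ratio(tiny_cm(tri, n_rep = 2))
  expect_equal(unname(f[2] / f[1]), 3)
  # every gene holding a zero triggers the documented TMM fallback
  z <- matrix(c(0, 5, 3, 0, 2, 0, 0, 4), 2)
  ws <- capture_warnings(fz <- normalize_median_ratio(tiny_cm(z, n_rep = 2)))
  expect_true(any(grepl("falling back", ws)))
  expect_identical(attr(fz, "method"), "tmm")
  skip_if_not_installed("DESeq2")
  set.seed(2)
  cts <- matrix(rnbinom(400 * 6, mu = 80, size = 5), 400,
                dimnames = list(paste0("g", 1:400), NULL))
  cm3 <- tiny_cm(cts, n_rep = 3)
  ours <- normalize_median_ratio(cm3)
  ref <- DESeq2::estimateSizeFactorsForMatrix(cts)
  expect_equal(as.numeric(ours / ref), rep(1, 6), tolerance = 1e-4)
})

test_that("dispersion estimation recovers the simulation truth", {
  pois <- simulate_null_counts(4, 2000, phi = 0, n_rep = 3)
  fp <- normalize_tmm(pois)
  expect_lte(median(estimate_dispersion(pois, fp)), 0.01)
  nb <- simulate_null_counts(4, 2000, phi = 0.2, n_rep = 3)
  fn <- normalize_tmm(nb)
  phi <- estimate_dispersion(nb, fn)
  expect_gte(median(phi), 0.1)
  expect_lte(median(phi), 0.3)
  # a constant gene falls back to the trend value
  cts <- nb$counts
  cts[1, ] <- 50
  cm <- count_matrix(cts, nb$design)
  f1 <- rep(1, 6)
  names(f1) <- colnames(cts)
  phi2 <- estimate_dispersion(cm, f1)
  expect_gte(phi2[1], 0)
  expect_lt(phi2[1], median(phi2) * 2 + 0.05)
})

test_that("exact test matches the Poisson-limit closed form and symmetry", {
  # group totals 10 vs 0: conditional binomial gives p = 2 * 0.5^10
  cts <- matrix(0, 1, 6, dimnames = list("g1", NULL))
  cts[1, 1:3] <- c(10, 0, 0)
  cm <- tiny_cm(cts, n_rep = 3)
  f <- stats::setNames(rep(1, 6), colnames(cm$counts))
  r <- exact_test(cm, f, 0)
  expect_equal(r$p, 2 * 0.5^10, tolerance = 1e-12)
  # identical groups: fold change zero, p = 1
  sym <- tiny_cm(matrix(c(5, 7, 9, 5, 7, 9), 1), n_rep = 3)
  rs <- exact_test(sym, f, 0.1)
  expect_identical(rs$log2fc, 0)
  expect_identical(rs$p, 1)
  # relabeling day and night negates the fold change, preserves p
  set.seed(8)
  cts2 <- matrix(rnbinom(50 * 6, mu = 60, size = 10), 50)
  cm2 <- tiny_cm(cts2, n_rep = 3)
  swapped <- cm2
  swapped$design$diel_phase <- rev(cm2$design$diel_phase)
  a <- exact_test(cm2, f, 0.1)
  b <- exact_test(swapped, f, 0.1)
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$p, b$p)
  aw <- wald_test(cm2, f, 0.1)
  bw <- wald_test(swapped, f, 0.1)
  expect_equal(aw$log2fc, -bw$log2fc, tolerance = 1e-6)
})

test_that("exact test equals the convolution enumeration oracle", {
  set.seed(21)
  n_rep <- 3
  for (phi in c(0, 0.1, 0.5)) {
    cts <- matrix(rnbinom(40 * 2 * n_rep, mu = 4,
                          size = if (phi > 0) 1 / phi else 1e8),
                  40, 2 * n_rep)
    keep <- rowSums(cts) <= 50 & rowSums(cts) > 0
    cts <- cts[keep, , drop = FALSE]
    rownames(cts) <- paste0("g", seq_len(nrow(cts)))
    cm <- tiny_cm(cts, n_rep = n_rep)
    f <- stats::setNames(rep(1, 2 * n_rep), colnames(cm$counts))
    r <- exact_test(cm, f, phi)
    day <- cm$design$diel_phase == "day"
    want <- vapply(seq_len(nrow(cts)), function(i)
      oracle_exact_p(sum(cts[i, day]), sum(cts[i, !day]),
                     sum(day), sum(!day), phi), 0)
    expect_equal(r$p, want, tolerance = 1e-8)
  }
})

test_that("Wald test is unbiased and handles degenerate genes", {
  f <- stats::setNames(rep(1, 6), tiny_design(n_rep = 3)$sample_id)
  # null fit: equal group means give |z| ~ 0
  eq <- tiny_cm(matrix(c(20, 20, 20, 20, 20, 20), 1), n_rep = 3)
  r0 <- wald_test(eq, f, 0.1)
  expect_gt(r0$p, 0.999)
  expect_equal(r0$log2fc, 0, tolerance = 1e-6)
  # recovery of a planted log2 fold change of 4 at phi = 0.1, n = 3 + 3
  cm <- simulate_de_counts(31, 500, mu = 100, lfc = 4, phi = 0.1)
  r <- wald_test(cm, f, 0.1)
  expect_lt(abs(mean(r$log2fc) - 4), 0.06)
  expect_gte(mean(abs(r$log2fc - 4) <= 0.75), 0.9)
  # all-zero gene skipped; one-zero-group gene gets the pseudo-count path
  dg <- rbind(g1 = rep(0, 6), g2 = c(0, 0, 0, 25, 30, 20))
  rz <- wald_test(tiny_cm(dg, n_rep = 3), f, 0.1)
  expect_identical(rz$flag, c("allzero", "pseudo"))
  expect_identical(rz$p[1], 1)
  expect_true(is.finite(rz$log2fc[2]) && rz$log2fc[2] > 3)
})

test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_bh(0.123), 0.123)
  p <- runif(100)
  adj <- adjust_bh(p)
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-12))
  expect_true(all(adj <= 1 & adj >= p))
})

test_that("significance calling applies FDR, fold-change and strata", {
  r <- data.frame(gene_id = c("a", "b", "c"),
                  log2fc = c(2.5, 1.9, -6),
                  mean_expr = 10, p = 0.001,
                  adj_p = c(0.03, 0.03, 0.03),
                  method = "wald", significant = FALSE)
  out <- call_significant(r)
  expect_identical(out$significant, c(TRUE, FALSE, TRUE))
  strong_day <- call_significant(r, stratum = c(-Inf, -5))
  expect_identical(strong_day$significant, c(FALSE, FALSE, TRUE))
  up <- call_significant(data.frame(r[1, ], row.names = NULL),
                         stratum = c(5, Inf))
  expect_false(up$significant)
})

test_that("method consensus reduces false positives on planted data", {
  cons_fp <- ex_fp <- wa_fp <- numeric(0)
  for (s in 1:10) {
    cfg <- sim_config(seed = s, n_ref_genes = 400, n_flipped = 10,
                      n_concordant = 10, n_single_species = 5, n_modules = 0)
    sim <- simulate_counts(cfg)
    m <- filter_low_expression(sim$counts$AN)
    ex <- run_de(m, "exact")
    wa <- run_de(m, "wald")
    cons <- method_consensus(ex, wa)
    truth <- sim$truth
    map <- sim$orthology$map
    true_de <- map$transcript_id[map$species == "AN" &
                                   map$reference_gene %in%
                                   truth$reference_gene[truth$de_class != "null"]]
    ex_fp <- c(ex_fp, sum(!(ex$gene_id[ex$significant] %in% true_de)))
    wa_fp <- c(wa_fp, sum(!(wa$gene_id[wa$significant] %in% true_de)))
    cons_fp <- c(cons_fp, sum(!(cons$genes %in% true_de)))
  }
  expect_lte(mean(cons_fp), mean(ex_fp))
  expect_lte(mean(cons_fp), mean(wa_fp))
  # intersection semantics
  a <- data.frame(gene_id = c("x", "y"), significant = c(TRUE, TRUE))
  b <- data.frame(gene_id = c("y", "z"), significant = c(TRUE, TRUE))
  expect_identical(method_consensus(a, b)$genes, "y")
  b$significant <- FALSE
  expect_length(method_consensus(a, b)$genes, 0)
})
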