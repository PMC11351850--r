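# small synthetic expression sets with planted module structure
planted_expr <- function(seed, n_samples = 12, sizes = c(50, 50),
                         n_noise = 100, noise_sd = 0.15) {
  set.seed(seed)
  z <- matrix(rnorm(length(sizes) * n_samples), length(sizes))
  # orthogonalize the latent factors so the planted programs are distinct
  if (length(sizes) > 1)
    for (i in 2:length(sizes))
      for (j in 1:(i - 1))
        z[i, ] <- z[i, ] - sum(z[i, ] * z[j, ]) / sum(z[j, ]^2) * z[j, ]
  cols <- list()
  for (m in seq_along(sizes))
    cols[[m]] <- t(replicate(sizes[m],
                             z[m, ] + rnorm(n_samples, 0, noise_sd)))
  noise <- matrix(rnorm(n_noise * n_samples), n_noise)
  x <- t(rbind(do.call(rbind, cols), noise))
  colnames(x) <- sprintf("g%03d", seq_len(ncol(x)))
  rownames(x) <- sprintf("s%02d", seq_len(nrow(x)))
  list(expr = scale(x),
       labels = c(rep(seq_along(sizes), sizes), rep(0, n_noise)))
}

test_that("expression preprocessing z-scores and drops constant genes", {
  cm <- tiny_cm(matrix(c(5, 6, 9, 12, 3, 3, 3, 3, 20, 9, 4, 2), 3,
                       byrow = TRUE), n_rep = 2)
  f <- stats::setNames(rep(1, 4), colnames(cm$counts))
  expect_message(x <- preprocess_expression(cm, f), "constant")
  expect_identical(ncol(x), 2L)
  expect_equal(unname(colMeans(x)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(x, 2, sd)), c(1, 1), tolerance = 1e-9)
  # combined matrix spans the shared reference-gene set
  cfg <- sim_config(seed = 2, n_ref_genes = 150, frac_one_to_one = 1,
                    frac_many_to_one = 0, frac_species_specific = 0,
                    n_flipped = 5, n_concordant = 5, n_single_species = 5,
                    n_modules = 1, module_size = 10)
  sim <- simulate_counts(cfg)
  fs <- lapply(sim$counts, normalize_median_ratio)
  xc <- preprocess_expression(sim$counts, fs, combined = TRUE,
                              map = sim$orthology$map)
  expect_identical(nrow(xc), 12L)
  expect_identical(ncol(xc), 150L)
  expect_identical(nrow(attr(xc, "design")), 12L)
})

test_that("TOM follows its formula on exact toy cases and stays bounded", {
  # x1 = x2 perfectly correlated, x3 orthogonal: TOM_12 = 1
  x1 <- rep(c(1, -1), 6)
  x3 <- rep(c(1, 1, -1, -1), 3)
  expr <- cbind(g1 = x1, g2 = x1, g3 = x3)
  tom <- adjacency_tom(expr, power = 6)
  expect_equal(tom["g1", "g2"], 1, tolerance = 1e-12)
  expect_equal(tom["g1", "g3"], 0, tolerance = 1e-12)
  expect_identical(diag(tom), c(g1 = 1, g2 = 1, g3 = 1))
  # bounds and symmetry on arbitrary data
  px <- planted_expr(5, sizes = c(20), n_noise = 40)
  tom2 <- adjacency_tom(px$expr, power = 9)
  expect_true(all(tom2 >= 0 & tom2 <= 1 + 1e-12))
  expect_equal(tom2, t(tom2), tolerance = 1e-12)
  # signed network: perfect anticorrelation gives zero adjacency
  toms <- adjacency_tom(cbind(g1 = x1, g2 = -x1, g3 = x3), power = 5,
                        network_type = "signed")
  expect_lt(toms["g1", "g2"], 0.05)
})

test_that("planted modules are detected and labels are stable", {
  px <- planted_expr(7, sizes = c(50, 50), n_noise = 100)
  tom <- adjacency_tom(px$expr, power = 9)
  mods <- detect_modules(tom)
  non_grey <- setdiff(unique(mods), "grey")
  expect_identical(length(non_grey), 2L)
  sizes <- sort(table(mods[mods != "grey"]), decreasing = TRUE)
  expect_true(all(abs(sizes - 50) <= 5))
  expect_gte(mclust::adjustedRandIndex(mods, px$labels), 0.9)
  # gene-order permutation leaves the assignment invariant
  perm <- sample(ncol(px$expr))
  tomp <- adjacency_tom(px$expr[, perm], power = 9)
  modp <- detect_modules(tomp)
  expect_identical(modp[colnames(px$expr)], mods)
  # an impossible minimum size sends everything to grey
  expect_true(all(detect_modules(tom, min_module_size = 1000) == "grey"))
  # pure noise stays unclustered
  for (s in 1:3) {
    nz <- planted_expr(100 + s, sizes = integer(0), n_noise = 150)
    tn <- adjacency_tom(nz$expr, power = 9)
    expect_true(all(detect_modules(tn) == "grey"))
  }
})

test_that("module eigengenes match the SVD oracle and orient positively", {
  px <- planted_expr(9, sizes = c(8, 10), n_noise = 20)
  tom <- adjacency_tom(px$expr, power = 9)
  mods <- detect_modules(tom, min_module_size = 5)
  eig <- module_eigengenes(px$expr, mods)
  expect_identical(nrow(eig), nrow(px$expr))
  for (mm in colnames(eig)) {
    sub <- scale(px$expr[, names(mods)[mods == mm], drop = FALSE])
    oracle <- stats::prcomp(sub, center = FALSE, scale. = FALSE)$x[, 1]
    oracle <- as.numeric(scale(oracle))
    agree <- max(abs(cor(eig[, mm], oracle)))
    expect_gt(agree, 1 - 1e-9)
    expect_gt(mean(cor(eig[, mm], sub)), 0)
    expect_equal(sd(eig[, mm]), 1, tolerance = 1e-9)
  }
  # rank-1 case: identical genes reproduce the shared profile
  prof <- as.numeric(scale(rnorm(12)))
  xx <- cbind(a = prof, b = prof, c = prof)
  e1 <- module_eigengenes(xx, c(a = "blue", b = "blue", c = "blue"))
  expect_equal(abs(cor(e1[, 1], prof)), 1, tolerance = 1e-9)
})

test_that("module-trait correlation separates phase from species", {
  design <- rbind(tiny_design("AN", "diurnal", 3),
                  tiny_design("DR", "nocturnal", 3))
  phase <- as.numeric(design$diel_phase == "night")
  species <- as.numeric(design$species == "DR")
  # a vector orthogonal to both the phase and the species contrasts
  orthv <- rep(c(1, -1, 0, 1, -1, 0), 2)
  eig <- cbind(phaseish = as.numeric(scale(phase)),
               orth = as.numeric(scale(orthv)))
  mt <- module_trait(eig, design)
  expect_equal(mt$cor[mt$module == "phaseish" & mt$trait == "diel_phase"], 1,
               tolerance = 1e-9)
  expect_lt(mt$p[mt$module == "phaseish" & mt$trait == "diel_phase"], 1e-9)
  expect_equal(mt$cor[mt$module == "orth" & mt$trait == "diel_phase"], 0,
               tolerance = 1e-9)
  expect_gt(mt$p[mt$module == "orth" & mt$trait == "diel_phase"], 0.99)
  expect_true(all(c("diel_phase", "species") %in% mt$trait))
})

test_that("soft-power choice honors its contract", {
  px <- planted_expr(3, sizes = c(40, 40), n_noise = 60)
  one <- suppressWarnings(pick_soft_power(px$expr, powers = 9))
  expect_identical(one$power, 9)
  res <- suppressWarnings(pick_soft_power(px$expr))
  expect_true(res$power %in% 1:20)
  expect_identical(nrow(res$fit_table), 20L)
  if (res$reached_target) {
    reached <- res$fit_table$power[res$fit_table$r_squared >= 0.8]
    expect_identical(res$power, min(reached))
  } else {
    expect_identical(res$power,
                     res$fit_table$power[which.max(res$fit_table$r_squared)])
  }
  # degenerate connectivity (all genes alike) forces the fallback path
  set.seed(11)
  prof <- rnorm(12)
  flat <- vapply(1:30, function(i) prof + rnorm(12, 0, 0.01),
                 numeric(12))
  colnames(flat) <- paste0("g", 1:30)
  expect_warning(pick_soft_power(scale(flat)), "target")
})
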