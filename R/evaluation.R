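#' Simulate a null (no differential expression) count matrix
#'
#' One species, day/night design, log-normal gene means and
#' negative-binomial noise, with no planted effects — used for type-I
#' error calibration of the two tests.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes.
#' @param phi NB dispersion.
#' @param n_rep Replicates per phase.
#' @param mean_log,sd_log Log-normal parameters of gene means.
#' @param lib_cv Library-size coefficient of variation.
#' @return A [count_matrix()].
#' @export
simulate_null_counts <- function(seed, n_genes = 10000, phi = 0.2,
                                 n_rep = 3, mean_log = log(100),
                                 sd_log = 1, lib_cv = 0.15) {
  with_seed(seed, {
    q <- rlnorm(n_genes, mean_log, sd_log)
    phases <- rep(c("day", "night"), each = n_rep)
    sigma <- sqrt(log(1 + lib_cv^2))
    lib <- exp(rnorm(2 * n_rep, 0, sigma) - sigma^2 / 2)
    mu <- outer(q, lib)
    cts <- if (phi > 0)
      matrix(rnbinom(length(mu), mu = mu, size = 1 / phi), n_genes)
    else matrix(stats::rpois(length(mu), mu), n_genes)
    dimnames(cts) <- list(sprintf("G%05d", seq_len(n_genes)),
                          sprintf("S_%s%d", phases, rep(seq_len(n_rep), 2)))
    design <- data.frame(sample_id = colnames(cts), species = "SP",
                         diel_phase = phases, activity_niche = "diurnal",
                         replicate = rep(seq_len(n_rep), 2))
    count_matrix(cts, design)
  })
}

#' Type-I error of the exact and Wald tests on null data
#'
#' Runs both tests, with their normalization and dispersion estimation, on
#' a null simulation and reports the fraction of unadjusted p-values below
#' 0.05 for each.
#'
#' @inheritParams simulate_null_counts
#' @return List with `frac_exact`, `frac_wald`, `n_genes`.
#' @export
eval_de_null <- function(seed, n_genes = 10000, phi = 0.2, n_rep = 3) {
  m <- simulate_null_counts(seed, n_genes = n_genes, phi = phi,
                            n_rep = n_rep)
  ex <- run_de(m, "exact")
  wa <- run_de(m, "wald")
  list(frac_exact = mean(ex$p < 0.05), frac_wald = mean(wa$p < 0.05),
       n_genes = n_genes)
}

#' Sign-flip recovery across simulation seeds
#'
#' For each seed, simulates the default study, runs consensus differential
#' expression in each species, collapses onto the planted ortholog map,
#' classifies cross-species patterns, and scores flip sensitivity and
#' precision against the planted truth.
#'
#' @param seeds Integer vector of simulation seeds.
#' @param cfg_fn Function seed -> [sim_config()] (default: the default
#'   study conditions at that seed).
#' @return List with per-seed `sensitivity` and `precision` vectors and
#'   their means.
#' @export
eval_flip_recovery <- function(seeds, cfg_fn = function(s) sim_config(seed = s)) {
  sens <- prec <- numeric(length(seeds))
  for (i in seq_along(seeds)) {
    study <- simulate_study(cfg_fn(seeds[i]))
    out <- run_study_analysis(study, orthology_source = "truth",
                              network = FALSE, conservation = FALSE,
                              enrichment = FALSE)
    ev <- evaluate_against_truth(out, study$truth)
    sens[i] <- ev$flip_sensitivity
    prec[i] <- ev$flip_precision
  }
  list(sensitivity = sens, precision = prec,
       mean_sensitivity = mean(sens), mean_precision = mean(prec, na.rm = TRUE),
       n_seeds = length(seeds))
}

#' End-to-end candidate ranking across simulation seeds
#'
#' Runs the full pipeline (reciprocal-best-hit orthology on the simulated
#' proteomes, consensus DE, coincidence, GO screening, candidate ranking)
#' and records the rank of the planted key gene per seed.
#'
#' @param seeds Integer vector of simulation seeds.
#' @param cfg_fn Function seed -> [sim_config()].
#' @return List with per-seed `rank`, the `top1_rate`, and `n_seeds`.
#' @export
eval_candidate_rank <- function(seeds,
                                cfg_fn = function(s) sim_config(seed = s)) {
  rk <- integer(length(seeds))
  for (i in seq_along(seeds)) {
    study <- simulate_study(cfg_fn(seeds[i]))
    out <- run_study_analysis(study, orthology_source = "rbh",
                              network = FALSE, conservation = FALSE,
                              enrichment = FALSE)
    ev <- evaluate_against_truth(out, study$truth)
    rk[i] <- ifelse(is.na(ev$candidate_rank_key_gene), Inf,
                    ev$candidate_rank_key_gene)
  }
  list(rank = rk, top1_rate = mean(rk == 1), n_seeds = length(seeds))
}

#' Co-expression module recovery across simulation seeds
#'
#' Builds the combined-species network on the planted-map expression
#' matrix (soft power 9), detects modules, and reports the adjusted Rand
#' index against the planted modules (over non-grey genes) plus whether the
#' first planted species-specific module's best-matching detected module
#' correlates more strongly with species than with diel phase.
#'
#' @param seeds Integer vector of simulation seeds.
#' @param cfg_fn Function seed -> [sim_config()].
#' @param power Soft-threshold power (default 9).
#' @return List with per-seed `ari`, logical `species_wins`, and their
#'   summaries.
#' @export
eval_network_recovery <- function(seeds,
                                  cfg_fn = function(s) sim_config(seed = s),
                                  power = 9) {
  ari <- numeric(length(seeds)); wins <- logical(length(seeds))
  for (i in seq_along(seeds)) {
    cfg <- cfg_fn(seeds[i])
    sim <- simulate_counts(cfg)
    spp <- cfg$species
    factors <- lapply(stats::setNames(spp, spp), function(sp)
      normalize_median_ratio(sim$counts[[sp]]))
    expr <- preprocess_expression(sim$counts[spp], factors, combined = TRUE,
                                  map = sim$orthology$map)
    tom <- adjacency_tom(expr, power = power)
    modules <- detect_modules(tom)
    de_planted <- sim$truth$reference_gene[sim$truth$de_class != "null"]
    keep <- names(modules)[modules != "grey" &
                             !(names(modules) %in% de_planted)]
    tm <- sim$truth$module_id[match(keep, sim$truth$reference_gene)]
    tm[is.na(tm)] <- "none"
    ari[i] <- if (length(keep)) mclust::adjustedRandIndex(modules[keep], tm)
    else 0
    # species-vs-phase correlation contest for a planted species module
    mt <- attr(sim$truth, "module_type")
    sp_mods <- names(mt)[mt %in% spp]
    wins[i] <- FALSE
    if (length(sp_mods)) {
      planted_genes <- sim$truth$reference_gene[
        !is.na(sim$truth$module_id) & sim$truth$module_id == sp_mods[1]]
      hit <- modules[intersect(planted_genes, names(modules))]
      hit <- hit[hit != "grey"]
      if (length(hit)) {
        best <- names(sort(table(hit), decreasing = TRUE))[1]
        eig <- module_eigengenes(expr, modules)
        if (best %in% colnames(eig)) {
          tr <- module_trait(eig[, best, drop = FALSE], attr(expr, "design"))
          cs <- abs(tr$cor[tr$trait == "species"])
          cp <- abs(tr$cor[tr$trait == "diel_phase"])
          wins[i] <- length(cs) && length(cp) && cs >= 0.8 && cs > cp
        }
      }
    }
  }
  list(ari = ari, species_wins = wins, mean_ari = mean(ari),
       species_win_rate = mean(wins), n_seeds = length(seeds))
}

#' Enrichment calibration under a permuted-annotation null, plus power
#'
#' Permutes the gene labels of the simulated GO table and records the
#' fraction of term p-values below 0.05 across permutations (super-uniform
#' when calibrated), then tests whether the planted circadian enrichment
#' among flipped-coincident genes is detected at adjusted p < 0.05.
#'
#' @param seed Simulation seed.
#' @param n_perm Number of label permutations (default 200).
#' @param cfg A [sim_config()] (default study conditions at `seed`).
#' @return List with `null_frac_p05`, `planted_circadian_adj_p`,
#'   `detected`, `n_perm`.
#' @export
eval_enrichment_calibration <- function(seed, n_perm = 200,
                                        cfg = sim_config(seed = seed)) {
  sim <- simulate_counts(cfg)
  goset <- simulate_go(cfg, sim$truth)
  background <- sim$truth$reference_gene
  study <- sim$truth$reference_gene[sim$truth$de_class == "flipped_coincident"]
  enr <- hypergeom_enrich(study, background, goset$go, goset$category_map)
  circ <- enr[enr$category == "circadian", , drop = FALSE]
  planted_adj_p <- if (nrow(circ)) min(circ$adj_p) else NA_real_
  fr <- with_seed(derive_seed(seed, 9), {
    ps <- numeric(0)
    for (b in seq_len(n_perm)) {
      perm_go <- goset$go
      relabel <- stats::setNames(sample(background), background)
      perm_go$gene_id <- unname(relabel[perm_go$gene_id])
      e <- hypergeom_enrich(study, background, perm_go, goset$category_map)
      ps <- c(ps, e$p)
    }
    mean(ps < 0.05)
  })
  list(null_frac_p05 = fr, planted_circadian_adj_p = planted_adj_p,
       detected = !is.na(planted_adj_p) && planted_adj_p < 0.05,
       n_perm = n_perm)
}

#' Conserved-block and focal-mutation recovery
#'
#' Simulates the protein family, profiles conservation, detects blocks,
#' and reports the Jaccard overlap with the planted blocks together with
#' the focal-pair mutation counts.
#'
#' @param seed Simulation seed.
#' @param cfg A [sim_config()].
#' @return List with `jaccard`, `n_total`, `n_in_block`, `n_blocks`.
#' @export
eval_conservation <- function(seed, cfg = sim_config(seed = seed)) {
  fam <- simulate_protein_family(cfg)
  prof <- column_conservation(fam$msa, reference_id = "REF")
  blocks <- find_blocks(prof)
  muts <- focal_mutations(fam$msa, "FOCAL_A", "FOCAL_B", prof, blocks)
  list(jaccard = jaccard_blocks(blocks, fam$blocks),
       n_total = muts$n_total, n_in_block = muts$n_in_block,
       n_blocks = nrow(blocks))
}
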