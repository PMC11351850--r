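#' Per-species day-vs-night differential expression
#'
#' Runs normalization (TMM for the exact flavour, median-of-ratios for the
#' Wald flavour, mirroring the pairing of the two mainstream count-based
#' tools), trend-shrunk dispersion estimation, and the chosen test.
#'
#' @param m A [count_matrix()] for one species.
#' @param method `"exact"` or `"wald"`.
#' @param alpha,lfc_min Significance thresholds.
#' @param prior_df Dispersion shrinkage prior.
#' @return DE result data frame; attribute `"factors"` carries the scaling
#'   factors.
#' @export
run_de <- function(m, method = c("exact", "wald"), alpha = 0.05,
                   lfc_min = 2.0, prior_df = 10) {
  method <- match.arg(method)
  factors <- if (method == "exact") normalize_tmm(m) else normalize_median_ratio(m)
  phi <- estimate_dispersion(m, factors, prior_df = prior_df)
  res <- if (method == "exact")
    exact_test(m, factors, phi, alpha = alpha, lfc_min = lfc_min)
  else wald_test(m, factors, phi, alpha = alpha, lfc_min = lfc_min)
  attr(res, "factors") <- factors
  res
}

#' Run the full cross-species analysis on a simulated (or loaded) study
#'
#' Executes the expression filter, both DE flavours per species with their
#' consensus, orthology (reciprocal best hits over the proteomes, or the
#' generator's planted map), reference collapse, pattern classification,
#' diel-coincidence, ortholog-pair records, GO enrichment of the flipped
#' set, candidate ranking, the combined-species co-expression network, and
#' the conservation profile of the protein family.
#'
#' @param study A study list from [simulate_study()] (or an equivalently
#'   shaped list of real inputs).
#' @param orthology_source `"rbh"` (run reciprocal best hits on the
#'   proteomes) or `"truth"` (use the generator's planted map).
#' @param alpha,lfc_min DE significance thresholds.
#' @param consensus Require significance under both DE flavours (default
#'   `TRUE`).
#' @param network,conservation,enrichment Stage toggles.
#' @param network_power Soft power for the combined network (default 9);
#'   `NULL` picks it by scale-free fit.
#' @param tpm_filter Apply the TPM >= 1 expression floor first.
#' @return List of stage outputs (`filtered`, `de`, `consensus`,
#'   `orthomap`, `records`, `candidates`, `enrichment`, `network`,
#'   `conservation`).
#' @export
run_study_analysis <- function(study,
                               orthology_source = c("rbh", "truth"),
                               alpha = 0.05, lfc_min = 2.0,
                               consensus = TRUE, network = TRUE,
                               conservation = TRUE, enrichment = TRUE,
                               network_power = 9, tpm_filter = TRUE) {
  orthology_source <- match.arg(orthology_source)
  cfg <- study$config
  spp <- cfg$species
  filtered <- lapply(study$counts, function(m)
    if (tpm_filter) filter_low_expression(m) else m)
  de <- list(); cons <- list(); detab <- list()
  for (sp in spp) {
    ex <- run_de(filtered[[sp]], "exact", alpha = alpha, lfc_min = lfc_min)
    wa <- run_de(filtered[[sp]], "wald", alpha = alpha, lfc_min = lfc_min)
    de[[sp]] <- list(exact = ex, wald = wa)
    cons[[sp]] <- method_consensus(ex, wa)
    tab <- wa
    if (consensus) tab$significant <- tab$gene_id %in% cons[[sp]]$genes
    detab[[sp]] <- tab
  }
  if (orthology_source == "rbh") {
    orthomap <- build_orthogroups(study$orthology$proteomes$ref,
                                  study$orthology$proteomes[spp])
    map <- orthomap$map
    links <- orthomap$pairwise_links
  } else {
    orthomap <- NULL
    map <- study$orthology$map
    links <- NULL
  }
  coll <- lapply(stats::setNames(spp, spp), function(sp)
    collapse_to_reference(detab[[sp]], map, species = sp))
  tbl <- cross_species_table(coll)
  tbl <- classify_pattern(tbl, species = spp)
  tbl <- diel_coincidence(tbl, cfg$niches)
  records <- tbl
  if (!is.null(links) && nrow(links)) {
    rr <- tbl[tbl$pattern %in% c("flipped", "concordant_day",
                                 "concordant_night"), , drop = FALSE]
    rr$source <- "reference_collapse"
    pair_rec <- ortholog_pair_de(detab[[spp[1]]], detab[[spp[2]]],
                                 links, map = map,
                                 reference_records = NULL, species = spp)
    pair_rec <- diel_coincidence(pair_rec, cfg$niches)
    pair_rec$pattern <- ifelse(
      sign(pair_rec[[paste0("log2fc_", spp[1])]]) *
        sign(pair_rec[[paste0("log2fc_", spp[2])]]) < 0, "flipped",
      ifelse(pair_rec[[paste0("log2fc_", spp[1])]] > 0,
             "concordant_night", "concordant_day"))
    extra <- pair_rec[is.na(pair_rec$reference_gene) |
                        !(pair_rec$reference_gene %in% rr$reference_gene), ,
                      drop = FALSE]
    records$source <- ifelse(records$pattern %in%
                               c("flipped", "concordant_day",
                                 "concordant_night"),
                             "reference_collapse", "")
    common <- intersect(names(records), names(extra))
    if (nrow(extra))
      records <- merge(records, extra[, common, drop = FALSE],
                       all = TRUE, sort = FALSE)
  }
  enr <- NULL
  if (enrichment) {
    background <- intersect(records$reference_gene[
      !is.na(records$reference_gene)], unique(study$go$gene_id))
    background <- unique(c(background,
                           intersect(tbl$reference_gene,
                                     unique(study$go$gene_id))))
    flip_set <- intersect(records$reference_gene[records$pattern == "flipped" &
                                                   !is.na(records$reference_gene)],
                          background)
    enr <- list(
      flipped = if (length(flip_set))
        hypergeom_enrich(flip_set, background, study$go,
                         study$category_map) else NULL,
      background = background, study = flip_set)
  }
  candidates <- rank_candidates(records, study$go, study$category_map)
  net <- NULL
  if (network) {
    factors <- lapply(stats::setNames(spp, spp), function(sp)
      normalize_median_ratio(filtered[[sp]]))
    expr <- preprocess_expression(filtered[spp], factors, combined = TRUE,
                                  map = map)
    pw <- if (is.null(network_power)) pick_soft_power(expr)$power
    else network_power
    tom <- adjacency_tom(expr, power = pw)
    modules <- detect_modules(tom)
    eig <- module_eigengenes(expr, modules)
    traits <- if (ncol(eig)) module_trait(eig, attr(expr, "design")) else NULL
    net <- list(power = pw, modules = modules, eigengenes = eig,
                traits = traits, n_genes = ncol(expr))
  }
  consv <- NULL
  if (conservation) {
    prof <- column_conservation(study$family$msa, reference_id = "REF")
    blocks <- find_blocks(prof)
    muts <- focal_mutations(study$family$msa, "FOCAL_A", "FOCAL_B",
                            prof, blocks)
    consv <- list(profile = prof, blocks = blocks, mutations = muts)
  }
  list(filtered = filtered, de = de, consensus = cons, de_tables = detab,
       orthomap = orthomap, map = map, records = records,
       candidates = candidates, enrichment = enr, network = net,
       conservation = consv, config = cfg)
}

jaccard_blocks <- function(a, b, L) {
  cols <- function(bl) {
    if (is.null(bl) || !nrow(bl)) return(integer(0))
    unlist(lapply(seq_len(nrow(bl)), function(i) bl$start[i]:bl$end[i]))
  }
  ca <- cols(a); cb <- cols(b)
  if (!length(ca) && !length(cb)) return(1)
  length(intersect(ca, cb)) / length(union(ca, cb))
}

#' Score pipeline outputs against the generator's planted truth
#'
#' Sensitivity = detected flipped reference genes / planted flipped genes;
#' precision is the analogous fraction of detections that were planted
#' (reported `NA` when nothing was detected). Module agreement is the
#' adjusted Rand index over genes assigned to a non-grey module. The DE
#' type-I error is the fraction of unadjusted p-values below 0.05 among
#' planted null genes.
#'
#' @param outputs Result of [run_study_analysis()] (or a compatible list).
#' @param truth Truth table from [simulate_counts()].
#' @param family_truth Optional protein-family truth
#'   (from [simulate_study()]'s `family`).
#' @return List of class `evaluation_report`.
#' @export
evaluate_against_truth <- function(outputs, truth, family_truth = NULL) {
  planted <- truth$reference_gene[truth$de_class %in%
                                    c("flipped_coincident",
                                      "flipped_anticoincident")]
  rec <- outputs$records
  det <- unique(rec$reference_gene[rec$pattern == "flipped" &
                                     !is.na(rec$reference_gene)])
  tp <- length(intersect(det, planted))
  sens <- if (length(planted)) tp / length(planted) else NA_real_
  prec <- if (length(det)) tp / length(det) else NA_real_
  key <- truth$reference_gene[truth$is_key_gene]
  cand_rank <- NA_integer_
  if (length(key) && !is.null(outputs$candidates)) {
    i <- match(key[1], outputs$candidates$reference_gene)
    if (!is.na(i)) cand_rank <- outputs$candidates$rank[i]
  }
  ari <- NA_real_
  if (!is.null(outputs$network)) {
    mods <- outputs$network$modules
    # planted DE genes co-express by construction (they carry the planted
    # phase/flip signal) and are excluded from the module-recovery score
    de_planted <- truth$reference_gene[truth$de_class != "null"]
    keep <- names(mods)[mods != "grey" & !(names(mods) %in% de_planted)]
    if (length(keep)) {
      tm <- truth$module_id[match(keep, truth$reference_gene)]
      tm[is.na(tm)] <- "none"
      ari <- mclust::adjustedRandIndex(mods[keep], tm)
    }
  }
  enr_flag <- NA
  if (!is.null(outputs$enrichment) && !is.null(outputs$enrichment$flipped)) {
    e <- outputs$enrichment$flipped
    enr_flag <- any(e$category == "circadian" & e$adj_p < 0.05, na.rm = TRUE)
  }
  jac <- NA_real_
  if (!is.null(outputs$conservation) && !is.null(family_truth))
    jac <- jaccard_blocks(outputs$conservation$blocks, family_truth$blocks)
  type1 <- NA_real_
  if (!is.null(outputs$de) && !is.null(outputs$map)) {
    nulls <- truth$reference_gene[truth$de_class == "null" &
                                    is.na(truth$module_id)]
    ps <- unlist(lapply(outputs$de, function(x) {
      refs <- outputs$map$reference_gene[match(x$wald$gene_id,
                                               outputs$map$transcript_id)]
      x$wald$p[!is.na(refs) & refs %in% nulls]
    }))
    if (length(ps)) type1 <- mean(ps < 0.05)
  }
  structure(list(flip_sensitivity = sens, flip_precision = prec,
                 n_planted_flips = length(planted), n_detected_flips = length(det),
                 candidate_rank_key_gene = cand_rank,
                 module_ari = ari, enrichment_detected = enr_flag,
                 block_jaccard = jac, de_type1 = type1),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation against planted truth:\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the nine-stage pipeline and write all stage outputs
#'
#' Orchestrates simulate, filter, de (both flavours), orthomap, compare,
#' enrich, network, conserve, and candidates, writing flat TSV/FASTA/JSON
#' outputs so any stage can be inspected or replaced, plus a manifest with
#' the seed, a config digest, per-stage timings, output-file digests and
#' collected warnings. A stage failure halts the run with the stage named;
#' outputs of completed stages are retained.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param orthology_source,network_power Passed to [run_study_analysis()].
#' @param annotation_path Optional external gene-to-GO TSV used by the
#'   enrichment stage in place of the simulated annotation; a missing file
#'   fails that stage by name.
#' @return The manifest (list), invisibly; all outputs are under
#'   `out_dir`.
#' @export
run_pipeline <- function(cfg = sim_config(), out_dir,
                         orthology_source = "rbh", network_power = 9,
                         annotation_path = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(tool = "dielortho",
                   version = as.character(utils::packageVersion("dielortho")),
                   seed = cfg$seed, stages = list(), warnings = character(0))
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                               null = "null", force = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  manifest$config_digest <- unname(tools::md5sum(cfg_path))
  files <- character(0)
  withCallingHandlers({
    stage_env <- new.env()
    stage <- function(name, fn) {
      t0 <- proc.time()[["elapsed"]]
      res <- tryCatch(fn(), error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
      manifest$stages[[name]] <<- list(
        seconds = round(proc.time()[["elapsed"]] - t0, 3),
        outputs = res)
      files <<- c(files, res)
      res
    }
    spp <- cfg$species
    stage("simulate", function() {
      study <- simulate_study(cfg)
      stage_env$study <- study
      out <- character(0)
      for (sp in spp) {
        paths <- file.path(out_dir, paste0(c("counts_", "samples_",
                                             "lengths_"), sp, ".tsv"))
        write_counts(study$counts[[sp]], paths[1], paths[2], paths[3])
        write_fasta(study$orthology$proteomes[[sp]],
                    file.path(out_dir, paste0("proteome_", sp, ".faa")))
        out <- c(out, paths, file.path(out_dir, paste0("proteome_", sp, ".faa")))
      }
      write_fasta(study$orthology$proteomes$ref,
                  file.path(out_dir, "proteome_ref.faa"))
      write_tsv(study$go, file.path(out_dir, "go.tsv"))
      write_tsv(data.frame(go_id = names(study$category_map),
                           category = unname(study$category_map)),
                file.path(out_dir, "go_categories.tsv"))
      write_tsv(study$truth, file.path(out_dir, "truth.tsv"))
      write_fasta(study$family$msa, file.path(out_dir, "family.afa"))
      c(out, file.path(out_dir, c("proteome_ref.faa", "go.tsv",
                                  "go_categories.tsv", "truth.tsv",
                                  "family.afa")))
    })
    study <- stage_env$study
    stage("filter", function() {
      stage_env$filtered <- lapply(study$counts, filter_low_expression)
      unlist(lapply(spp, function(sp) {
        rem <- attr(stage_env$filtered[[sp]], "removed_genes")
        write_tsv(data.frame(gene_id = rem),
                  file.path(out_dir, paste0("filtered_out_", sp, ".tsv")))
      }))
    })
    stage("de", function() {
      stage_env$de <- list(); stage_env$detab <- list()
      out <- character(0)
      for (sp in spp) {
        ex <- run_de(stage_env$filtered[[sp]], "exact")
        wa <- run_de(stage_env$filtered[[sp]], "wald")
        stage_env$de[[sp]] <- list(exact = ex, wald = wa)
        cons <- method_consensus(ex, wa)
        tab <- wa
        tab$significant <- tab$gene_id %in% cons$genes
        stage_env$detab[[sp]] <- tab
        out <- c(out,
                 write_tsv(ex, file.path(out_dir, paste0("de_exact_", sp, ".tsv"))),
                 write_tsv(wa, file.path(out_dir, paste0("de_wald_", sp, ".tsv"))))
      }
      out
    })
    stage("orthomap", function() {
      if (orthology_source == "rbh") {
        og <- build_orthogroups(study$orthology$proteomes$ref,
                                study$orthology$proteomes[spp])
        stage_env$map <- og$map; stage_env$links <- og$pairwise_links
        c(write_tsv(og$groups, file.path(out_dir, "orthogroups.tsv")),
          write_tsv(og$pairwise_links,
                    file.path(out_dir, "pairwise_links.tsv")))
      } else {
        stage_env$map <- study$orthology$map; stage_env$links <- NULL
        write_tsv(stage_env$map, file.path(out_dir, "orthomap_truth.tsv"))
      }
    })
    stage("compare", function() {
      coll <- lapply(stats::setNames(spp, spp), function(sp)
        collapse_to_reference(stage_env$detab[[sp]], stage_env$map,
                              species = sp))
      tbl <- cross_species_table(coll)
      tbl <- classify_pattern(tbl, species = spp)
      tbl <- diel_coincidence(tbl, cfg$niches)
      stage_env$records <- tbl
      write_tsv(tbl, file.path(out_dir, "flips.tsv"))
    })
    stage("enrich", function() {
      go_tab <- study$go
      if (!is.null(annotation_path)) {
        if (!file.exists(annotation_path))
          stop("annotation file not found: ", annotation_path)
        go_tab <- read_go_table(annotation_path)
      }
      rec <- stage_env$records
      background <- intersect(rec$reference_gene,
                              unique(go_tab$gene_id))
      flips <- intersect(rec$reference_gene[rec$pattern == "flipped"],
                         background)
      enr <- if (length(flips))
        hypergeom_enrich(flips, background, go_tab, study$category_map)
      else data.frame()
      stage_env$enr <- enr
      write_tsv(enr, file.path(out_dir, "enrichment_flipped.tsv"))
    })
    stage("network", function() {
      factors <- lapply(stats::setNames(spp, spp), function(sp)
        normalize_median_ratio(stage_env$filtered[[sp]]))
      expr <- preprocess_expression(stage_env$filtered[spp], factors,
                                    combined = TRUE, map = stage_env$map)
      tom <- adjacency_tom(expr, power = network_power)
      modules <- detect_modules(tom)
      eig <- module_eigengenes(expr, modules)
      traits <- if (ncol(eig)) module_trait(eig, attr(expr, "design"))
      else data.frame()
      stage_env$net <- list(modules = modules)
      c(write_tsv(data.frame(reference_gene = names(modules),
                             module = unname(modules)),
                  file.path(out_dir, "modules.tsv")),
        write_tsv(data.frame(sample_id = rownames(eig), eig,
                             check.names = FALSE),
                  file.path(out_dir, "eigengenes.tsv")),
        write_tsv(traits, file.path(out_dir, "module_trait.tsv")))
    })
    stage("conserve", function() {
      prof <- column_conservation(study$family$msa, reference_id = "REF")
      blocks <- find_blocks(prof)
      muts <- focal_mutations(study$family$msa, "FOCAL_A", "FOCAL_B",
                              prof, blocks)
      stage_env$consv <- list(blocks = blocks, mutations = muts)
      c(write_tsv(prof$columns, file.path(out_dir, "conservation.tsv")),
        write_tsv(blocks, file.path(out_dir, "blocks.tsv")),
        write_tsv(muts$mutations, file.path(out_dir, "mutations.tsv")))
    })
    stage("candidates", function() {
      cand <- rank_candidates(stage_env$records, study$go,
                              study$category_map)
      write_tsv(cand, file.path(out_dir, "candidates.tsv"))
    })
  }, warning = function(w) {
    manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  digests <- tools::md5sum(unique(files[file.exists(files)]))
  manifest$digests <- stats::setNames(unname(digests),
                                      basename(names(digests)))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
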