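AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

#' Configuration for the synthetic two-species diel study
#'
#' Defines the study conditions the generator emulates: a two-species,
#' two-time-point (midday/midnight), three-replicate bulk RNA-seq design over
#' a reference-anchored orthology, with planted differential expression
#' (concordant, sign-flipped, and single-species genes), planted
#' co-expression modules, planted GO enrichment, and a simulated protein
#' family with conserved blocks and a controlled number of focal-pair
#' mutations.
#'
#' @param seed Integer seed; the same seed reproduces every generated object
#'   byte for byte.
#' @param species Two species labels; the first is diurnal, the second
#'   nocturnal.
#' @param n_ref_genes Number of reference (anchor) genes.
#' @param frac_one_to_one,frac_many_to_one,frac_species_specific Orthology
#'   class proportions; must sum to 1.
#' @param n_replicates Replicates per species and diel phase.
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters for
#'   per-gene baseline mean counts.
#' @param dispersion Negative-binomial dispersion `phi`
#'   (variance `mu + phi * mu^2`).
#' @param lib_size_mean,lib_size_cv Mean and coefficient of variation of the
#'   per-sample library scaling factor.
#' @param n_flipped Planted diel-coincident sign-flipped genes.
#' @param n_flipped_anti Planted anticoincident sign-flipped genes.
#' @param n_concordant Planted same-direction genes (split evenly between
#'   day- and night-upregulated).
#' @param n_single_species Planted genes differentially expressed in exactly
#'   one species, at the full `planted_lfc` magnitude so they qualify as
#'   strong single-species signals.
#' @param planted_lfc Total cross-species log2 fold-change separation; each
#'   species receives half (`planted_lfc / 2`) with the sign determined by
#'   the gene class.
#' @param plant_key_gene Plant one designated candidate gene
#'   (flipped-coincident, guaranteed circadian GO annotation, focal
#'   mutations in the protein family) at `key_gene_lfc`.
#' @param key_gene_lfc Effect size of the key gene (default
#'   `2 * planted_lfc`), making it the strongest cycler as expected of a
#'   top-ranked candidate.
#' @param n_modules,module_size,module_noise_sd Planted co-expression
#'   modules: module 1 tracks the day/night phase in both species, the rest
#'   are species-specific (alternating species); `module_noise_sd` is the
#'   per-gene log-scale noise around the shared latent factor.
#' @param go_terms_per_category,go_terms_other,go_base_rate,enrich_factor GO
#'   planting: per-category and uncategorized term counts, background
#'   annotation rate, and the rate multiplier applied to circadian terms on
#'   flipped-coincident genes.
#' @param ortho_sub_rate Per-residue substitution rate between a reference
#'   protein and its species transcripts.
#' @param protein_len_range Length range (aa) of reference proteins.
#' @param protein List of protein-family simulator settings: `ref_length`,
#'   `block_spans` (list of 1-based inclusive `(start, end)` conserved
#'   blocks), `in_block_sub_rate`, `out_block_sub_rate`, `n_species`,
#'   `focal_mut_in_block`, `focal_mut_out_block`.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       species = c("AN", "DR"),
                       n_ref_genes = 2000,
                       frac_one_to_one = 0.70,
                       frac_many_to_one = 0.15,
                       frac_species_specific = 0.15,
                       n_replicates = 3,
                       baseline_log_mean = log(100),
                       baseline_log_sd = 1.0,
                       dispersion = 0.1,
                       lib_size_mean = 1.0,
                       lib_size_cv = 0.15,
                       n_flipped = 50,
                       n_flipped_anti = 0,
                       n_concordant = 50,
                       n_single_species = 50,
                       planted_lfc = 6,
                       plant_key_gene = TRUE,
                       key_gene_lfc = NULL,
                       n_modules = 3,
                       module_size = 50,
                       module_noise_sd = 0.15,
                       go_terms_per_category = 3,
                       go_terms_other = 30,
                       go_base_rate = 0.02,
                       enrich_factor = 10,
                       ortho_sub_rate = 0.05,
                       protein_len_range = c(80, 200),
                       protein = list()) {
  pdef <- list(ref_length = 600,
               block_spans = list(c(101L, 240L), c(401L, 470L)),
               in_block_sub_rate = 0.02,
               out_block_sub_rate = 0.30,
               n_species = 10,
               focal_mut_in_block = 3,
               focal_mut_out_block = 20)
  user_spans <- protein[["block_spans"]]
  protein <- utils::modifyList(pdef,
                               protein[setdiff(names(protein), "block_spans")])
  if (!is.null(user_spans)) protein$block_spans <- user_spans
  cfg <- list(seed = as.integer(seed), species = species,
              niches = stats::setNames(c("diurnal", "nocturnal"), species),
              n_ref_genes = as.integer(n_ref_genes),
              frac_one_to_one = frac_one_to_one,
              frac_many_to_one = frac_many_to_one,
              frac_species_specific = frac_species_specific,
              n_replicates = as.integer(n_replicates),
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              dispersion = dispersion,
              lib_size_mean = lib_size_mean, lib_size_cv = lib_size_cv,
              n_flipped = as.integer(n_flipped),
              n_flipped_anti = as.integer(n_flipped_anti),
              n_concordant = as.integer(n_concordant),
              n_single_species = as.integer(n_single_species),
              planted_lfc = planted_lfc,
              plant_key_gene = isTRUE(plant_key_gene),
              key_gene_lfc = key_gene_lfc %||% (2 * planted_lfc),
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              module_noise_sd = module_noise_sd,
              go_terms_per_category = as.integer(go_terms_per_category),
              go_terms_other = as.integer(go_terms_other),
              go_base_rate = go_base_rate,
              enrich_factor = enrich_factor,
              ortho_sub_rate = ortho_sub_rate,
              protein_len_range = protein_len_range,
              protein = protein)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  fr <- c(cfg$frac_one_to_one, cfg$frac_many_to_one, cfg$frac_species_specific)
  if (any(fr < 0) || any(fr > 1) || abs(sum(fr) - 1) > 1e-9)
    stop("orthology class proportions must lie in [0,1] and sum to 1")
  if (length(cfg$species) != 2) stop("exactly two species are required")
  if (cfg$dispersion < 0) stop("dispersion must be non-negative")
  if (cfg$n_replicates < 2) stop("need at least 2 replicates per phase")
  n11 <- round(cfg$frac_one_to_one * cfg$n_ref_genes)
  need <- cfg$n_flipped + cfg$n_flipped_anti + cfg$n_concordant +
    cfg$n_single_species + cfg$n_modules * cfg$module_size
  if (need > n11)
    stop("infeasible planting: ", need, " one-to-one genes needed but only ",
         n11, " available")
  p <- cfg$protein
  spans <- p$block_spans
  if (length(spans)) {
    sp <- do.call(rbind, lapply(spans, as.integer))
    if (any(sp[, 1] < 1) || any(sp[, 2] > p$ref_length) ||
        any(sp[, 1] > sp[, 2]))
      stop("block_spans must lie within [1, ref_length]")
    o <- order(sp[, 1])
    sp <- sp[o, , drop = FALSE]
    if (nrow(sp) > 1 && any(sp[-1, 1] <= sp[-nrow(sp), 2]))
      stop("block_spans must be non-overlapping")
    n_in <- sum(sp[, 2] - sp[, 1] + 1)
  } else n_in <- 0
  if (p$focal_mut_in_block > n_in)
    stop("focal_mut_in_block exceeds available in-block columns")
  if (p$focal_mut_out_block > p$ref_length - n_in)
    stop("focal_mut_out_block exceeds available out-of-block columns")
  class(cfg) <- "sim_config"
  cfg
}

# vectorized random proteins: n sequences with the given lengths
random_proteins <- function(lens) {
  chars <- sample(AA20, sum(lens), replace = TRUE)
  idx <- rep.int(seq_along(lens), lens)
  vapply(split(chars, idx), paste0, "", collapse = "")
}

# substitute residues at `rate` per position, never to the same residue
mutate_proteins <- function(seqs, rate) {
  ch <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(ch)
  flat <- unlist(ch, use.names = FALSE)
  hit <- which(runif(length(flat)) < rate)
  if (length(hit)) {
    cur <- match(flat[hit], AA20)
    flat[hit] <- AA20[(cur + sample.int(19L, length(hit), replace = TRUE) - 1L) %% 20L + 1L]
  }
  idx <- rep.int(seq_along(lens), lens)
  out <- vapply(split(flat, idx), paste0, "", collapse = "")
  names(out) <- names(seqs)
  out
}

#' Simulate a reference-anchored orthology and its proteomes
#'
#' Assigns each reference gene an orthology class (one-to-one, many-to-one,
#' or species-specific) per the configured proportions, emits a transcript
#' for each species copy, and generates protein sequences: a random
#' reference protein per gene and mutated copies (at `ortho_sub_rate`) for
#' species transcripts, so reciprocal-best-hit search can recover the
#' planted map.
#'
#' @param cfg A [sim_config()].
#' @return List with `classes` (per-reference-gene class table), `map`
#'   (species, transcript_id, reference_gene), `proteomes` (named character
#'   vectors: `ref` plus one per species), and `transcript_lengths` (bp,
#'   3x protein length).
#' @export
simulate_orthology <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(derive_seed(cfg$seed, 1), {
    n <- cfg$n_ref_genes
    genes <- sprintf("REF%05d", seq_len(n))
    n_m <- round(cfg$frac_many_to_one * n)
    n_s <- round(cfg$frac_species_specific * n)
    n_1 <- n - n_m - n_s
    classes <- c(rep("one_to_one", n_1), rep("many_to_one", n_m),
                 rep("species_specific", n_s))
    host <- rep(NA_character_, n)
    if (n_s > 0)
      host[classes == "species_specific"] <-
        rep_len(cfg$species, n_s)[sample.int(n_s)]
    lens <- sample(seq(cfg$protein_len_range[1], cfg$protein_len_range[2]),
                   n, replace = TRUE)
    ref <- random_proteins(lens)
    names(ref) <- genes
    map <- list(); proteomes <- list(ref = ref)
    for (sp in cfg$species) {
      ncopy <- ifelse(classes == "many_to_one", 2L,
                      ifelse(classes == "species_specific",
                             ifelse(host == sp, 1L, 0L), 1L))
      gidx <- rep.int(seq_len(n), ncopy)
      copy_no <- sequence(ncopy)
      tid <- sprintf("%s_T%05d%s", sp, gidx, c("a", "b")[copy_no])
      prot <- mutate_proteins(stats::setNames(ref[gidx], tid),
                              cfg$ortho_sub_rate)
      proteomes[[sp]] <- prot
      map[[sp]] <- data.frame(species = sp, transcript_id = tid,
                              reference_gene = genes[gidx],
                              stringsAsFactors = FALSE)
    }
    map <- do.call(rbind, map)
    rownames(map) <- NULL
    tl <- unlist(lapply(cfg$species,
                        function(sp) nchar(proteomes[[sp]]) * 3L))
    list(classes = data.frame(reference_gene = genes,
                              orthology_class = classes,
                              host_species = host,
                              stringsAsFactors = FALSE),
         map = map, proteomes = proteomes, transcript_lengths = tl)
  })
}

#' Simulate two-species diel count matrices with planted truth
#'
#' Counts are negative binomial with mean
#' `lib_s * q_g * 2^(phase_sign * lfc / 2) * module_effect` and variance
#' `mu + phi * mu^2`; `phase_sign` is +1 at night and -1 at day, so the
#' night-over-day log2 fold change of a gene equals its planted per-species
#' `lfc`. Flipped-coincident genes are day-up in the diurnal species and
#' night-up in the nocturnal species. Module effects follow a per-sample
#' latent factor shared by the module's genes.
#'
#' @param cfg A [sim_config()].
#' @param orthology Optional result of [simulate_orthology()] (regenerated
#'   deterministically from `cfg` when omitted).
#' @return List with `counts` (named list of transcript-level
#'   [count_matrix()], one per species), `truth` (per-reference-gene truth
#'   table), and `orthology`.
#' @export
simulate_counts <- function(cfg, orthology = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(orthology)) orthology <- simulate_orthology(cfg)
  with_seed(derive_seed(cfg$seed, 2), {
    n <- cfg$n_ref_genes
    genes <- orthology$classes$reference_gene
    sp1 <- cfg$species[1]; sp2 <- cfg$species[2]  # diurnal, nocturnal
    q <- rlnorm(n, meanlog = cfg$baseline_log_mean, sdlog = cfg$baseline_log_sd)
    names(q) <- genes

    eligible <- genes[orthology$classes$orthology_class == "one_to_one"]
    n_de <- cfg$n_flipped + cfg$n_flipped_anti + cfg$n_concordant +
      cfg$n_single_species
    picked <- sample(eligible, n_de + cfg$n_modules * cfg$module_size)
    de_genes <- picked[seq_len(n_de)]
    module_genes <- picked[-seq_len(n_de)]

    de_class <- stats::setNames(rep("null", n), genes)
    lfc1 <- stats::setNames(numeric(n), genes)
    lfc2 <- stats::setNames(numeric(n), genes)
    pos <- 0L
    take <- function(k) {
      out <- de_genes[pos + seq_len(k)]
      pos <<- pos + k
      out
    }
    flip <- take(cfg$n_flipped)
    de_class[flip] <- "flipped_coincident"
    lfc1[flip] <- -cfg$planted_lfc / 2   # diurnal: day-up
    lfc2[flip] <- +cfg$planted_lfc / 2   # nocturnal: night-up
    key_gene <- NA_character_
    if (cfg$plant_key_gene) {
      if (cfg$n_flipped < 1) stop("plant_key_gene requires n_flipped >= 1")
      key_gene <- flip[1]
      lfc1[key_gene] <- -cfg$key_gene_lfc / 2
      lfc2[key_gene] <- +cfg$key_gene_lfc / 2
      # the key candidate is a robustly expressed cycler: floor its baseline
      # at the typical gene level so its strong fold change is estimable
      q[key_gene] <- max(q[key_gene], exp(cfg$baseline_log_mean))
    }
    anti <- take(cfg$n_flipped_anti)
    de_class[anti] <- "flipped_anticoincident"
    lfc1[anti] <- +cfg$planted_lfc / 2
    lfc2[anti] <- -cfg$planted_lfc / 2
    conc <- take(cfg$n_concordant)
    nday <- ceiling(cfg$n_concordant / 2)
    de_class[conc[seq_len(nday)]] <- "concordant_day"
    lfc1[conc[seq_len(nday)]] <- lfc2[conc[seq_len(nday)]] <- -cfg$planted_lfc / 2
    if (cfg$n_concordant > nday) {
      cn <- conc[(nday + 1):cfg$n_concordant]
      de_class[cn] <- "concordant_night"
      lfc1[cn] <- lfc2[cn] <- +cfg$planted_lfc / 2
    }
    single <- take(cfg$n_single_species)
    de_class[single] <- "single_species"
    if (length(single)) {
      in_sp1 <- sample(c(TRUE, FALSE), length(single), replace = TRUE)
      sgn <- sample(c(-1, 1), length(single), replace = TRUE)
      lfc1[single[in_sp1]] <- sgn[in_sp1] * cfg$planted_lfc
      lfc2[single[!in_sp1]] <- sgn[!in_sp1] * cfg$planted_lfc
    }

    module_id <- stats::setNames(rep(NA_character_, n), genes)
    module_type <- character(0)
    if (cfg$n_modules > 0) {
      module_type <- vapply(seq_len(cfg$n_modules), function(m) {
        if (m == 1) "shared_phase" else cfg$species[(m %% 2) + 1]
      }, "")
      module_id[module_genes] <- rep(sprintf("M%02d", seq_len(cfg$n_modules)),
                                     each = cfg$module_size)
    }
    load_g <- stats::setNames(runif(n, 0.8, 1.2), genes)

    lfc_by_sp <- list(lfc1, lfc2)
    names(lfc_by_sp) <- cfg$species
    sigma_lib <- sqrt(log(1 + cfg$lib_size_cv^2))
    counts <- list(); lib_by_sp <- list()
    for (sp in cfg$species) {
      sub <- orthology$map[orthology$map$species == sp, , drop = FALSE]
      phases <- rep(c("day", "night"), each = cfg$n_replicates)
      reps <- rep(seq_len(cfg$n_replicates), 2)
      sample_id <- sprintf("%s_%s%d", sp, phases, reps)
      design <- data.frame(sample_id = sample_id, species = sp,
                           diel_phase = phases,
                           activity_niche = unname(cfg$niches[sp]),
                           replicate = reps, stringsAsFactors = FALSE)
      lib <- cfg$lib_size_mean *
        exp(rnorm(length(sample_id), 0, sigma_lib) - sigma_lib^2 / 2)
      lib_by_sp[[sp]] <- stats::setNames(lib, sample_id)
      phase_sign <- ifelse(phases == "night", 1, -1)
      # module latent factor per (module, sample)
      mod_u <- NULL
      if (cfg$n_modules > 0) {
        # per-sample latent factor shared by a module's genes; phase-linked
        # modules track the day/night contrast, species-specific modules
        # combine a species offset with their own regulatory dynamics (a
        # module-specific latent factor). The latent factors of distinct
        # species modules are planted mutually orthogonal (centered
        # Gram-Schmidt) so the planted programs are independent rather than
        # chance-aligned at this small sample size.
        ns <- length(sample_id)
        mod_u <- matrix(0, cfg$n_modules, ns)
        smods <- which(module_type != "shared_phase")
        if (length(smods)) {
          Zn <- matrix(rnorm(length(smods) * ns), length(smods), ns)
          Zn <- Zn - rowMeans(Zn)
          for (i in seq_along(smods)) {
            if (i > 1) for (j in seq_len(i - 1))
              Zn[i, ] <- Zn[i, ] -
                sum(Zn[i, ] * Zn[j, ]) / sum(Zn[j, ]^2) * Zn[j, ]
          }
          Zn <- Zn / sqrt(rowSums(Zn^2) / ns) * 0.8
          for (ii in seq_along(smods)) {
            m <- smods[ii]
            mod_u[m, ] <- Zn[ii, ] + 2.5 * (module_type[m] == sp)
          }
        }
        for (m in which(module_type == "shared_phase"))
          mod_u[m, ] <- 1.25 * phase_sign + rnorm(ns, 0, 0.25)
        rownames(mod_u) <- sprintf("M%02d", seq_len(cfg$n_modules))
      }
      g <- sub$reference_gene
      base <- outer(q[g], lib)                       # transcripts x samples
      lfc_t <- lfc_by_sp[[sp]][g]
      fc <- 2^(outer(lfc_t / 2, phase_sign))
      mu <- base * fc
      mid <- module_id[g]
      has_mod <- !is.na(mid)
      if (any(has_mod)) {
        eff <- exp(load_g[g[has_mod]] * mod_u[mid[has_mod], , drop = FALSE] +
                     matrix(rnorm(sum(has_mod) * length(sample_id), 0,
                                  cfg$module_noise_sd),
                            sum(has_mod), length(sample_id)))
        mu[has_mod, ] <- mu[has_mod, ] * eff
      }
      nt <- nrow(sub)
      if (cfg$dispersion > 0)
        cts <- matrix(rnbinom(nt * length(sample_id), mu = mu,
                              size = 1 / cfg$dispersion),
                      nt, length(sample_id))
      else
        cts <- matrix(stats::rpois(nt * length(sample_id), lambda = mu),
                      nt, length(sample_id))
      dimnames(cts) <- list(sub$transcript_id, sample_id)
      lens <- orthology$transcript_lengths[sub$transcript_id]
      counts[[sp]] <- count_matrix(cts, design, lengths = lens)
    }

    truth <- data.frame(reference_gene = genes,
                        de_class = unname(de_class),
                        true_lfc_1 = unname(lfc1),
                        true_lfc_2 = unname(lfc2),
                        module_id = unname(module_id),
                        is_key_gene = genes %in% key_gene,
                        enriched_go = unname(de_class == "flipped_coincident"),
                        orthology_class = orthology$classes$orthology_class,
                        host_species = orthology$classes$host_species,
                        stringsAsFactors = FALSE)
    names(truth)[names(truth) == "true_lfc_1"] <- paste0("true_lfc_", sp1)
    names(truth)[names(truth) == "true_lfc_2"] <- paste0("true_lfc_", sp2)
    attr(truth, "module_type") <- stats::setNames(module_type,
                                                  sprintf("M%02d", seq_along(module_type)))
    list(counts = counts, truth = truth, orthology = orthology,
         params = list(q = q, lib = lib_by_sp, lfc = lfc_by_sp))
  })
}

#' Simulate gene-to-GO annotations with planted circadian enrichment
#'
#' Background reference genes receive each GO term at `go_base_rate`;
#' circadian-category terms are planted on flipped-coincident genes at
#' `enrich_factor` times the base rate, and the designated key gene is
#' guaranteed a circadian annotation.
#'
#' @param cfg A [sim_config()].
#' @param truth Truth table from [simulate_counts()].
#' @return List with `go` (gene_id, go_id, go_namespace) and `category_map`
#'   (named character, go_id -> category).
#' @export
simulate_go <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(derive_seed(cfg$seed, 3), {
    cats <- functional_categories()
    term_cat <- c(rep(cats, each = cfg$go_terms_per_category),
                  rep("other", cfg$go_terms_other))
    go_ids <- sprintf("GO:%07d", seq_along(term_cat))
    category_map <- stats::setNames(term_cat, go_ids)
    genes <- truth$reference_gene
    n <- length(genes); k <- length(go_ids)
    rate <- matrix(cfg$go_base_rate, n, k)
    circ <- which(term_cat == "circadian")
    flip <- truth$de_class == "flipped_coincident"
    rate[flip, circ] <- pmin(1, cfg$enrich_factor * cfg$go_base_rate)
    ann <- matrix(rbinom(n * k, 1, rate), n, k) == 1
    if (any(truth$is_key_gene) && length(circ))
      ann[which(truth$is_key_gene)[1], circ[1]] <- TRUE
    idx <- which(ann, arr.ind = TRUE)
    go <- data.frame(gene_id = genes[idx[, 1]], go_id = go_ids[idx[, 2]],
                     go_namespace = "BP", stringsAsFactors = FALSE)
    go <- go[order(go$gene_id, go$go_id), ]
    rownames(go) <- NULL
    list(go = validate_go_table(go), category_map = category_map)
  })
}

#' Simulate an aligned protein family with conserved blocks
#'
#' Emits a gap-free multiple sequence alignment of `n_species` sequences
#' (the first is the unmutated reference, `"REF"`) plus two focal sequences
#' (`"FOCAL_A"`, `"FOCAL_B"`). Columns inside the configured block spans
#' substitute at `in_block_sub_rate`, outside at `out_block_sub_rate`; the
#' two focal sequences differ at exactly
#' `focal_mut_in_block + focal_mut_out_block` columns, placed accordingly.
#'
#' @param cfg A [sim_config()].
#' @return List with `msa` (named character vector of aligned sequences),
#'   `blocks` (data frame of planted 1-based inclusive spans),
#'   `focal_columns` (planted focal mutation columns), and `in_block`
#'   (logical mask over columns).
#' @export
simulate_protein_family <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  p <- cfg$protein
  with_seed(derive_seed(cfg$seed, 4), {
    L <- p$ref_length
    in_block <- rep(FALSE, L)
    for (sp in p$block_spans) in_block[sp[1]:sp[2]] <- TRUE
    rate <- ifelse(in_block, p$in_block_sub_rate, p$out_block_sub_rate)
    ref <- sample(AA20, L, replace = TRUE)
    mut_seq <- function(base) {
      hit <- which(runif(L) < rate)
      out <- base
      if (length(hit)) {
        cur <- match(base[hit], AA20)
        out[hit] <- AA20[(cur + sample.int(19L, length(hit), replace = TRUE) - 1L) %% 20L + 1L]
      }
      out
    }
    seqs <- list(REF = ref)
    for (i in seq_len(p$n_species - 1))
      seqs[[sprintf("SP%02d", i + 1)]] <- mut_seq(ref)
    focal_a <- mut_seq(ref)
    focal_b <- focal_a
    # keep planted focal mutations clear of block boundaries (beyond the
    # smoothing window) so their in/out-of-block status is unambiguous
    margin <- 5L
    dist_ok <- rep(TRUE, L)
    for (sp in p$block_spans) {
      lo <- max(1L, sp[1] - margin); hi <- min(L, sp[2] + margin)
      idx <- lo:hi
      dist_ok[idx] <- idx >= sp[1] + margin & idx <= sp[2] - margin
    }
    in_ok <- which(in_block & dist_ok)
    out_ok <- which(!in_block & dist_ok)
    if (length(in_ok) < p$focal_mut_in_block ||
        length(out_ok) < p$focal_mut_out_block)
      stop("requested focal mutations exceed the available columns")
    mut_in <- sample(in_ok, p$focal_mut_in_block)
    mut_out <- sample(out_ok, p$focal_mut_out_block)
    cols <- sort(c(mut_in, mut_out))
    cur <- match(focal_b[cols], AA20)
    focal_b[cols] <- AA20[(cur + sample.int(19L, length(cols), replace = TRUE) - 1L) %% 20L + 1L]
    seqs$FOCAL_A <- focal_a
    seqs$FOCAL_B <- focal_b
    msa <- vapply(seqs, paste0, "", collapse = "")
    blocks <- do.call(rbind, lapply(p$block_spans, function(s)
      data.frame(start = s[1], end = s[2])))
    list(msa = msa, blocks = blocks, focal_columns = cols,
         in_block = in_block)
  })
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running [simulate_orthology()], [simulate_counts()],
#' [simulate_go()] and [simulate_protein_family()] under one configuration.
#'
#' @param cfg A [sim_config()].
#' @return List with `counts`, `truth`, `orthology`, `go`, `category_map`,
#'   `family`, and the `config`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  ortho <- simulate_orthology(cfg)
  sim <- simulate_counts(cfg, ortho)
  go <- simulate_go(cfg, sim$truth)
  fam <- simulate_protein_family(cfg)
  list(counts = sim$counts, truth = sim$truth, orthology = ortho,
       go = go$go, category_map = go$category_map, family = fam,
       config = cfg)
}

#' Write aligned or unaligned protein sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Read protein sequences (possibly aligned) from FASTA
#'
#' @param path Input path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
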