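wgcna_colors <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                  "black", "pink", "magenta", "purple", "greenyellow", "tan",
                  "salmon", "cyan", "midnightblue", "lightcyan", "grey60",
                  "lightgreen", "lightyellow", "royalblue", "darkred",
                  "darkgreen", "darkturquoise", "darkgrey", "orange",
                  "darkorange", "white", "skyblue", "saddlebrown",
                  "steelblue", "paleturquoise", "violet", "darkolivegreen",
                  "darkmagenta")

#' Expression matrix for network analysis
#'
#' Normalized counts transformed as `log2(count / factor + 1)` and z-scored
#' per gene; constant (zero-variance) genes are dropped with a message.
#' With two species and `combined = TRUE`, samples of both species are
#' concatenated over a shared reference-gene set: per species, each
#' reference gene is represented by its mapped transcript with the highest
#' mean normalized count.
#'
#' @param m A [count_matrix()] or (for `combined`) a named list of two.
#' @param factors Scaling factor vector, or named list of two.
#' @param combined Concatenate two species over shared reference genes.
#' @param map Transcript -> reference map (required for `combined`).
#' @param shared_genes Optional explicit reference gene set for the
#'   combined matrix (default: genes mapped in both species).
#' @return Numeric samples x genes matrix, genes z-scored (mean 0, sd 1);
#'   attribute `design` carries the row design.
#' @export
preprocess_expression <- function(m, factors, combined = FALSE, map = NULL,
                                  shared_genes = NULL) {
  if (!combined) {
    x <- t(log2(sweep(m$counts, 2, factors, "/") + 1))
    design <- m$design
  } else {
    stopifnot(is.list(m), length(m) == 2, !is.null(map))
    spp <- names(m)
    per <- lapply(spp, function(sp) {
      y <- sweep(m[[sp]]$counts, 2, factors[[sp]], "/")
      sm <- map[map$species == sp, , drop = FALSE]
      sm <- sm[sm$transcript_id %in% rownames(y), , drop = FALSE]
      mu <- rowMeans(y)[sm$transcript_id]
      o <- order(sm$reference_gene, -mu, sm$transcript_id)
      sm <- sm[o, , drop = FALSE]
      pick <- sm[!duplicated(sm$reference_gene), , drop = FALSE]
      out <- y[pick$transcript_id, , drop = FALSE]
      rownames(out) <- pick$reference_gene
      out
    })
    names(per) <- spp
    genes <- shared_genes %||% intersect(rownames(per[[1]]), rownames(per[[2]]))
    genes <- sort(genes)
    x <- t(log2(cbind(per[[1]][genes, , drop = FALSE],
                      per[[2]][genes, , drop = FALSE]) + 1))
    design <- rbind(m[[1]]$design, m[[2]]$design)
  }
  v <- apply(x, 2, var)
  drop <- v == 0 | is.na(v)
  if (any(drop)) {
    message(sum(drop), " constant gene(s) dropped before network analysis")
    x <- x[, !drop, drop = FALSE]
  }
  x <- scale(x)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  attr(x, "design") <- design
  x
}

#' Soft-threshold power by scale-free topology fit
#'
#' For each candidate power, computes the connectivity distribution of the
#' network `|cor|^beta` (or signed), bins log10 connectivity into
#' `n_bins`, and fits `log10 p(k)` on `log10 k`; the fit R-squared is the
#' scale-free topology index (set to 0 when the slope is positive). Returns
#' the smallest power reaching `r2_target`, falling back to the argmax with
#' a warning when none does.
#'
#' @param expr Samples x genes matrix from [preprocess_expression()].
#' @param powers Candidate integer powers (default 1:20).
#' @param r2_target Scale-free fit target (default 0.8).
#' @param network_type `"unsigned"` or `"signed"`.
#' @param n_bins Connectivity histogram bins (default 10).
#' @return List with `power`, `fit_table` (power, r_squared, slope,
#'   mean_k), and `reached_target`.
#' @export
pick_soft_power <- function(expr, powers = 1:20, r2_target = 0.8,
                            network_type = c("unsigned", "signed"),
                            n_bins = 10) {
  network_type <- match.arg(network_type)
  C <- cor(expr)
  diag(C) <- 0
  base <- if (network_type == "unsigned") abs(C) else (1 + C) / 2
  tab <- data.frame(power = powers, r_squared = NA_real_, slope = NA_real_,
                    mean_k = NA_real_)
  for (i in seq_along(powers)) {
    k <- rowSums(base^powers[i])
    tab$mean_k[i] <- mean(k)
    k <- k[k > 0]
    br <- seq(min(k), max(k), length.out = n_bins + 1)
    bin <- cut(k, br, include.lowest = TRUE)
    pk <- tapply(k, bin, length) / length(k)
    xk <- tapply(k, bin, mean)
    ok <- !is.na(pk) & pk > 0 & !is.na(xk) & xk > 0
    if (sum(ok) < 3) { tab$r_squared[i] <- 0; next }
    fit <- stats::lm(log10(pk[ok]) ~ log10(xk[ok]))
    sl <- stats::coef(fit)[2]
    r2 <- summary(fit)$r.squared
    tab$slope[i] <- sl
    tab$r_squared[i] <- if (is.na(sl) || sl > 0) 0 else r2
  }
  reached <- tab$power[tab$r_squared >= r2_target]
  if (length(reached)) {
    power <- min(reached); ok <- TRUE
  } else {
    warning("no candidate power reached the scale-free fit target; ",
            "using the best-fitting power")
    power <- tab$power[which.max(tab$r_squared)]; ok <- FALSE
  }
  list(power = power, fit_table = tab, reached_target = ok)
}

#' Adjacency and topological overlap matrix
#'
#' Adjacency `a_ij = |cor(x_i, x_j)|^beta` (unsigned) or
#' `((1 + cor) / 2)^beta` (signed) with zero diagonal; the topological
#' overlap `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with unit diagonal, where `k_i` is node connectivity.
#'
#' @param expr Samples x genes matrix.
#' @param power Soft-threshold power `beta`.
#' @param network_type `"unsigned"` (default) or `"signed"`.
#' @return Symmetric TOM similarity matrix in `[0, 1]` with unit diagonal.
#' @export
adjacency_tom <- function(expr, power = 9,
                          network_type = c("unsigned", "signed")) {
  network_type <- match.arg(network_type)
  C <- cor(expr)
  A <- if (network_type == "unsigned") abs(C)^power else ((1 + C) / 2)^power
  diag(A) <- 0
  k <- rowSums(A)
  num <- crossprod(A) + A
  den <- outer(k, k, pmin) + 1 - A
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(C)
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - TOM`
#' with a static cut at `cut_height` times the maximum merge height;
#' clusters smaller than `min_module_size` are set to `"grey"`
#' (unassigned). Module labels follow the conventional color sequence in
#' decreasing size order, ties broken by the smallest member id.
#'
#' @param tom TOM matrix from [adjacency_tom()].
#' @param min_module_size Smallest retained module (default 10).
#' @param cut_height Static cut as a fraction of the maximum merge height
#'   (default 0.6). At designs of a dozen samples, chance correlations of
#'   `|r| ~ 0.6-0.8` are common and give topological-overlap
#'   dissimilarities down to about 0.6-0.9, so merges above 0.6 x max are
#'   dominated by spurious attachments; genuine modules (within-module
#'   `|r| > 0.9`) merge well below it.
#' @return Named character vector of module labels per gene.
#' @export
detect_modules <- function(tom, min_module_size = 10, cut_height = 0.6) {
  d <- stats::as.dist(1 - tom)
  h <- hclust(d, method = "average")
  cl <- cutree(h, h = cut_height * max(h$height))
  genes <- colnames(tom)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  lab <- rep("grey", length(cl))
  if (length(keep)) {
    first_gene <- vapply(keep, function(k) min(genes[cl == k]), "")
    o <- keep[order(-sizes[keep], first_gene)]
    for (i in seq_along(o)) {
      nm <- if (i <= length(wgcna_colors)) wgcna_colors[i]
      else paste0("module", i)
      lab[cl == o[i]] <- nm
    }
  }
  stats::setNames(lab, genes)
}

#' Module eigengenes
#'
#' Per module, the first principal component of the z-scored member
#' submatrix, sign-oriented so its mean correlation with the members is
#' positive and scaled to unit variance.
#'
#' @param expr Samples x genes matrix.
#' @param modules Module labels from [detect_modules()]; `"grey"` is
#'   skipped.
#' @return Samples x modules matrix of eigengenes (columns mean 0, sd 1).
#' @export
module_eigengenes <- function(expr, modules) {
  mods <- setdiff(unique(modules), "grey")
  mods <- mods[order(match(mods, c(wgcna_colors,
                                   sort(setdiff(mods, wgcna_colors)))))]
  if (!length(mods))
    return(matrix(numeric(0), nrow(expr), 0,
                  dimnames = list(rownames(expr), NULL)))
  out <- vapply(mods, function(mm) {
    sub <- scale(expr[, names(modules)[modules == mm], drop = FALSE])
    e <- svd(sub, nu = 1, nv = 0)$u[, 1]
    if (mean(cor(e, sub)) < 0) e <- -e
    as.numeric(scale(e))
  }, numeric(nrow(expr)))
  rownames(out) <- rownames(expr)
  out
}

#' Module-trait correlations
#'
#' Pearson correlation of each eigengene with binary sample traits
#' (diel phase: day = 0, night = 1; species: first sorted label = 0), with
#' p-values from the t-distribution on `n - 2` degrees of freedom.
#'
#' @param eigengenes Samples x modules matrix from [module_eigengenes()].
#' @param design Sample design data frame aligned with the eigengene rows.
#' @return Data frame with `module`, `trait`, `cor`, `p`.
#' @export
module_trait <- function(eigengenes, design) {
  traits <- list(diel_phase = as.numeric(design$diel_phase == "night"))
  if (length(unique(design$species)) > 1) {
    lv <- sort(unique(design$species))
    traits$species <- as.numeric(design$species == lv[2])
  }
  n <- nrow(eigengenes)
  out <- list()
  for (tr in names(traits)) {
    r <- as.numeric(cor(eigengenes, traits[[tr]]))
    r <- pmin(pmax(r, -1), 1)
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    out[[tr]] <- data.frame(module = colnames(eigengenes), trait = tr,
                            cor = r, p = p, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
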