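#' TMM scaling factors
#'
#' Trimmed mean of M-values computed on raw counts, so the factors absorb
#' both library size and composition (size-factor semantics: dividing each
#' sample's counts by its factor puts all samples on a common effective
#' scale). The reference sample is the column whose 75th percentile of
#' counts-per-total is closest to the mean of those percentiles. Per sample,
#' the factor is `2^(weighted trimmed mean of M)` over genes nonzero in both
#' the sample and the reference, trimming `trim_m` of the M-values and
#' `trim_a` of the A-values at each end, with inverse-asymptotic-variance
#' weights `1 / (1/c_s + 1/c_r)`. Factors are rescaled so their product
#' is 1.
#'
#' @param m A [count_matrix()].
#' @param trim_m Fraction of M-values trimmed at each end (default 0.30).
#' @param trim_a Fraction of A-values trimmed at each end (default 0.05).
#' @return Named numeric vector of positive factors with attribute
#'   `method = "tmm"`.
#' @export
normalize_tmm <- function(m, trim_m = 0.30, trim_a = 0.05) {
  cts <- m$counts
  if (ncol(cts) < 2) stop("TMM requires at least 2 samples")
  if (all(cts == 0)) stop("all counts are zero")
  tot <- colSums(cts)
  q75 <- apply(sweep(cts, 2, pmax(tot, 1), "/"), 2, quantile, probs = 0.75)
  ref <- which.min(abs(q75 - mean(q75)))
  f <- rep(1, ncol(cts))
  for (s in seq_len(ncol(cts))) {
    if (s == ref) next
    both <- cts[, s] > 0 & cts[, ref] > 0
    if (!any(both)) {
      warning("sample ", colnames(cts)[s],
              " shares no nonzero gene with the reference; factor set to 1")
      next
    }
    cs <- cts[both, s]; cr <- cts[both, ref]
    M <- log2(cs) - log2(cr)
    A <- 0.5 * (log2(cs) + log2(cr))
    w <- 1 / (1 / cs + 1 / cr)
    keepM <- rank(M, ties.method = "first")
    keepA <- rank(A, ties.method = "first")
    n <- length(M)
    lo_m <- floor(n * trim_m) + 1; hi_m <- n - floor(n * trim_m)
    lo_a <- floor(n * trim_a) + 1; hi_a <- n - floor(n * trim_a)
    keep <- keepM >= lo_m & keepM <= hi_m & keepA >= lo_a & keepA <= hi_a
    if (!any(keep)) keep <- rep(TRUE, n)
    f[s] <- 2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  }
  f <- f / exp(mean(log(f)))
  structure(stats::setNames(f, colnames(cts)), method = "tmm")
}

#' Median-of-ratios scaling factors
#'
#' Per sample, the median over genes of `count[g, s] / gm_g` where `gm_g` is
#' the geometric mean of gene `g` across samples; genes with any zero are
#' excluded from the reference set. Falls back to [normalize_tmm()] with a
#' warning when no gene is nonzero in all samples.
#'
#' @param m A [count_matrix()].
#' @return Named numeric factor vector with attribute
#'   `method = "median_ratio"` (or `"tmm"` after fallback).
#' @export
normalize_median_ratio <- function(m) {
  cts <- m$counts
  allpos <- rowSums(cts == 0) == 0
  if (!any(allpos)) {
    warning("no gene is nonzero in all samples; falling back to TMM")
    return(normalize_tmm(m))
  }
  lg <- log(cts[allpos, , drop = FALSE])
  gm <- exp(rowMeans(lg))
  f <- apply(cts[allpos, , drop = FALSE] / gm, 2, median)
  structure(stats::setNames(f, colnames(cts)), method = "median_ratio")
}

#' Per-gene negative-binomial dispersion with trend shrinkage
#'
#' Method-of-moments estimate on normalized counts pooled within diel-phase
#' groups, `phi_hat = max(0, (s2 - mean) / mean^2)` with a small-sample
#' moment correction of the squared mean, shrunk toward a lowess trend of
#' `phi_hat` on log mean (floored at 1e-8) with weights
#' `df / (df + prior_df)` where `df` is the pooled residual degrees of
#' freedom.
#'
#' @param m A [count_matrix()] for one species.
#' @param factors Scaling factors from [normalize_tmm()] or
#'   [normalize_median_ratio()].
#' @param prior_df Prior degrees of freedom for trend shrinkage (default 10).
#' @return Named numeric vector of per-gene dispersions.
#' @export
estimate_dispersion <- function(m, factors, prior_df = 10) {
  y <- sweep(m$counts, 2, factors, "/")
  grp <- m$design$diel_phase
  groups <- unique(grp)
  n <- ncol(y); K <- length(groups)
  df <- n - K
  if (all(table(grp) < 2)) {
    warning("fewer than 2 replicates in every group; returning trend-only dispersions")
    df <- 0
  }
  # per-group moments so unequal group means do not masquerade as
  # dispersion: phi_hat = sum_k df_k (s2_k - mean_k) / sum_k df_k mean_k^2,
  # with the squared group mean corrected for its own sampling variance
  # (E[mean^2] = mu^2 + sigma^2/n)
  num <- 0; den <- 0
  for (g in groups) {
    idx <- grp == g
    n_k <- sum(idx); df_k <- n_k - 1
    if (df_k < 1) next
    mu_k <- rowMeans(y[, idx, drop = FALSE])
    s2_k <- rowSums((y[, idx, drop = FALSE] - mu_k)^2) / df_k
    num <- num + df_k * (s2_k - mu_k)
    den <- den + df_k * pmax(mu_k^2 - s2_k / n_k, mu_k^2 * 0.01)
  }
  mu <- rowMeans(y)
  phi_hat <- if (df > 0) pmax(0, num / den) else rep(NA_real_, nrow(y))
  phi_hat[!is.finite(phi_hat)] <- 0
  ok <- mu > 0
  trend <- rep(1e-8, nrow(y))
  if (sum(ok) >= 10 && df > 0) {
    # the trend describes the typical gene; leave out genes whose estimate
    # is extreme relative to the bulk (genuine extra-variance genes), which
    # removes negligible mass under a common-dispersion model
    cap <- 6 * max(median(phi_hat[ok]), 1e-4)
    use <- ok & phi_hat <= cap
    if (sum(use) < 10) use <- ok
    lo <- lowess(log(mu[use]), phi_hat[use], f = 0.5, iter = 0)
    trend[ok] <- pmax(1e-8, stats::approx(lo$x, lo$y, xout = log(mu[ok]),
                                          rule = 2, ties = "ordered")$y)
  }
  w <- df / (df + prior_df)
  phi <- if (df > 0) w * phi_hat + (1 - w) * trend else trend
  phi[mu == 0] <- trend[mu == 0]
  stats::setNames(pmax(phi, 0), rownames(y))
}

# conditional two-sided exact NB p-values, vectorized over genes.
# yA, yB: group totals of pseudo-counts; nA, nB: group sizes; phi: per gene.
exact_nb_pvalue <- function(yA, yB, nA, nB, phi) {
  t <- yA + yB
  G <- length(t)
  p <- rep(1, G)
  nz <- which(t > 0)
  if (!length(nz)) return(p)
  tt <- t[nz]
  gene <- rep.int(seq_along(tt), tt + 1)
  a <- sequence(tt + 1) - 1
  n <- nA + nB
  mu_g <- tt / n
  phi_g <- phi[nz]
  muA <- (nA * mu_g)[gene]; muB <- (nB * mu_g)[gene]
  pois <- phi_g < 1e-12
  lp <- numeric(length(a))
  pg <- pois[gene]
  if (any(pg)) {
    # Poisson limit: conditional distribution is binomial(t, nA/n)
    lp[pg] <- dbinom(a[pg], size = tt[gene][pg], prob = nA / n, log = TRUE)
  }
  if (any(!pg)) {
    szA <- (nA / phi_g)[gene]; szB <- (nB / phi_g)[gene]
    i <- !pg
    lp[i] <- dnbinom(a[i], mu = muA[i], size = szA[i], log = TRUE) +
      dnbinom(tt[gene][i] - a[i], mu = muB[i], size = szB[i], log = TRUE)
  }
  mx <- vapply(split(lp, gene), max, 0)
  pr <- exp(lp - mx[gene])
  tot_pr <- vapply(split(pr, gene), sum, 0)
  # index of the observed split within each gene's run of candidate splits
  run_start <- cumsum(c(1, head(tt + 1, -1)))
  obs_idx <- run_start + yA[nz]
  p_obs <- pr[obs_idx]
  le <- pr <= p_obs[gene] * (1 + 1e-10)
  p_nz <- vapply(split(pr * le, gene), sum, 0) / tot_pr
  p[nz] <- pmin(1, p_nz)
  p
}

de_result <- function(gene_id, log2fc, mean_expr, p, method,
                      alpha = 0.05, lfc_min = 2.0, flags = NULL) {
  adj_p <- adjust_bh(p)
  res <- data.frame(gene_id = gene_id, log2fc = log2fc,
                    mean_expr = mean_expr, p = p, adj_p = adj_p,
                    method = method,
                    significant = adj_p < alpha & abs(log2fc) >= lfc_min,
                    stringsAsFactors = FALSE)
  if (!is.null(flags)) res$flag <- flags
  rownames(res) <- NULL
  res
}

#' Exact conditional negative-binomial day-vs-night test
#'
#' Counts are rescaled to a common effective library size by dividing by the
#' scaling factors and rounding half-to-even; per gene, the two-sided
#' p-value is the total conditional probability of all splits of the grand
#' total between the day and night groups whose probability does not exceed
#' that of the observed split, under a negative binomial with equal means
#' and the gene's dispersion. The log2 fold change uses a +0.5 pseudo-count:
#' `log2((night mean + 0.5) / (day mean + 0.5))` on normalized counts, so a
#' positive value means night overexpression.
#'
#' @param m A [count_matrix()] for one species with both diel phases.
#' @param factors Scaling factors.
#' @param dispersion Per-gene dispersions (recycled if length 1).
#' @param alpha,lfc_min Significance thresholds applied to the BH-adjusted
#'   p-values and |log2FC| (defaults 0.05 and 2).
#' @return Data frame of per-gene results with columns `gene_id`, `log2fc`,
#'   `mean_expr`, `p`, `adj_p`, `method`, `significant`.
#' @export
exact_test <- function(m, factors, dispersion, alpha = 0.05, lfc_min = 2.0) {
  grp <- m$design$diel_phase
  if (!all(c("day", "night") %in% grp))
    stop("both day and night samples are required")
  phi <- rep_len(dispersion, nrow(m$counts))
  y <- sweep(m$counts, 2, factors, "/")
  pseudo <- round(y)
  day <- grp == "day"; night <- grp == "night"
  yA <- rowSums(pseudo[, day, drop = FALSE])
  yB <- rowSums(pseudo[, night, drop = FALSE])
  p <- exact_nb_pvalue(yA, yB, sum(day), sum(night), phi)
  mu_day <- rowMeans(y[, day, drop = FALSE])
  mu_night <- rowMeans(y[, night, drop = FALSE])
  de_result(rownames(m$counts),
            log2fc = log2((mu_night + 0.5) / (mu_day + 0.5)),
            mean_expr = rowMeans(y), p = p, method = "exact",
            alpha = alpha, lfc_min = lfc_min)
}

#' Wald test from a negative-binomial log-linear model
#'
#' Per gene, fits `log mu = b0 + b1 * night + log(factor)` by iteratively
#' reweighted least squares with the gene's dispersion; `log2fc = b1 / ln 2`
#' and the two-sided p-value comes from the normal tail of `b1 / SE(b1)`
#' with the standard error from the information matrix. Genes with all
#' counts zero are skipped with p = 1; genes with an all-zero group (perfect
#' separation) are refitted on counts + 0.5 and flagged; non-convergence
#' within `max_iter` iterations yields p = 1 and a `nonconverged` flag.
#'
#' @inheritParams exact_test
#' @param max_iter IRLS iteration cap (default 100).
#' @return Data frame as in [exact_test()] with `method = "wald"` and a
#'   `flag` column (`ok`, `pseudo`, `nonconverged`, `allzero`).
#' @export
wald_test <- function(m, factors, dispersion, alpha = 0.05, lfc_min = 2.0,
                      max_iter = 100) {
  grp <- m$design$diel_phase
  if (!all(c("day", "night") %in% grp))
    stop("both day and night samples are required")
  phi <- rep_len(dispersion, nrow(m$counts))
  y <- m$counts
  x <- as.numeric(grp == "night")
  o <- log(factors)
  G <- nrow(y); S <- ncol(y)
  flags <- rep("ok", G)
  allzero <- rowSums(y) == 0
  flags[allzero] <- "allzero"
  dayzero <- rowSums(y[, x == 0, drop = FALSE]) == 0
  nightzero <- rowSums(y[, x == 1, drop = FALSE]) == 0
  sep <- (dayzero | nightzero) & !allzero
  flags[sep] <- "pseudo"
  yfit <- y
  yfit[sep, ] <- yfit[sep, ] + 0.5
  om <- matrix(o, G, S, byrow = TRUE)
  xm <- matrix(x, G, S, byrow = TRUE)
  b0 <- log(pmax(rowMeans(sweep(yfit, 2, exp(o), "/")), 1e-8))
  b1 <- rep(0, G)
  conv <- rep(FALSE, G)
  for (it in seq_len(max_iter)) {
    eta <- pmin(b0 + b1 * xm + om, 30)
    mu <- exp(eta)
    w <- mu / (1 + phi * mu)
    z <- (eta - om) + (yfit - mu) / mu
    Sw <- rowSums(w); Swx <- rowSums(w * xm); Swxx <- Swx  # x is 0/1
    Swz <- rowSums(w * z); Swxz <- rowSums(w * xm * z)
    det <- Sw * Swxx - Swx^2
    det[det < 1e-12] <- NA
    nb1 <- (Sw * Swxz - Swx * Swz) / det
    nb0 <- (Swz - Swx * nb1) / Sw
    bad <- !is.finite(nb1) | !is.finite(nb0)
    nb1[bad] <- b1[bad]; nb0[bad] <- b0[bad]
    delta <- pmax(abs(nb1 - b1), abs(nb0 - b0))
    b0 <- nb0; b1 <- nb1
    conv <- conv | delta < 1e-8
    if (all(conv | allzero)) break
  }
  flags[!conv & !allzero & flags == "ok"] <- "nonconverged"
  eta <- pmin(b0 + b1 * xm + om, 30)
  mu <- exp(eta)
  w <- mu / (1 + phi * mu)
  Sw <- rowSums(w); Swx <- rowSums(w * xm)
  det <- Sw * Swx - Swx^2
  se <- sqrt(Sw / pmax(det, 1e-12))
  zstat <- b1 / se
  p <- 2 * pnorm(-abs(zstat))
  p[allzero | flags == "nonconverged"] <- 1
  lfc <- b1 / log(2)
  lfc[allzero] <- 0
  ynorm <- sweep(y, 2, exp(o), "/")
  de_result(rownames(y), log2fc = lfc, mean_expr = rowMeans(ynorm),
            p = p, method = "wald", alpha = alpha, lfc_min = lfc_min,
            flags = flags)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]): sorted ascending,
#' `adj_i = min_{j >= i} p_j * m / j`, capped at 1, original order restored.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values in the input order.
#' @export
adjust_bh <- function(p) p.adjust(p, method = "BH")

#' Flag significant genes, optionally within a fold-change stratum
#'
#' `significant` is `adj_p < alpha` and `|log2fc| >= lfc_min`. A one-sided
#' `stratum` window `(lo, hi]` on log2FC (e.g. `c(-Inf, -5)` for strongly
#' day-upregulated, `c(5, Inf)` for strongly night-upregulated) further
#' restricts the flags.
#'
#' @param r Data frame from [exact_test()] or [wald_test()].
#' @param alpha FDR threshold (default 0.05).
#' @param lfc_min Minimum |log2FC| (default 2, i.e. the
#'   `-2 < log2FC < 2` exclusion window).
#' @param stratum Optional numeric length-2 log2FC window (inclusive
#'   bounds).
#' @return `r` with the `significant` column recomputed.
#' @export
call_significant <- function(r, alpha = 0.05, lfc_min = 2.0, stratum = NULL) {
  sig <- r$adj_p < alpha & abs(r$log2fc) >= lfc_min
  if (!is.null(stratum))
    sig <- sig & r$log2fc >= stratum[1] & r$log2fc <= stratum[2]
  r$significant <- sig
  r
}

#' Cross-method consensus of significant genes
#'
#' Intersection of the significant gene ids from two method flavours for one
#' species, mirroring the practice of retaining only genes recovered by both
#' differential-expression tools.
#'
#' @param a,b Result data frames from the two methods.
#' @return List with `genes` (intersection), `n_a`, `n_b`, `n_shared`.
#' @export
method_consensus <- function(a, b) {
  sa <- a$gene_id[a$significant]
  sb <- b$gene_id[b$significant]
  shared <- intersect(sa, sb)
  list(genes = shared, n_a = length(sa), n_b = length(sb),
       n_shared = length(shared))
}
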