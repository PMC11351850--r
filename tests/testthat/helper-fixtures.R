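# shared fixtures and independent oracles used across test files

tiny_design <- function(species = "SP", niche = "diurnal", n_rep = 2) {
  phases <- rep(c("day", "night"), each = n_rep)
  data.frame(sample_id = sprintf("%s_%s%d", species, phases,
                                 rep(seq_len(n_rep), 2)),
             species = species, diel_phase = phases,
             activity_niche = niche, replicate = rep(seq_len(n_rep), 2),
             stringsAsFactors = FALSE)
}

tiny_cm <- function(counts, n_rep = ncol(counts) / 2, lengths = NULL,
                    species = "SP") {
  design <- tiny_design(species = species, n_rep = n_rep)
  colnames(counts) <- design$sample_id
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  count_matrix(counts, design, lengths = lengths)
}

# NB counts for one species with a planted night-vs-day log2 fold change
simulate_de_counts <- function(seed, n_genes, mu = 100, lfc = 0, phi = 0.1,
                               n_rep = 3) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    mu_day <- mu * 2^(-lfc / 2)
    mu_night <- mu * 2^(lfc / 2)
    cts <- cbind(matrix(rnbinom(n_genes * n_rep, mu = mu_day, size = 1 / phi),
                        n_genes),
                 matrix(rnbinom(n_genes * n_rep, mu = mu_night, size = 1 / phi),
                        n_genes))
    tiny_cm(cts, n_rep = n_rep)
  })
}

# Independent oracle for the conditional exact NB test: the group-total
# distribution is built by explicit numeric convolution of per-sample NB
# probability vectors (no reliance on NB size-additivity), conditioned on
# the grand total.
oracle_exact_p <- function(yA, yB, nA, nB, phi) {
  t <- yA + yB
  if (t == 0) return(1)
  mu <- t / (nA + nB)
  pmf1 <- if (phi < 1e-12) stats::dpois(0:t, mu)
  else dnbinom(0:t, mu = mu, size = 1 / phi)
  conv_n <- function(p, n) {
    out <- c(1, rep(0, t))
    for (i in seq_len(n)) out <- stats::convolve(out, rev(p), type = "open")[1:(t + 1)]
    out
  }
  pA <- conv_n(pmf1, nA)
  pB <- conv_n(pmf1, nB)
  joint <- pA * rev(pB)           # P(A = a) * P(B = t - a)
  joint <- joint / sum(joint)
  obs <- joint[yA + 1]
  sum(joint[joint <= obs * (1 + 1e-10)])
}

# Brute-force hypergeometric upper tail via binomial coefficients
oracle_hyper_p <- function(k, K, N, n) {
  ks <- k:min(n, K)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

random_protein <- function(len) {
  paste0(sample(c("A","R","N","D","C","Q","E","G","H","I",
                  "L","K","M","F","P","S","T","W","Y","V"),
                len, replace = TRUE), collapse = "")
}

mutate_protein_str <- function(seq, rate) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(aa, ch[i]), 1)
  paste0(ch, collapse = "")
}
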