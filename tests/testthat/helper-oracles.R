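# Independent reference implementations used as oracles. These follow the
# definitions step by step and stay deliberately naive; they must never
# call into the package's own engines.

# ssGSEA running-sum integral, computed with an explicit per-position loop.
naive_ssgsea <- function(values, set_genes, alpha = 0.25) {
  n <- length(values)
  ord <- order(-values, names(values))
  genes_sorted <- names(values)[ord]
  in_set <- genes_sorted %in% set_genes
  n_in <- sum(in_set)
  w_sum_in <- 0
  for (i in seq_len(n)) if (in_set[i]) w_sum_in <- w_sum_in + (n - i + 1)^alpha
  es <- 0
  run_in <- 0
  run_out <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) run_in <- run_in + (n - i + 1)^alpha / w_sum_in
    else run_out <- run_out + 1 / (n - n_in)
    es <- es + (run_in - run_out)
  }
  es
}

# AUC by brute-force pair counting with half credit for ties.
auc_brute <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Kaplan-Meier by explicit product over distinct event times.
km_brute <- function(time, event, at) {
  ev_times <- sort(unique(time[event]))
  s <- 1
  for (t in ev_times[ev_times <= at]) {
    d <- sum(time == t & event)
    r <- sum(time >= t)
    s <- s * (1 - d / r)
  }
  s
}

# Agglomerative complete-linkage merge heights recomputed from the
# distance matrix, lowest-index pair first on ties.
complete_linkage_heights <- function(x) {
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Small cohort designs keep the simulation-heavy tests quick while
# preserving the default effect structure.
small_design <- function(n_genes = 600, seed = 1L, ...) {
  cohort_design(
    n_genes = n_genes,
    module_sizes = list(emt_angio = 40, immune = 30,
                        metabolism_cellcycle = 30, ln_fibrosis = 9),
    seed = seed, ...)
}

null_design <- function(n_genes = 600, seed = 1L) {
  small_design(
    n_genes = n_genes, seed = seed,
    effect_log2fc = list(emt_angio = 0, immune = 0,
                         metabolism_cellcycle = 0, ln_fibrosis = 0))
}

# Random named TPM-like sample for ssGSEA instances.
random_sample_values <- function(n) {
  v <- round(stats::rexp(n, 0.1), 2)  # rounding induces occasional ties
  names(v) <- sprintf("g%02d", sample(n))
  v
}
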