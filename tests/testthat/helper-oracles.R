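# Independent oracles and small random generators shared across tests.

# All downward paths from `from` to the disease node of `dag`.
enumerate_paths <- function(dag, from) {
  if (from == dag$disease) return(list(from))
  out <- list()
  for (child in dag$children[[from]]) {
    for (p in enumerate_paths(dag, child)) out <- c(out, list(c(from, p)))
  }
  out
}

# Brute-force semantic contribution: max over all downward paths of the
# per-edge factor product, multiplied right-to-left (innermost edge first)
# so it is comparable to the sweep at full precision.
sv_bruteforce <- function(dag, factor_at) {
  one <- function(t) {
    paths <- enumerate_paths(dag, t)
    best <- -Inf
    for (p in paths) {
      v <- 1
      if (length(p) > 1L)
        for (i in rev(seq_len(length(p) - 1L))) v <- factor_at(p[i], p[i + 1L]) * v
      best <- max(best, v)
    }
    best
  }
  stats::setNames(vapply(dag$nodes, one, numeric(1)), dag$nodes)
}

# Brute-force Mann-Whitney AUC by O(n^2) pair counting.
auc_bruteforce <- function(pos, neg) {
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Random disease universe: `n` diseases with 1-2 tree numbers over a tiny
# segment alphabet, giving DAGs of at most ~12 nodes.
random_universe <- function(n = 4L, max_depth = 4L) {
  segs <- c("A1", "A2", "B1", "B2", "C1")
  recs <- list()
  for (i in seq_len(n)) {
    k <- sample(1:2, 1)
    tns <- unique(vapply(seq_len(k), function(j) {
      depth <- sample.int(max_depth, 1)
      paste(sample(segs, depth, replace = TRUE), collapse = ".")
    }, character(1)))
    recs[[sprintf("dis%02d", i)]] <- disease_record(sprintf("dis%02d", i), tns)
  }
  recs
}

# Random symmetric positive-definite matrix with unit diagonal (a valid
# similarity matrix).
random_similarity <- function(n, names = sprintf("x%02d", seq_len(n))) {
  A <- matrix(stats::runif(n * n), n, n)
  S <- crossprod(A) + n * diag(n)           # SPD, diagonally dominant
  D <- diag(1 / sqrt(diag(S)))
  S <- D %*% S %*% D                        # unit diagonal, entries in [0,1]
  S <- (S + t(S)) / 2
  dimnames(S) <- list(names, names)
  S
}

random_score_matrix <- function(nl, nd) {
  matrix(stats::runif(nl * nd), nl, nd,
         dimnames = list(sprintf("l%02d", seq_len(nl)),
                         sprintf("d%02d", seq_len(nd))))
}

small_planted_spec <- function(seed) {
  fixture_spec(n_diseases = 40L, n_lncrnas = 30L, tree_depth = 4L,
               n_roots = 2L, n_blocks = 3L,
               density_in = 0.5, density_out = 0.05, seed = seed)
}

# Full small pipeline inputs for a given seed.
planted_case <- function(seed, spec = small_planted_spec(seed),
                         params = model_params()) {
  dat <- simulate_dataset(spec)
  Sd <- disease_similarity_matrix(dat$records, params)
  list(records = dat$records, Y = dat$Y,
       Sd = Sd[colnames(dat$Y), colnames(dat$Y)], params = params)
}
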