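# Independent oracles, deliberately avoiding phyper()/dhyper()/choose().

# Hypergeometric pmf by sequential-draw dynamic programming: draw n items
# one at a time from N containing K successes; P(success | i drawn, k
# successes so far) = (K - k) / (N - i).
hyper_pmf_dp <- function(N, K, n) {
  P <- 1  # P[k + 1] = P(X = k) after i draws
  if (n == 0L) return(P)
  for (i in seq_len(n) - 1L) {
    k <- seq_along(P) - 1L
    p_succ <- (K - k) / (N - i)
    P <- c(P * (1 - p_succ), 0) + c(0, P * p_succ)
  }
  P
}

hyper_upper_tail_dp <- function(k, N, K, n) {
  pmf <- hyper_pmf_dp(N, K, n)
  sum(pmf[(k + 1L):length(pmf)])
}

# Exhaustive-enumeration upper tail for small N: enumerate every possible
# draw of n items from N, count those overlapping the first K items by
# >= k.
hyper_upper_tail_enum <- function(k, N, K, n) {
  if (n == 0L) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Literal Benjamini-Hochberg step-up definition:
# q_i = min over j with p_(j) >= p_i of (m * p_(j) / rank_j), clipped to 1.
bh_literal <- function(p) {
  m <- length(p)
  sp <- sort(p)
  vapply(p, function(pi) {
    js <- which(sp >= pi - 1e-15)
    min(1, min(m * sp[js] / js))
  }, numeric(1))
}

# Small deterministic expression matrix: `effects` is a named list
# gene -> log2 shift added to treated samples; baseline log2 = base.
toy_matrix <- function(genes = paste0("g", 1:6), effects = list(),
                       timepoints = c(8), replicates = 4, noise_sd = 0.1,
                       base = 4, seed = 42, namespace = "symbol") {
  set.seed(seed)
  samples <- expand.grid(replicate = seq_len(replicates),
                         timepoint = timepoints,
                         condition = c("control", "treated"),
                         stringsAsFactors = FALSE)[, c("condition",
                                                       "timepoint",
                                                       "replicate")]
  lv <- matrix(rnorm(length(genes) * nrow(samples), base, noise_sd),
               nrow = length(genes), dimnames = list(genes, NULL))
  for (g in names(effects))
    lv[g, samples$condition == "treated"] <-
      lv[g, samples$condition == "treated"] + effects[[g]]
  expression_matrix(2^lv, samples, namespace = namespace)
}

toy_collection <- function(terms, universe = NULL, name = "toy",
                           namespace = "symbol") {
  gene_set_collection(terms, universe = universe, name = name,
                      namespace = namespace)
}

gl <- function(members, ...) gene_list(members, ...)
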