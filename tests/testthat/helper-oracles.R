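# Independent brute-force oracles used to check the exact statistics and the
# clustering. These deliberately avoid the code paths they validate.

# single-linkage partition by O(n^2) transitive closure over |xi - xj| <= gap
brute_single_linkage <- function(pos, gap = 24) {
  n <- length(pos)
  adj <- abs(outer(pos, pos, "-")) <= gap
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      m <- min(comp[adj[i, ]])
      if (m < comp[i]) {
        comp[comp == comp[i]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# two-sided Fisher p by full hypergeometric enumeration over one margin
enum_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a)
    choose(r1, a) * choose(r2, c1 - a), 0)
  probs <- probs / sum(probs)
  obs <- probs[tab[1, 1] - lo + 1]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# two-sided binomial p: sum of outcome probabilities <= observed
enum_binom_p <- function(k, n, p0) {
  d <- dbinom(0:n, n, p0)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# two-sided Wilcoxon rank-sum p by full enumeration of group assignments
enum_wilcox_p <- function(x, y) {
  v <- c(x, y)
  n1 <- length(x)
  r <- rank(v)
  obs <- sum(r[seq_len(n1)])
  ew <- n1 * (length(v) + 1) / 2
  idx <- utils::combn(length(v), n1)
  ws <- colSums(matrix(r[idx], nrow = n1))
  mean(abs(ws - ew) >= abs(obs - ew) - 1e-9)
}

# Benjamini-Hochberg by direct step-up arithmetic
enum_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
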