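# Independent brute-force oracles. These deliberately re-derive every
# statistic from first principles (enumeration / tail sums) and share no
# code with the package implementations they check.

# Two-sided Fisher p by full hypergeometric enumeration over the table's
# margins: sum the probabilities of all tables as or less probable than the
# observed one.
oracle_fisher_p <- function(a, b, c, d) {
  K <- a + c          # target-set size
  n <- a + b          # selected size
  N <- a + b + c + d  # universe
  lo <- max(0L, K + n - N)
  hi <- min(K, n)
  probs <- stats::dhyper(lo:hi, K, N - K, n)
  p_obs <- stats::dhyper(a, K, N - K, n)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# One-tailed (second group larger) rank-sum p by full enumeration of all
# choose(m+n, m) group assignments.
oracle_wilcox_p <- function(a, b) {
  x <- c(a, b)
  m <- length(a)
  r <- rank(x)
  w_obs <- sum(r[seq_len(m)])
  combos <- utils::combn(length(x), m)
  w_all <- apply(combos, 2, function(i) sum(r[i]))
  mean(w_all <= w_obs)  # small rank-sum of group a <=> b larger
}

# Two-sided exact binomial p against 0.5 as a doubled tail sum, capped at 1.
oracle_binom_p <- function(k, n) {
  lo <- min(k, n - k)
  min(1, 2 * stats::pbinom(lo, n, 0.5))
}

# Literal reimplementation of the two transition-calling rules.
oracle_transition <- function(beta_t, stable_state, normal_mean,
                              lower = 0.25, upper = 0.7, buffer = 0.10) {
  if (is.na(beta_t)) return(NA_character_)
  st <- if (beta_t < lower) 0L else if (beta_t <= upper) 1L else 2L
  if (st == stable_state) return("none")
  if (abs(beta_t - normal_mean) < buffer) return("none")
  if (stable_state == 0L) return("0->1/2")
  if (stable_state == 1L && st == 2L) return("1->2")
  if (stable_state == 1L && st == 0L) return("1->0")
  "2->0/1"
}

# AUC by exhaustive pair concordance (ties count half).
oracle_auc <- function(pos, neg) {
  pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(pairs)
}
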