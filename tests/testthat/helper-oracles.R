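# Independent brute-force oracles used to freeze expected values.

# Mann-Whitney U of the first sample by direct pair counting.
oracle_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Exact two-sided p by enumerating all group assignments of the pooled
# values, recomputing U by pair counting for each.
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  combs <- utils::combn(length(pooled), n1)
  u_all <- apply(combs, 2, function(idx) oracle_u(pooled[idx], pooled[-idx]))
  u_obs <- oracle_u(x, y)
  eps <- 1e-9
  min(1, 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps)))
}

oracle_rank_biserial <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  fav <- sum(outer(x, y, ">"))
  unfav <- sum(outer(x, y, "<"))
  (fav - unfav) / (n1 * n2)
}

# Spearman rho via the classical sum-of-squared-rank-differences formula
# (tie-free data only).
oracle_spearman_d2 <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Random hypnogram stage sequence.
random_stages <- function(n, p_w = 0.3) {
  sample(SLEEP_STAGES, n, replace = TRUE,
         prob = c(p_w, rep((1 - p_w) / 4, 4)))
}

# Alpha burst schedule covering the given micro-epoch indices (1-based),
# each burst spanning 2.2 s of its 3-s micro-epoch.
alpha_schedule_for <- function(epochs) {
  if (!length(epochs)) return(NULL)
  data.frame(start = (epochs - 1) * 3 + 0.3, end = (epochs - 1) * 3 + 2.5)
}

# A well-mixed 5x5 generator chain with all transitions possible.
mixed_chain <- function() {
  m <- rbind(c(0.50, 0.20, 0.15, 0.10, 0.05),
             c(0.10, 0.45, 0.25, 0.10, 0.10),
             c(0.05, 0.10, 0.60, 0.15, 0.10),
             c(0.05, 0.05, 0.20, 0.60, 0.10),
             c(0.10, 0.05, 0.10, 0.05, 0.70))
  dimnames(m) <- list(SLEEP_STAGES, SLEEP_STAGES)
  m
}
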