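# Small deterministic fixtures shared across test files.

# A tiny two-group cohort where ff separates MASH perfectly and a second
# variable is pure noise.
toy_cohort <- function(n_neg = 30, n_pos = 10, seed = 99) {
  set.seed(seed)
  tibble::tibble(
    id = sprintf("T%02d", seq_len(n_neg + n_pos)),
    group = factor(rep(c("NoS", "MASH"), c(n_neg, n_pos)),
                   levels = c("NoS", "MASLD", "MASH")),
    mash = rep(c(FALSE, TRUE), c(n_neg, n_pos)),
    # ranges chosen so any train-subset midpoint threshold still separates
    ff = c(runif(n_neg, 0.5, 4), runif(n_pos, 8, 11)),
    noise = rnorm(n_neg + n_pos)
  )
}

# Brute-force pairwise AUC oracle: concordant pairs + half ties.
auc_pairs <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  grid <- outer(pos, neg, "-")
  (sum(grid > 0) + 0.5 * sum(grid == 0)) / length(grid)
}

# Direct log-likelihood-difference oracle for the G2 of a 2x2 table.
g2_loglik_oracle <- function(tab) {
  n <- sum(tab)
  ll <- function(p) sum(ifelse(tab > 0, tab * log(p), 0))
  p_sat <- tab / n
  p_ind <- outer(rowSums(tab), colSums(tab)) / n^2
  2 * (ll(p_sat) - ll(p_ind))
}
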