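# small generic feature tables for preprocessing / GA tests

# k-variable two-class table: variable 1 shifted by `shift` SDs between
# classes, remaining variables pure noise
toy_table <- function(n_per_class = 30, k = 4, shift = 5, seed = 1) {
  set.seed(seed)
  lab <- rep(c("natural", "random"), each = n_per_class)
  cols <- lapply(seq_len(k), function(j) {
    mu <- if (j == 1) ifelse(lab == "natural", shift, 0) else 0
    rnorm(2 * n_per_class, mu, 1)
  })
  names(cols) <- paste0("v", seq_len(k))
  cbind(data.frame(id = sprintf("p%04d", seq_len(2 * n_per_class)),
                   stringsAsFactors = FALSE),
        as.data.frame(cols),
        data.frame(label = lab, stringsAsFactors = FALSE))
}

# exact two-sided rank-sum p-value by enumerating all C(n1+n2, n1) splits
exact_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  u_all <- apply(combs, 2, function(idx) sum(ranks[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}
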