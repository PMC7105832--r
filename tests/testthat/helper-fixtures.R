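# Shared fixture builders: everything is generated in code at test time.

# two-attribute toy: three items (A1, A2, A1+A2)
tiny_qmatrix <- function() {
  as_qmatrix(rbind(c(1, 0), c(0, 1), c(1, 1)))
}

tiny_item_params <- function() {
  list(item_params(-1.5, main_effects = 2.5),
       item_params(-1.0, main_effects = 2.0),
       item_params(-2.0, main_effects = 1.2, interactions = c("1,2" = 1.5)))
}

# short two-chain schedule for fast fits
quick_schedule <- function(iterations = 600, burnin = 300, thin = 2) {
  chain_schedule(iterations, burnin, thin, chains = 2)
}

# exact class posterior for standard-model data at given kernels and weights
enum_class_posterior <- function(ratings, qmatrix, item_params, w = NULL) {
  pat <- attribute_patterns(ncol(qmatrix))
  C <- nrow(pat)
  if (is.null(w)) w <- rep(1 / C, C)
  N <- max(ratings$ratee)
  ll <- matrix(log(w), N, C, byrow = TRUE)
  for (c in seq_len(C)) {
    p <- vapply(seq_len(nrow(qmatrix)), function(j)
      lcdm_prob(item_params[[j]], pat[c, ], qmatrix[j, ]), 0)
    pr <- p[ratings$item]
    contrib <- ifelse(ratings$score == 1, log(pr), log(1 - pr))
    ll[, c] <- ll[, c] + as.numeric(rowsum(contrib, ratings$ratee))
  }
  mx <- apply(ll, 1, max)
  pr <- exp(ll - mx)
  pr / rowSums(pr)
}
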