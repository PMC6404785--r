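# Independent brute-force implementations used as oracles. These share no
# code with the package: distances are double loops, orders are R's stable
# order(), neighbour weights are walked explicitly.

oracle_dist <- function(a, b) {
  out <- matrix(NA_real_, nrow(a), nrow(b))
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      out[i, j] <- sqrt(sum((a[i, ] - b[j, ])^2))
  out
}

# class-1 probability by full sort; ties at the k-th rank go to the lowest
# training index because order() is stable
oracle_knn_prob <- function(train_x, train_y, queries, k) {
  vapply(seq_len(nrow(queries)), function(i) {
    d <- vapply(seq_len(nrow(train_x)), function(j)
      sqrt(sum((queries[i, ] - train_x[j, ])^2)), numeric(1L))
    mean(train_y[order(d)[seq_len(k)]])
  }, numeric(1L))
}

# weighted variant: counts[j] copies of training point j take part
oracle_knn_prob_weighted <- function(train_x, train_y, counts, queries, k) {
  vapply(seq_len(nrow(queries)), function(i) {
    d <- vapply(seq_len(nrow(train_x)), function(j)
      sqrt(sum((queries[i, ] - train_x[j, ])^2)), numeric(1L))
    ord <- order(d)
    taken <- 0L
    s1 <- 0
    for (j in ord) {
      if (counts[j] <= 0L) next
      take <- min(counts[j], k - taken)
      s1 <- s1 + take * train_y[j]
      taken <- taken + take
      if (taken >= k) break
    }
    s1 / k
  }, numeric(1L))
}

oracle_vote <- function(member_probs) {
  votes <- colMeans(member_probs > 0.5)
  out <- as.integer(votes > 0.5)
  tie <- votes == 0.5
  out[tie] <- as.integer(colMeans(member_probs)[tie] > 0.5)
  out
}

# two well-separated Gaussian blobs: any reasonable classifier scores 0
make_separable <- function(n_per_class = 30L, d = 4L, gap = 20) {
  x <- rbind(matrix(rnorm(n_per_class * d), ncol = d),
             matrix(rnorm(n_per_class * d, mean = gap), ncol = d))
  knn_dataset(x, rep(c(0L, 1L), each = n_per_class))
}

make_random_dataset <- function(n, d) {
  knn_dataset(matrix(rnorm(n * d), n, d), rbinom(n, 1L, 0.5))
}
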