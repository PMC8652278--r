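# Shared fixture builders. Everything is generated in code at test time.

# strip the simmat class/attributes down to a plain labelled matrix
unclass_mat <- function(x) {
  attributes(x) <- list(dim = dim(x), dimnames = dimnames(x))
  x
}

# random symmetric non-negative matrix with labels
random_simmat <- function(d, seed, kind = "similarity") {
  set.seed(seed)
  w <- matrix(stats::runif(d * d), d, d)
  m <- (w + t(w)) / 2
  dimnames(m) <- list(paste0("s", seq_len(d)), paste0("s", seq_len(d)))
  similarity_matrix(m, kind = kind)
}

# random symmetric PSD non-negative matrix (B B' with non-negative B)
random_psd_simmat <- function(d, seed) {
  set.seed(seed)
  b <- matrix(stats::runif(d * d), d, d)
  m <- b %*% t(b)
  dimnames(m) <- list(paste0("s", seq_len(d)), paste0("s", seq_len(d)))
  similarity_matrix(m, kind = "similarity")
}

# noiseless planted block model Y = A* X* A*' with one-hot A*
planted_block_model <- function(d = 30, k = 3, seed = 1) {
  set.seed(seed)
  a <- mixture_assignment(d, k)
  x <- diag(stats::runif(k, 4, 8))
  x[upper.tri(x)] <- stats::runif(k * (k - 1) / 2, 0, 1)
  x[lower.tri(x)] <- t(x)[lower.tri(x)]
  y <- a %*% x %*% t(a)
  list(a = a, x = x, y = y,
       partition = apply(a, 1, which.max))
}

# adjusted Rand index between two labelled partitions
partition_agreement <- function(p1, p2) {
  mclust::adjustedRandIndex(p1, p2)
}

argmax_partition <- function(a) apply(a, 1L, which.max)

random_features <- function(d, L, seed) {
  set.seed(seed)
  matrix(stats::rnorm(d * L), d, L,
         dimnames = list(sprintf("s%03d", seq_len(d)), paste0("f", seq_len(L))))
}
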