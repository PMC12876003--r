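# Independent oracles used across the suite. These deliberately avoid the
# package's closed-form code paths.

# truncated Neumann series sum_{k=1..K} D^k
neumann_total_influence <- function(D, K = 50) {
  acc <- matrix(0, nrow(D), ncol(D))
  P <- diag(nrow(D))
  for (k in seq_len(K)) {
    P <- P %*% D
    acc <- acc + P
  }
  acc
}

# dominant eigenvector of a column-stochastic matrix by plain power iteration
power_iteration_weights <- function(W, iters = 5000) {
  v <- rep(1 / nrow(W), nrow(W))
  for (i in seq_len(iters)) v <- as.vector(W %*% v)
  v / sum(v)
}

# abscissa of the maximum-membership crossing of the descending conservative
# edge (from (mid,1) to (high,0)) and the ascending optimistic edge (from
# (low,0) to (mid,1)), found numerically
tfn_crossing_oracle <- function(cons, opt) {
  mu_desc <- function(x) (cons$high - x) / (cons$high - cons$mid)
  mu_asc <- function(x) (x - opt$low) / (opt$mid - opt$low)
  stats::uniroot(function(x) mu_desc(x) - mu_asc(x),
                 lower = min(opt$low, cons$mid), upper = max(cons$high, opt$mid),
                 tol = 1e-12)$root
}

tfn <- function(low, mid, high) {
  structure(list(low = low, mid = mid, high = high), class = "tfn")
}

# small random framework: dimension sizes drawn in 1..3
random_framework <- function(K = 3, seed = 1) {
  set.seed(seed)
  sizes <- sample(1:3, K, replace = TRUE)
  dims <- data.frame(code = paste0("D", seq_len(K)),
                     name = paste("dim", seq_len(K)))
  crit <- data.frame(
    code = paste0("C", unlist(lapply(seq_len(K), function(d) {
      paste0(d, seq_len(sizes[d]))
    }))),
    name = "c",
    dimension = rep(paste0("D", seq_len(K)), times = sizes))
  criteria_framework(dims, crit)
}

# random normalized-direct-style matrix with row sums bounded by rho
random_contraction <- function(n, rho = 0.9, seed = 1) {
  set.seed(seed)
  A <- matrix(stats::runif(n * n), n, n)
  diag(A) <- 0
  A / max(rowSums(A)) * rho
}

# random strictly positive column-stochastic matrix
random_column_stochastic <- function(n, seed = 1) {
  set.seed(seed)
  W <- matrix(stats::runif(n * n, 0.05, 1), n, n)
  sweep(W, 2, colSums(W), "/")
}

# the printed per-panel and integrated gap columns of the bundled case table
case_printed_gaps <- function() {
  list(
    resident = c(C11 = 0.284, C12 = 0.481, C13 = 0.384, C21 = 0.582,
                 C22 = 0.196, C31 = 0.383, C32 = 0.483, C41 = 0.677,
                 C42 = 0.584, C51 = 0.721, C52 = 0.284, C53 = 0.381,
                 C54 = 0.784, C61 = 0.482, C62 = 0.676, C63 = 0.742),
    expert = c(C11 = 0.200, C12 = 0.370, C13 = 0.270, C21 = 0.280,
               C22 = 0.130, C31 = 0.200, C32 = 0.300, C41 = 0.380,
               C42 = 0.480, C51 = 0.610, C52 = 0.210, C53 = 0.310,
               C54 = 0.710, C61 = 0.310, C62 = 0.400, C63 = 0.500),
    integrated = c(C11 = 0.279, C12 = 0.474, C13 = 0.377, C21 = 0.562,
                   C22 = 0.192, C31 = 0.371, C32 = 0.471, C41 = 0.657,
                   C42 = 0.577, C51 = 0.713, C52 = 0.279, C53 = 0.377,
                   C54 = 0.779, C61 = 0.471, C62 = 0.658, C63 = 0.726),
    dim_integrated = c(D1 = 0.370, D2 = 0.395, D3 = 0.411, D4 = 0.617,
                      D5 = 0.459, D6 = 0.629))
}
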