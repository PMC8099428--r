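# Shared builders for small test objects. Everything is generated in code;
# no fixture files.

# a tiny trajectory with known coordinates: `frames` is a list of
# atoms x 3 matrices
toy_trajectory <- function(frames, atoms = NULL, frame_interval = 1) {
  arr <- array(0, c(length(frames), nrow(frames[[1]]), 3))
  for (i in seq_along(frames)) arr[i, , ] <- frames[[i]]
  trajectory(arr, atoms = atoms, frame_interval = frame_interval)
}

# 4-atom square in the xy plane
square_frame <- function(shift = c(0, 0, 0)) {
  base <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  sweep(base, 2, shift, "+")
}

rotate_z <- function(coords, theta) {
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta),  cos(theta), 0),
             c(0, 0, 1))
  coords %*% t(R)
}

# simulate a discrete Markov chain from transition matrix T (1-based labels)
simulate_chain <- function(T, n, x0 = 1L, seed = 1L) {
  withr::with_seed(seed, {
    k <- nrow(T)
    x <- integer(n)
    x[1] <- x0
    cum <- apply(T, 1, cumsum)  # column s = cumsum of row s
    u <- runif(n)
    for (t in 2:n) x[t] <- findInterval(u[t], cum[, x[t - 1]]) + 1L
    x
  })
}

# block-structured metastable reversible chain: `sizes` blocks, in-block
# mixing strong, between-block coupling eps
block_chain <- function(sizes, eps = 1e-3) {
  k <- sum(sizes)
  block <- rep(seq_along(sizes), sizes)
  S <- matrix(eps, k, k)
  for (b in seq_along(sizes)) {
    i <- which(block == b)
    S[i, i] <- 1
  }
  diag(S) <- diag(S) + 1
  T <- S / rowSums(S)
  list(T = T, block = block)
}

# standard test I-V parameters (the printed-equation forward model)
iv_true <- list(Gmax = 1, Vrev = 80, Vhalf = 20, slope_k = 6)
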