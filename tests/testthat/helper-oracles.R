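# closed-form oracles for the discretized chain

# mean bending energy of a free rigid-bond chain: per joint
# <E> = k + 1 - k coth k (independent joints, p(theta) ~ sin e^{-k(1-cos)})
free_chain_energy <- function(Nb, k) (Nb - 2) * (k + 1 - k / tanh(k))

# exact mean-square end-to-end distance of the free discrete chain:
# <R^2> = ds^2 [n + 2 sum_{d<n} (n-d) lambda^d], lambda = coth k - 1/k
discrete_mean_square_R <- function(Nb, ds, k) {
  lam <- 1 / tanh(k) - 1 / k
  n <- Nb - 1
  d <- 1:(n - 1)
  ds^2 * (n + 2 * sum((n - d) * lam^d))
}

# joint-angle CDF of a single free joint
joint_angle_cdf <- function(k) {
  function(theta) (1 - exp(-k * (1 - cos(theta)))) / (1 - exp(-2 * k))
}

# joint bend angles from snapshot frames (3*Nb x n matrix)
snapshot_joint_angles <- function(snaps, Nb, joint) {
  vapply(seq_len(ncol(snaps)), function(j) {
    p <- matrix(snaps[, j], nrow = 3)
    a <- p[, joint] - p[, joint - 1]
    b <- p[, joint + 1] - p[, joint]
    acos(max(-1, min(1, sum(a * b) / sqrt(sum(a^2) * sum(b^2)))))
  }, numeric(1))
}
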