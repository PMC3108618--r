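# Shared in-code fixtures for the test suite.

# A labeled dist object from explicit pairwise values.
make_dist <- function(m, labels) {
  dimnames(m) <- list(labels, labels)
  stats::as.dist(m)
}

# 3-point worked distances: d(A,B)=2, d(A,C)=d(B,C)=4 (ultrametric).
dist_ultra3 <- function() {
  make_dist(matrix(c(0, 2, 4,
                     2, 0, 4,
                     4, 4, 0), 3, 3), c("A", "B", "C"))
}

# 3-point non-ultrametric distances: d(A,B)=2, d(A,C)=3, d(B,C)=4.
dist_tri3 <- function() {
  make_dist(matrix(c(0, 2, 3,
                     2, 0, 4,
                     3, 4, 0), 3, 3), c("A", "B", "C"))
}

# The recursive chain model x -> m -> y with a known parameter vector.
chain_spec <- function() parse_model("x -> m\nm -> y", name = "chain")
chain_theta <- function() c(0.7, -0.5, 2, 1, 0.5)

# Covariance table generated exactly from the chain model's truth.
chain_cov <- function(N = 200L) {
  covariance_table(implied_covariance(chain_spec(), chain_theta()), N)
}

# Random symmetric binary interaction matrix over n taxa (diag 0).
random_web <- function(n, p = 0.4) {
  m <- matrix(0L, n, n)
  m[upper.tri(m)] <- stats::rbinom(n * (n - 1) / 2, 1L, p)
  m <- m + t(m)
  dimnames(m) <- list(paste0("t", seq_len(n)), paste0("t", seq_len(n)))
  interaction_matrix(m)
}

# A design of n replicate full (richness 9) webs: every consumer present,
# so the generator's structural equations hold without structural zeros.
full_web_design <- function(n = 70L) {
  data.frame(web_id = seq_len(n), richness = 9L,
             composition = paste(consumers(sarracenia_pool()),
                                 collapse = ";"),
             stringsAsFactors = FALSE)
}
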