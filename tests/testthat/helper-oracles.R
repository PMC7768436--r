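# Independent oracles and small fixture builders shared across tests.

# Hellinger distance between two normals by numerical integration of the
# Bhattacharyya integral (independent of the closed form in the package).
hellinger_integral <- function(mu1, s1, mu2, s2) {
  f <- function(x) sqrt(dnorm(x, mu1, s1) * dnorm(x, mu2, s2))
  # the integrand is a single Gaussian bump; integrate over its support
  # (precision-weighted center, combined width) so quadrature cannot miss it
  w1 <- 1 / s1^2; w2 <- 1 / s2^2
  center <- (mu1 * w1 + mu2 * w2) / (w1 + w2)
  width <- sqrt(2) * s1 * s2 / sqrt(s1^2 + s2^2)
  bc <- integrate(f, center - 60 * width, center + 60 * width,
                  subdivisions = 2000L, rel.tol = 1e-12)$value
  sqrt(max(0, 1 - bc))
}

# Upper-tail hypergeometric by explicit summation of binomial-coefficient
# ratios (exact in double precision for N <= 25).
hyper_upper_enum <- function(k, m, N, n) {
  js <- max(k, 0):min(m, n)
  if (length(js) == 0 || k > min(m, n)) return(0)
  sum(choose(m, js) * choose(N - m, n - js)) / choose(N, n)
}

# Two-sided exact Mann-Whitney by full enumeration of rank assignments.
mw_enum <- function(a, b) {
  n <- length(a); pool <- c(a, b)
  r <- rank(pool)
  obs <- sum(r[seq_len(n)])
  combs <- combn(length(pool), n)
  W <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- n * (length(pool) + 1) / 2
  mean(abs(W - mu) >= abs(obs - mu) - 1e-9)
}

# Brute-force induced subgraph: scan every node pair of the network.
induced_enum <- function(seeds, net) {
  nodes <- intersect(seeds, unique(c(net$from, net$to)))
  keep <- logical(nrow(net))
  for (i in seq_len(nrow(net))) {
    keep[i] <- net$from[i] %in% nodes && net$to[i] %in% nodes
  }
  edges <- net[keep, c("from", "to")]
  list(nodes = sort(unique(c(edges$from, edges$to))),
       edges = edges[order(edges$from, edges$to), ])
}

as_tibble_strip <- function(x) {
  out <- tibble::as_tibble(x)
  attr(out, "universe") <- NULL
  out
}

# tiny abundance fixture: features x samples from a vector, with flags
tiny_abund <- function(values, n_feat, n_samp, flags = NULL, scale = "raw",
                       feature_ids = sprintf("F%02d", seq_len(n_feat)),
                       sample_ids = sprintf("S%02d", seq_len(n_samp))) {
  m <- matrix(values, n_feat, n_samp,
              dimnames = list(feature_ids, sample_ids))
  abundance_tbl(m, flags = flags, scale = scale, zero_as_missing = FALSE)
}
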