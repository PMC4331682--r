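# Shared fixtures and independent oracles for the test suite.

# TOY-1: A: u1-u2-u3 path; B: v1-v2 edge; M = {(u1,v1),(u2,v2),(u3,v1)}
# with scores (2, 1, 1). Closed form: P rows ((u2,v2):1), ((u1,v1):2/3,
# (u3,v1):1/3), ((u2,v2):1); s = (1/2, 1/4, 1/4); pi = (1/3, 1/2, 1/6);
# lambda = 0.
toy1 <- function() {
  A <- csrw_network("A", rbind(c("u1", "u2"), c("u2", "u3")))
  B <- csrw_network("B", rbind(c("v1", "v2")))
  sim <- sim_table("A", "B", c("u1", "u2", "u3"), c("v1", "v2", "v1"),
                   c(2, 1, 1))
  list(A = A, B = B, sim = sim)
}

# TOY-2: A: u1-u2; B: v1-v2-v3; M = {(u1,v1),(u2,v3)}; every candidate
# move lands in I, so both states are dangling.
toy2 <- function() {
  A <- csrw_network("A", rbind(c("u1", "u2")))
  B <- csrw_network("B", rbind(c("v1", "v2"), c("v2", "v3")))
  sim <- sim_table("A", "B", c("u1", "u2"), c("v1", "v3"), c(1, 1))
  list(A = A, B = B, sim = sim)
}

# Random Erdos-Renyi-ish network on n nodes with edge probability p.
rand_network <- function(label, n, p, prefix) {
  nodes <- sprintf("%s%02d", prefix, seq_len(n))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pick <- stats::runif(nrow(idx)) < p
  edges <- cbind(nodes[idx[pick, 1]], nodes[idx[pick, 2]])
  csrw_network(label, edges = edges, nodes = nodes)
}

# Random pairwise instance: two networks plus a random similarity table.
# Uses the current RNG state; callers set the seed.
rand_pair_instance <- function(nU = 6, nV = 6, p_edge = 0.5, p_sim = 0.4) {
  U <- rand_network("A", nU, p_edge, "u")
  V <- rand_network("B", nV, p_edge, "v")
  pu <- rep(U$nodes, times = nV)
  pv <- rep(V$nodes, each = nU)
  pick <- stats::runif(length(pu)) < p_sim
  if (!any(pick)) pick[sample(length(pick), 2L)] <- TRUE
  sim <- sim_table("A", "B", pu[pick], pv[pick],
                   stats::runif(sum(pick), 0.5, 2))
  list(U = U, V = V, sim = sim)
}

# Independent oracle: stationary distribution by direct linear solve of
# pi P = pi, sum(pi) = 1 (least squares via QR on the stacked system).
direct_stationary <- function(P) {
  P <- as.matrix(P)
  n <- nrow(P)
  A <- rbind(t(P) - diag(n), rep(1, n))
  b <- c(rep(0, n), 1)
  as.vector(qr.solve(A, b))
}

# TRUE iff the chain is irreducible (support strongly connected) and
# aperiodic: exactly one eigenvalue on the unit circle.
irreducible_aperiodic <- function(P) {
  g <- igraph::graph_from_adjacency_matrix(as.matrix(P) > 0, mode = "directed")
  if (igraph::components(g, mode = "strong")$no != 1L) return(FALSE)
  ev <- abs(eigen(as.matrix(P), only.values = TRUE)$values)
  sum(ev > 1 - 1e-9) == 1L
}

# Dense-matrix oracle for intra-network smoothing.
dense_smoothing <- function(C, netU, netV, alpha) {
  Cd <- as.matrix(C)
  rn <- function(net) {
    A <- as.matrix(igraph::as_adjacency_matrix(net$graph))
    d <- rowSums(A)
    A[d > 0, ] <- A[d > 0, , drop = FALSE] / d[d > 0]
    A
  }
  out <- alpha * Cd + (1 - alpha) * rn(netU) %*% Cd %*% t(rn(netV))
  out[Cd == 0] <- 0
  out
}

# Canonical comparison form of an alignment: sorted member strings.
alignment_signature <- function(A) {
  sig <- vapply(A$classes, function(cl)
    paste(sort(paste(cl$network, cl$node, sep = "|")), collapse = "\t"),
    character(1))
  sort(sig)
}
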