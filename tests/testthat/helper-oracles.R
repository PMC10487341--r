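# Independent dense oracle: solves the full (n_branch + n_nodes) system
# [Poiseuille per branch; mass balance or fixed pressure per node] with a
# dense base-R solve. Unknowns are (Q_1..m, p_1..n).
dense_flow_oracle <- function(nodes, edges, mu, bc) {
  m <- nrow(edges); n <- nrow(nodes)
  R <- 128 * mu * (edges$length * 1e-6) / (pi * (edges$diameter * 1e-6)^4)
  # scale flows by the median resistance so the dense system is well
  # conditioned; unknowns become u = s Q
  s_ <- stats::median(R)
  R <- R / s_
  A <- matrix(0, m + n, m + n)
  rhs <- numeric(m + n)
  ai <- match(edges$node_a, nodes$id)
  bi <- match(edges$node_b, nodes$id)
  for (i in seq_len(m)) {
    A[i, i] <- R[i]
    A[i, m + ai[i]] <- A[i, m + ai[i]] - 1
    A[i, m + bi[i]] <- A[i, m + bi[i]] + 1
  }
  for (j in seq_len(n)) {
    row <- m + j
    k <- match(nodes$id[j], bc$node)
    if (!is.na(k)) {
      A[row, m + j] <- 1
      rhs[row] <- bc$pressure[k]
    } else {
      for (i in seq_len(m)) {
        if (ai[i] == j) A[row, i] <- A[row, i] - 1
        if (bi[i] == j) A[row, i] <- A[row, i] + 1
      }
    }
  }
  sol <- solve(A, rhs)
  list(Q = sol[seq_len(m)] / s_, p = sol[m + seq_len(n)])
}

random_network <- function(seed, n_nodes = 8, extra = 3) {
  set.seed(seed)
  nodes <- data.frame(id = seq_len(n_nodes),
                      x = runif(n_nodes, 0, 500),
                      y = runif(n_nodes, 0, 500),
                      z = runif(n_nodes, 0, 100))
  # random spanning tree + extra chords
  edges <- data.frame(node_a = integer(0), node_b = integer(0))
  for (v in 2:n_nodes)
    edges <- rbind(edges, data.frame(node_a = sample(v - 1, 1), node_b = v))
  for (e in seq_len(extra)) {
    ab <- sample(n_nodes, 2)
    edges <- rbind(edges, data.frame(node_a = ab[1], node_b = ab[2]))
  }
  edges$length <- runif(nrow(edges), 50, 200)
  edges$diameter <- runif(nrow(edges), 10, 40)
  edges
}

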