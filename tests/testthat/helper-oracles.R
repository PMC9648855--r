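# Independent oracles used across tests. These deliberately re-derive
# results by brute force rather than calling the implementation paths
# they check.

# brute-force hexagonal lattice enumeration: count points of the lattice
# spanned by u = s*(1,0), v = s*(1/2, sqrt(3)/2), anchored at the arena
# center, that fall strictly inside the (0, L)^2 square
oracle_hex_node_count <- function(L, s) {
  eps <- 1e-9
  count <- 0L
  rng <- ceiling(L / s) + 2L
  for (i in -rng:rng) {
    for (j in -rng:rng) {
      x <- L / 2 + i * s + j * s / 2
      y <- L / 2 + j * s * sqrt(3) / 2
      if (x > eps && x < L - eps && y > eps && y < L - eps) count <- count + 1L
    }
  }
  count
}

# direct (non-separable) 2-D convolution with a truncated discrete
# Gaussian kernel and edge replication
oracle_gaussian_smooth <- function(m, sigma) {
  r <- ceiling(3 * sigma)
  x <- (-r):r
  k1 <- exp(-x^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  n <- nrow(m); p <- ncol(m)
  out <- matrix(0, n, p)
  for (i in seq_len(n)) {
    for (j in seq_len(p)) {
      acc <- 0
      for (a in x) {
        for (b in x) {
          ii <- min(max(i + a, 1L), n)
          jj <- min(max(j + b, 1L), p)
          acc <- acc + k2[a + r + 1L, b + r + 1L] * m[ii, jj]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# single-ray intersection oracle: distance from p along unit direction d
# to a circle of radius rad at c, Inf if missed
oracle_ray_circle <- function(p, d, c, rad) {
  o <- c - p
  proj <- sum(d * o)
  disc <- proj^2 - (sum(o^2) - rad^2)
  if (disc < 0) return(Inf)
  t <- proj - sqrt(disc)
  if (t > 1e-9) t else Inf
}

# breadth-first search distance (in moves) between nodes of a hex grid
oracle_bfs_dist <- function(grid, from, to) {
  n <- nrow(grid$nodes)
  dist <- rep(Inf, n)
  dist[from] <- 0
  frontier <- from
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (node in frontier) {
      for (d in 1:6) {
        nb <- grid$adjacency[node, d]
        if (!is.na(nb) && dist[nb] == Inf) {
          dist[nb] <- dist[node] + 1
          nxt <- c(nxt, nb)
        }
      }
    }
    frontier <- nxt
  }
  dist[to]
}

# tabular Q-learning oracle on the discrete pose space of a tiny grid
oracle_tabular_q <- function(env, n_episodes, alpha, gamma, seed) {
  set.seed(seed)
  nA <- n_actions(env$space)
  n <- nrow(env$grid$nodes)
  Q <- array(0, dim = c(n, 6L, nA))
  for (ep in seq_len(n_episodes)) {
    env_reset(env)
    repeat {
      s <- c(env$pose$node, env$pose$heading + 1L)
      a <- sample.int(nA, 1L)
      st <- env_step(env, a)
      s2 <- c(env$pose$node, env$pose$heading + 1L)
      target <- if (st$terminal) st$reward else {
        st$reward + gamma * max(Q[s2[1L], s2[2L], ])
      }
      Q[s[1L], s[2L], a] <- Q[s[1L], s[2L], a] +
        alpha * (target - Q[s[1L], s[2L], a])
      if (st$terminal) break
    }
  }
  Q
}
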