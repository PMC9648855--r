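# direct-convolution oracle for one layer (loops, no im2col)
oracle_conv_relu <- function(X, W, b, Hin, Win, Cin, nF, sh, sw, ph) {
  Hout <- (Hin + 2 * ph - 5) %/% sh + 1L
  Wout <- (Win - 5) %/% sw + 1L
  Xa <- array(X, c(Hin, Win, Cin))
  Y <- array(0, c(Hout, Wout, nF))
  for (f in seq_len(nF)) for (ow in seq_len(Wout)) for (oh in seq_len(Hout)) {
    s <- b[f]
    for (cin in seq_len(Cin)) for (kw in 1:5) for (kh in 1:5) {
      ih <- (oh - 1L) * sh + (kh - 1L) - ph + 1L
      iw <- (ow - 1L) * sw + (kw - 1L) + 1L
      xv <- if (ih >= 1L && ih <= Hin) Xa[ih, iw, cin] else 0
      s <- s + W[f, ((cin - 1L) * 5L + (kw - 1L)) * 5L + kh] * xv
    }
    Y[oh, ow, f] <- s
  }
  pmax(Y, 0)
}

oracle_q_forward <- function(params, obs) {
  y1 <- oracle_conv_relu(obs, params$W1, params$b1, 12L, 48L, 3L, 32L, 2L, 2L, 0L)
  y2 <- oracle_conv_relu(as.numeric(y1), params$W2, params$b2, 4L, 22L, 32L, 64L, 2L, 2L, 2L)
  y3 <- oracle_conv_relu(as.numeric(y2), params$W3, params$b3, 2L, 9L, 64L, 64L, 1L, 2L, 2L)
  h <- pmax(params$W4 %*% as.numeric(y3) + params$b4, 0)
  v <- as.numeric(params$Wv %*% h + params$bv)
  a <- as.numeric(params$Wa %*% h + params$ba)
  list(q = dueling_q(v, a), h = h)
}

test_that("the network forward pass matches a direct convolution oracle", {
  set.seed(31)
  agent <- dqn_network(12)
  params <- hexnav:::dqn_get_params(agent$ptr)
  obs <- stats::runif(1728)
  want <- oracle_q_forward(params, obs)
  # the compiled core accumulates in single precision; the oracle in double
  expect_equal(as.numeric(q_values(agent, obs)), as.numeric(want$q),
               tolerance = 1e-4)
  expect_equal(as.numeric(hidden_activations(agent, obs)),
               as.numeric(want$h), tolerance = 1e-4)
})

test_that("dueling aggregation centers advantages", {
  expect_equal(dueling_q(2, c(1, 0, -1)), c(3, 2, 1))
  expect_equal(dueling_q(0, c(5, 5, 5)), c(0, 0, 0))
  a <- c(0.3, -1.2, 2.0, 0.1)
  expect_equal(dueling_q(1.5, a), dueling_q(1.5, a + 7))  # shift invariance
})

test_that("epsilon-greedy selection is greedy, uniform, and breaks ties fairly", {
  set.seed(32)
  expect_identical(select_action(c(1, 5, 3), 0), 2L)
  # epsilon = 1: uniform over actions
  draws <- replicate(30000, select_action(c(1, 5, 3), 1))
  p <- stats::chisq.test(table(factor(draws, levels = 1:3)))$p.value
  expect_gt(p, 0.01)
  # exact ties split evenly under the greedy branch
  ties <- replicate(4000, select_action(c(2, 2, 0), 0))
  expect_setequal(unique(ties), c(1L, 2L))
  expect_lt(abs(mean(ties == 1L) - 0.5), 0.05)
  # empirical exploration rate: greedy always picks action 1 here, so
  # non-1 choices estimate epsilon * (nA - 1) / nA
  q <- c(10, rep(0, 11))
  picks <- replicate(20000, select_action(q, 0.3))
  eps_hat <- mean(picks != 1L) * 12 / 11
  expect_lt(abs(eps_hat - 0.3), 0.02)
})

test_that("double-Q targets bootstrap from the online argmax under the target net", {
  expect_equal(td_target(1, TRUE, matrix(5), matrix(9), 0.99), 1)
  qo <- matrix(c(0, 3, 1), 3)   # online argmax = action 2
  qt <- matrix(c(7, 10, -2), 3)
  expect_equal(td_target(-1, FALSE, qo, qt, 0.99), -1 + 0.99 * 10)
  # identical networks reduce to the standard max target
  expect_equal(td_target(-1, FALSE, qt, qt, 0.9), -1 + 0.9 * max(qt))
  # vectorized over a batch
  y <- td_target(c(1, -1), c(TRUE, FALSE), cbind(qo, qo), cbind(qt, qt), 0.5)
  expect_equal(y, c(1, -1 + 0.5 * 10))
  # agrees with the compiled path on random inputs
  set.seed(33)
  agent <- dqn_network(5)
  obs_next <- matrix(stats::runif(1728 * 6), ncol = 6)
  r <- stats::rnorm(6)
  term <- c(1L, 0L, 0L, 1L, 0L, 0L)
  qn <- q_values(agent, obs_next)
  want <- td_target(r, as.logical(term), qn, qn, 0.99)  # fresh net: target == online
  got <- hexnav:::dqn_td_targets(agent$ptr, obs_next, r, term, 0.99)
  # single-precision forwards; BLAS blocking varies with batch width
  expect_equal(as.numeric(got), want, tolerance = 1e-6)
})

test_that("analytic gradients match finite differences", {
  set.seed(34)
  agent <- dqn_network(4)
  p <- hexnav:::dqn_get_params(agent$ptr)
  obs <- matrix(stats::runif(1728 * 3), ncol = 3)
  acts <- c(1L, 4L, 2L)
  y <- stats::rnorm(3)
  gr <- hexnav:::dqn_gradients_given_targets(agent$ptr, obs, acts, y)
  # single-precision loss values limit the finite-difference resolution:
  # use a wide central difference and a correspondingly loose tolerance
  eps <- 5e-3
  for (nm in c("W1", "W2", "W3", "W4", "Wv", "Wa", "b2", "b4", "ba")) {
    idx <- sample(length(p[[nm]]), 3L)
    for (i in idx) {
      p2 <- p
      p2[[nm]][i] <- p2[[nm]][i] + eps
      hexnav:::dqn_set_params(agent$ptr, p2)
      lp <- hexnav:::dqn_loss_given_targets(agent$ptr, obs, acts, y)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      hexnav:::dqn_set_params(agent$ptr, p2)
      lm <- hexnav:::dqn_loss_given_targets(agent$ptr, obs, acts, y)
      fd <- (lp - lm) / (2 * eps)
      expect_lt(abs(gr[[nm]][i] - fd), 0.05 * max(1, abs(fd)))
    }
  }
  hexnav:::dqn_set_params(agent$ptr, p)
})

test_that("the replay buffer is strictly FIFO and capacity-bounded", {
  buf <- replay_buffer(3000L, obs_dim = 4L)
  for (k in 1:5000) {
    buffer_push(buf, rep(k, 4L), (k %% 7L) + 1L, -1, rep(k + 0.5, 4L), FALSE)
  }
  expect_identical(buf$size, 3000L)
  # holds exactly the most recent 3000 transitions
  expect_setequal(buf$obs[1L, ], 2001:5000)
  # the oldest remaining transition sits just after the write head
  expect_identical(buf$obs[1L, buf$pos + 1L], 2001)
  set.seed(35)
  mb <- buffer_sample(buf, 32L)
  expect_identical(dim(mb$obs), c(4L, 32L))
  expect_true(all(mb$obs[1L, ] >= 2001))
})

test_that("dropout perturbs training forwards but never evaluation forwards", {
  set.seed(36)
  agent <- dqn_network(3, dropout_rate = 0.35)
  obs <- matrix(stats::runif(1728 * 2), ncol = 2)
  h1 <- hidden_activations(agent, obs)
  h2 <- hidden_activations(agent, obs)
  expect_identical(h1, h2)   # evaluation mode is deterministic
  # training losses differ across calls with identical data: dropout masks
  acts <- c(1L, 2L)
  y <- c(0, 0)
  l1 <- replicate(5, {
    a2 <- dqn_network(3, dropout_rate = 0.35)
    hexnav:::dqn_set_params(a2$ptr, hexnav:::dqn_get_params(agent$ptr))
    hexnav:::dqn_train_batch(a2$ptr, obs, obs, acts, y, c(0L, 0L), 0.99, 0)
  })
  expect_gt(stats::sd(l1), 0)
})

test_that("duplicated egocentric copies start with independent Q-values", {
  set.seed(37)
  agent <- dqn_network(24)
  obs <- stats::runif(1728)
  q <- as.numeric(q_values(agent, obs))
  # copies of ego_forward sit at indices 13, 16, 19, 22 in the full space
  expect_gt(stats::sd(q[c(13L, 16L, 19L, 22L)]), 0)
})
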