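test_that("cross-cell correlation matches its definition on small cases", {
  top <- fx_two_edge_top()
  expr <- rbind(i = c(A = 1, B = 2, C = 0, D = 0),
                j = c(A = 0, B = 0, C = 2, D = 4))
  # two activating edges, e_R,i = (1,2), e_T,j = (2,4): perfect collinearity
  expect_equal(compute_ccc(top, expr, 1, 2), 1)

  top_inh <- grn_topology(c("A", "B", "C", "D"),
                          data.frame(source = c("A", "B"),
                                     target = c("C", "D"),
                                     sign = c(-1L, -1L)))
  expect_equal(compute_ccc(top_inh, expr, 1, 2), -1)

  # fewer than 2 edges is an error
  one_edge <- grn_topology(c("A", "B"),
                           data.frame(source = "A", target = "B", sign = 1L))
  expect_error(compute_ccc(one_edge, expr[, 1:2], 1, 2), "2 edges")
  expect_error(ccc_context(one_edge, expr[, 1:2]), "2 edges")
})

test_that("the CCC matrix agrees with an independent Pearson oracle", {
  set.seed(101)
  genes <- LETTERS[1:5]
  top <- grn_topology(genes,
    data.frame(source = c("A", "B", "C", "D", "E"),
               target = c("B", "C", "D", "E", "A"),
               sign = c(1L, -1L, 1L, -1L, 1L)))
  expr <- matrix(stats::rnorm(8 * 5), 8, 5,
                 dimnames = list(paste0("c", 1:8), genes))
  ctx <- ccc_context(top, expr)
  for (i in 1:8) for (j in 1:8) {
    r_i <- expr[i, top$edges$source] * top$edges$sign
    t_j <- expr[j, top$edges$target]
    expect_lt(abs(ctx$ccc[i, j] - stats::cor(r_i, t_j)), 1e-12)
  }
  # a constant cell always has a zero-variance target vector (column NA);
  # its regulator vector keeps variance when edge signs are mixed, but is
  # degenerate too under an all-activating topology (row NA)
  expr2 <- expr
  expr2[3, ] <- 7
  ctx2 <- ccc_context(top, expr2)
  expect_true(all(is.na(ctx2$ccc[, 3])))
  expect_false(anyNA(ctx2$ccc[3, -3]))  # signs (+,-,+,-,+) keep variance
  expect_false(anyNA(ctx2$ccc[-3, -3]))
  top_act <- grn_topology(top$genes,
                          transform(top$edges, sign = 1L))
  ctx3 <- ccc_context(top_act, expr2)
  expect_true(all(is.na(ctx3$ccc[3, ])))
})

test_that("radius neighborhoods match a brute-force filter", {
  set.seed(7)
  co <- matrix(stats::rnorm(100), 50, 2)
  sp <- embedding_space(co)
  D <- as.matrix(stats::dist(co))
  for (i in c(1, 17, 50)) {
    for (r in c(0.1, 0.3, 0.6)) {
      expect_identical(find_neighbors(sp, i, r),
                       setdiff(which(D[i, ] <= r * max(D)), i))
    }
    expect_identical(find_neighbors(sp, i, 1), setdiff(1:50, i))
  }
  expect_length(find_neighbors(sp, 1, 1e-9), 0)
})

test_that("vector inference solves the normal equations exactly", {
  set.seed(11)
  for (rep_i in 1:25) {
    m <- sample(2:5, 1)
    n <- 30
    co <- matrix(stats::rnorm((n + 1) * m), n + 1, m)
    sp <- embedding_space(co)
    C <- matrix(stats::runif((n + 1)^2, -1, 1), n + 1, n + 1)
    nb <- 2:(n + 1)
    f1 <- infer_outgoing(C, sp, 1, nb)
    f2 <- infer_incoming(C, sp, 1, nb)
    X <- sweep(co[nb, , drop = FALSE], 2, co[1, ])
    y1 <- C[1, nb] - C[1, 1]
    y2 <- C[nb, 1] - C[1, 1]
    v1_oracle <- solve(t(X) %*% X, t(X) %*% y1)
    v2_oracle <- -solve(t(X) %*% X, t(X) %*% y2)
    expect_lt(max(abs(f1$v - v1_oracle)), 1e-10)
    expect_lt(max(abs(f2$v - v2_oracle)), 1e-10)
  }
})

test_that("planted linear CCC gradients are recovered exactly", {
  set.seed(12)
  m <- 3; n <- 40
  co <- matrix(stats::rnorm((n + 1) * m), n + 1, m)
  sp <- embedding_space(co)
  g <- c(2, -1, 0.5)
  C <- matrix(0, n + 1, n + 1)
  C[1, ] <- 0.5 + (sweep(co, 2, co[1, ]) %*% g)  # rho_{1->j} linear in x_j - x_1
  C[1, 1] <- 0.5
  f1 <- infer_outgoing(C, sp, 1, 2:(n + 1))
  expect_lt(max(abs(f1$v - g)), 1e-8)
  expect_lt(max(abs(f1$residuals)), 1e-8)

  # all-zero response: zero vector
  C0 <- matrix(0.3, n + 1, n + 1)
  f0 <- infer_outgoing(C0, sp, 1, 2:(n + 1))
  expect_equal(unname(f0$v), rep(0, m))
})

test_that("symmetric CCC fields have v2 = -v1 and zero net flow", {
  set.seed(13)
  n <- 60
  co <- matrix(stats::rnorm(n * 2), n, 2)
  sp <- embedding_space(co)
  C <- matrix(stats::runif(n * n, -1, 1), n, n)
  C <- (C + t(C)) / 2  # force rho_{i->j} = rho_{j->i}
  for (i in c(1, 25, 60)) {
    nb <- find_neighbors(sp, i, 0.9)
    f1 <- infer_outgoing(C, sp, i, nb)
    f2 <- infer_incoming(C, sp, i, nb)
    expect_lt(max(abs(f2$v + f1$v)), 1e-10)
    dec <- decompose_vectors(f1$v, f2$v)
    expect_lt(max(abs(dec$net_flow)), 1e-10)
  }
})

test_that("net flow and reversibility decomposition is exact arithmetic", {
  expect_equal(decompose_vectors(c(1, 2), c(1, 2)),
               list(net_flow = c(1, 2), reversibility = c(0, 0)))
  expect_equal(decompose_vectors(c(1, 2), c(-1, -2)),
               list(net_flow = c(0, 0), reversibility = c(1, 2)))
  expect_equal(decompose_vectors(c(2, 0), c(0, 2)),
               list(net_flow = c(1, 1), reversibility = c(1, -1)))
  expect_error(decompose_vectors(c(1, 2), c(1, 2, 3)), "dimension")
  # identities on a fitted object
  fit <- fx_rep()$fit
  v <- fit$valid
  expect_lt(max(abs(fit$net_flow[v, ] + fit$reversibility[v, ] -
                    fit$v1[v, ])), 1e-12)
  expect_lt(max(abs(fit$net_flow[v, ] - fit$reversibility[v, ] -
                    fit$v2[v, ])), 1e-12)
})

test_that("sticc is equivariant under cell permutation", {
  set.seed(14)
  top <- builtin_circuit("REP")
  raw <- simulate_steady_states(top, 120, sim_config(seed = 21))
  logm <- normalize_log(raw)
  fit <- sticc(top, logm, radius = 0.3)
  perm <- sample(nrow(logm))
  fit_p <- sticc(top, logm[perm, ], radius = 0.3)
  expect_equal(unname(fit_p$v1), unname(fit$v1[perm, ]), tolerance = 1e-10)
  expect_equal(unname(fit_p$net_flow), unname(fit$net_flow[perm, ]),
               tolerance = 1e-10)
  expect_identical(fit_p$valid, fit$valid[perm])
})

test_that("degenerate inputs raise diagnosable errors", {
  top <- builtin_circuit("REP")
  expr <- matrix(stats::runif(6), 2, 3,
                 dimnames = list(c("c1", "c2"), top$genes))
  expect_error(sticc(top, expr), "min_neighbors")
  raw <- simulate_steady_states(top, 100, sim_config(seed = 2))
  logm <- normalize_log(raw)
  expect_error(sticc(top, logm, radius = 1e-6), "radius too small")
  bad <- logm[, 1:2]
  expect_error(sticc(top, bad), "missing from expression")
})

test_that("cells with thin neighborhoods are flagged, not fitted", {
  top <- builtin_circuit("REP")
  raw <- simulate_steady_states(top, 150, sim_config(seed = 23))
  logm <- normalize_log(raw)
  fit <- sticc(top, logm, radius = 0.22, min_neighbors = 15)
  expect_true(any(fit$valid))
  bad <- which(!fit$valid)
  if (length(bad)) {
    expect_true(all(nzchar(fit$reason[bad])))
    expect_true(all(is.na(fit$v1[bad, ])))
    expect_true(all(fit$n_used[fit$reason == "insufficient neighborhood"] <
                    15))
  }
  tab <- as.data.frame(fit)
  expect_equal(nrow(tab), 150)
  expect_true(all(c("cell_id", "v1_1", "net_1", "rev_1", "valid") %in%
                  names(tab)))
})
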