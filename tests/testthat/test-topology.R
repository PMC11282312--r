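# Connectivity builders: densities, cluster scaling, determinism, export.

test_that("full connection probability yields the complete graph minus autapses", {
  s <- network_spec(N = 60, Q = 1, J_Eplus = 1,
                    p = c(p_EE = 1, p_EI = 1, p_IE = 1, p_II = 1))
  conn <- build_random_balanced(s, seed = 3)
  expect_equal(length(conn$W@x), 60 * 59)
  expect_true(all(Matrix::diag(conn$W) == 0))
})

test_that("realized densities stay within 3 binomial SDs of p", {
  s <- small_spec(N = 400, Q = 1, J_Eplus = 1)
  conn <- build_random_balanced(s, seed = 7)
  ns <- population_sizes(s)
  blocks <- list(c("E", "E", s$p[["p_EE"]]), c("E", "I", s$p[["p_EI"]]),
                 c("I", "E", s$p[["p_IE"]]), c("I", "I", s$p[["p_II"]]))
  for (b in blocks) {
    W <- weight_block(conn, b[1], b[2])
    n_pairs <- prod(dim(W)) - (b[1] == b[2]) * nrow(W)
    p <- as.numeric(b[3])
    n_edges <- length(W@x)
    expect_lt(abs(n_edges - p * n_pairs), 3 * sqrt(n_pairs * p * (1 - p)))
  }
})

test_that("building is deterministic in the seed and varies across seeds", {
  s <- small_spec()
  c1 <- build_ei_clustered(s, seed = 5)
  c2 <- build_ei_clustered(s, seed = 5)
  c3 <- build_ei_clustered(s, seed = 6)
  expect_identical(c1$W, c2$W)
  expect_false(identical(c1$W, c3$W))
  # same density within tolerance even for different seeds
  expect_lt(abs(length(c1$W@x) - length(c3$W@x)) / length(c1$W@x), 0.05)
})

test_that("J_Eplus = 1 reduces every clustered topology to the random one", {
  s <- small_spec(J_Eplus = 1)
  base <- build_random_balanced(s, seed = 9)
  expect_equal(build_e_clustered(s, seed = 9)$W, base$W)
  sc0 <- cluster_scaling(s$Q, 1, R_J = 0)
  expect_equal(build_ei_clustered(s, scaling = sc0, seed = 9)$W, base$W)
})

test_that("cluster scaling forces the within/across weight ratio", {
  s <- small_spec(N = 400, Q = 4, J_Eplus = 3.5)
  sc <- cluster_scaling(4, 3.5, R_J = 3/4)
  conn <- build_e_clustered(s, scaling = sc, seed = 13)
  W <- weight_block(conn, "E", "E")
  cl <- conn$units$cluster[conn$units$population == "E"]
  tw <- Matrix::summary(W)
  same <- cl[tw$i] == cl[tw$j]
  expect_equal(mean(tw$x[same]) / mean(tw$x[!same]), 3.5 / sc$J_Eminus,
               tolerance = 1e-12)
  # population mean weight is conserved up to autapse exclusion and edge
  # sampling noise, both O(J+/N)
  w_base <- compute_weights(s)[["J_EE"]]
  expect_equal(mean(tw$x), w_base, tolerance = 0.05)
})

test_that("E/I clustering scales all inhibitory-related blocks; R_J = 0 does not", {
  s <- small_spec(N = 400, Q = 4, J_Eplus = 3)
  sc <- cluster_scaling(4, 3, R_J = 3/4)
  conn <- build_ei_clustered(s, scaling = sc, seed = 17)
  u <- conn$units
  for (blk in list(c("E", "I", "J_EI"), c("I", "E", "J_IE"),
                   c("I", "I", "J_II"))) {
    W <- weight_block(conn, blk[1], blk[2])
    cl_t <- u$cluster[u$population == blk[1]]
    cl_s <- u$cluster[u$population == blk[2]]
    tw <- Matrix::summary(W)
    same <- cl_t[tw$i] == cl_s[tw$j]
    expect_equal(mean(tw$x[same]) / mean(tw$x[!same]),
                 sc$J_Iplus / sc$J_Iminus, tolerance = 1e-12)
    # grand mean close to the unclustered base weight
    expect_equal(mean(tw$x), compute_weights(s)[[blk[3]]], tolerance = 0.05)
  }

  sc0 <- cluster_scaling(4, 3, R_J = 0)
  expect_equal(build_ei_clustered(s, scaling = sc0, seed = 17)$W,
               build_e_clustered(s, scaling = sc0, seed = 17)$W)
})

test_that("the E+I variant scales only the excitatory input to I clusters", {
  s <- small_spec(N = 400, Q = 4, J_Eplus = 3)
  sc <- cluster_scaling(4, 3, R_J = 3/4)
  conn <- build_e_plus_i_variant(s, scaling = sc, seed = 19)
  base <- build_random_balanced(s, seed = 19)
  u <- conn$units
  # I -> E and I -> I identical to the random network under the same seed
  expect_equal(weight_block(conn, "E", "I"), weight_block(base, "E", "I"))
  expect_equal(weight_block(conn, "I", "I"), weight_block(base, "I", "I"))
  # E -> I within/across ratio forced by construction
  W <- weight_block(conn, "I", "E")
  cl_t <- u$cluster[u$population == "I"]
  cl_s <- u$cluster[u$population == "E"]
  tw <- Matrix::summary(W)
  same <- cl_t[tw$i] == cl_s[tw$j]
  expect_equal(mean(tw$x[same]) / mean(tw$x[!same]),
               sc$J_Iplus / sc$J_Iminus, tolerance = 1e-12)
})

test_that("task-network clusters have 200 E and 50 I units each", {
  ca <- cluster_assignment(task_network_spec(), cluster_I = TRUE)
  tab <- table(ca$population, ca$cluster)
  expect_equal(unname(tab["E", ]), rep(200, 6))
  expect_equal(unname(tab["I", ]), rep(50, 6))
  expect_error(cluster_assignment(network_spec(N = 5000, Q = 7)),
               "divisible")
})

test_that("connectivity round-trips through coordinate-list CSV", {
  conn <- build_ei_clustered(small_spec(), seed = 23)
  ep <- tempfile(fileext = ".csv"); up <- tempfile(fileext = ".csv")
  write_connectivity_csv(conn, ep, up)
  back <- read_connectivity_csv(ep, up)
  expect_equal(as(back$W, "generalMatrix"), conn$W, ignore_attr = TRUE)
  expect_equal(back$units$cluster, conn$units$cluster)
})
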