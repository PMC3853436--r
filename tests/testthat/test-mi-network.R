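test_that("KSG estimate is exactly symmetric and deterministic", {
  set.seed(1)
  x <- rnorm(80); y <- rnorm(80)
  expect_identical(ksg_mutual_information(x, y),
                   ksg_mutual_information(y, x))
  expect_identical(ksg_mutual_information(x, y),
                   ksg_mutual_information(x, y))
  expect_error(ksg_mutual_information(x, y[-1]), "length")
  expect_error(ksg_mutual_information(x[1:4], y[1:4]), "k_neighbors \\+ 2")
  expect_warning(mi <- ksg_mutual_information(rep(1, 80), y), "constant")
  expect_equal(mi, 0)
})

test_that("independent samples give near-zero MI, correlated samples the Gaussian value", {
  set.seed(2)
  x <- rnorm(1000); z <- rnorm(1000)
  expect_lt(abs(ksg_mutual_information(x, z)), 0.1)
  est <- sapply(1:5, function(s) {
    set.seed(s)
    a <- rnorm(2000); b <- 0.9 * a + sqrt(1 - 0.81) * rnorm(2000)
    ksg_mutual_information(a, b)
  })
  expect_lt(abs(mean(est) - (-0.5 * log(1 - 0.81))), 0.05)
})

test_that("estimator error against the Gaussian closed form shrinks with n", {
  rho <- 0.7
  target <- -0.5 * log(1 - rho^2)
  err <- sapply(c(200, 2000), function(n) {
    mean(sapply(1:5, function(s) {
      set.seed(100 + s)
      a <- rnorm(n); b <- rho * a + sqrt(1 - rho^2) * rnorm(n)
      abs(ksg_mutual_information(a, b) - target)
    }))
  })
  expect_lt(err[2], err[1])
})

test_that("pairwise MI handles duplicates, single features, and constants", {
  set.seed(4)
  X <- matrix(rnorm(5 * 120), 5, dimnames = list(paste0("f", 1:5), NULL))
  X[2, ] <- X[1, ]  # exact duplicate
  mi <- pairwise_mi(X)
  expect_true(all(is.na(diag(mi))))
  expect_equal(mi, t(mi))
  # self-information dominates: the duplicate pair is row 1's maximum
  expect_equal(which.max(mi[1, ]), c(f2 = 2))
  expect_equal(nrow(pairwise_mi(X[1, , drop = FALSE])), 1)
  X[3, ] <- 5
  expect_warning(mi2 <- pairwise_mi(X), "constant")
  expect_true(all(mi2[3, -3] == 0))
})

test_that("DPI removes exactly the dominated edges in hand-worked triples", {
  ids <- c("A", "B", "C")
  mi <- matrix(c(NA, 2.0, 0.4, 2.0, NA, 1.5, 0.4, 1.5, NA), 3,
               dimnames = list(ids, ids))
  net <- dpi_prune(mi, epsilon = 0.05)
  e <- network_edges(net)
  edges <- paste(e$node_a, e$node_b)
  expect_setequal(edges, c("A B", "B C"))

  mi2 <- matrix(c(NA, 1.0, 0.99, 1.0, NA, 0.98, 0.99, 0.98, NA), 3,
                dimnames = list(ids, ids))
  net2 <- dpi_prune(mi2, epsilon = 0.05)
  expect_equal(igraph::ecount(net2), 3)  # weakest edge fails both inequalities
})

test_that("DPI equals the brute-force triple oracle on random matrices", {
  set.seed(6)
  for (rep in 1:100) {
    p <- sample(3:12, 1)
    v <- runif(p * (p - 1) / 2, 0, 2)
    mi <- matrix(0, p, p)
    mi[upper.tri(mi)] <- v
    mi <- mi + t(mi)
    diag(mi) <- NA
    ids <- sprintf("F%02d", 1:p)
    dimnames(mi) <- list(ids, ids)
    eps <- sample(c(0, 0.05, 0.2), 1)
    net <- dpi_prune(mi, epsilon = eps)
    keep <- oracle_dpi(mi, eps)
    expected <- which(upper.tri(mi) & keep & mi > 0, arr.ind = TRUE)
    got <- network_edges(net)
    expect_equal(nrow(got), nrow(expected))
    expect_setequal(paste(got$node_a, got$node_b),
                    paste(ids[expected[, 1]], ids[expected[, 2]]))
  }
})

test_that("pruning never adds edges and epsilon = Inf removes nothing", {
  set.seed(7)
  p <- 8
  mi <- matrix(0, p, p)
  mi[upper.tri(mi)] <- runif(p * (p - 1) / 2, 0.1, 2)
  mi <- mi + t(mi)
  diag(mi) <- NA
  net_inf <- dpi_prune(mi, epsilon = Inf)
  expect_equal(igraph::ecount(net_inf), p * (p - 1) / 2)
  net <- dpi_prune(mi, epsilon = 0)
  expect_lte(igraph::ecount(net), p * (p - 1) / 2)
  expect_error(dpi_prune(mi, epsilon = -1), "epsilon")
  asym <- mi; asym[1, 2] <- asym[1, 2] + 1
  expect_error(dpi_prune(asym), "symmetric")
})

test_that("relabeling features yields an isomorphic network", {
  set.seed(8)
  X <- matrix(rnorm(8 * 100), 8, dimnames = list(paste0("f", 1:8), NULL))
  X[2, ] <- 0.9 * X[1, ] + 0.3 * rnorm(100)
  X[3, ] <- 0.8 * X[1, ] + 0.4 * rnorm(100)
  net1 <- build_network(X, mi_floor = "none")
  perm <- sample(nrow(X))
  net2 <- build_network(X[perm, , drop = FALSE], mi_floor = "none")
  e1 <- network_edges(net1)
  e2 <- network_edges(net2)
  expect_setequal(paste(e1$node_a, e1$node_b), paste(e2$node_a, e2$node_b))
  expect_equal(sort(e1$mi_nats), sort(e2$mi_nats), tolerance = 1e-12)
})

test_that("build_network keeps planted structure and discards noise", {
  cfg <- synthetic_config(n_class_a = 100, n_class_b = 100, n_mirna = 30,
                          n_hubs = 2, module_size = 5, rho = 0.9,
                          de_fraction = 0, n_genes = 100, seed = 12)
  sim <- generate_dual_dataset(cfg)
  net <- build_network(sim$mirna)
  deg <- igraph::degree(net)
  for (h in sim$truth$hub_ids)
    expect_gte(deg[[h]], 4)  # hub keeps (almost) all module edges
  # independent noise features stay near-isolated under the null-max floor
  noise <- setdiff(rownames(sim$mirna),
                   c(sim$truth$hub_ids, unlist(sim$truth$module_members)))
  expect_lt(mean(deg[noise]), 1)
  # a single feature yields an empty network
  single <- build_network(sim$mirna[1, , drop = FALSE])
  expect_equal(igraph::ecount(single), 0)
  expect_equal(igraph::vcount(single), 1)
})
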