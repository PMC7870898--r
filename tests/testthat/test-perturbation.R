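test_that("perturbation is a bounded symmetric L1 distance on V", {
  expect_equal(perturbation(c(u = 0, v = 1), c(u = 1, v = 0)), 2)
  expect_equal(perturbation(c(u = 0.3, v = 0.7), c(u = 0.3, v = 0.7)), 0)
  expect_equal(perturbation(c(u = 0.5, v = 0.5), c(u = 0.75, v = 0.25)), 0.5)
  # renormalization within V: the added species' mass is excluded
  comp_gp <- c(u = 0.375, v = 0.125, a = 0.5)
  expect_equal(perturbation(c(u = 0.5, v = 0.5), comp_gp, c("u", "v")), 0.5)
  # symmetry and bounds on random compositions
  set.seed(7)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    y <- runif(k)
    yp <- runif(k)
    names(y) <- names(yp) <- paste0("s", seq_len(k))
    p <- perturbation(y, yp)
    expect_equal(p, perturbation(yp, y))
    expect_gte(p, 0)
    expect_lte(p, 2)
  }
  expect_error(perturbation(c(u = 0, v = 0), c(u = 1, v = 0)), "zero total")
  expect_error(perturbation(c(u = 1), c(w = 1)), "empty")
})

test_that("perturbation_params counts breadth, novelty and background", {
  # 3-cycle u -> v -> w -> u at rate e, via an explicit table
  ab <- c("a", "b", "c", "x")
  e <- 0.5
  alpha <- matrix(0, 4, 4, dimnames = list(ab, ab))
  alpha["a", "b"] <- e
  alpha["b", "c"] <- e
  alpha["c", "a"] <- e
  u <- "aa"; v <- "bb"; w <- "cc"  # igs letter i, tag letter i
  # novel-IGS catalyst x targeting v and w
  alpha["x", "b"] <- e
  alpha["x", "c"] <- e
  tab <- rate_table(alpha, alpha * 0.1, edge_threshold = 1e-9)
  net <- build_network(c(u, v, w), tab)
  par <- perturbation_params(net, "xa", tab)
  expect_equal(par[c("n", "m", "sigma_G", "e")],
               list(n = 2L, m = 0L, sigma_G = 3 * e, e = e))
  # same network; an added catalyst sharing u's IGS, one target
  par2 <- perturbation_params(net, "ax", tab)
  expect_equal(par2[c("n", "m", "sigma_G", "e")],
               list(n = 1L, m = 1L, sigma_G = 3 * e, e = e))
  # no targets in the network
  alpha2 <- alpha
  alpha2["x", ] <- 0
  alpha2["x", "x"] <- e
  tab2 <- rate_table(alpha2, alpha2 * 0.1, edge_threshold = 1e-9)
  net2 <- build_network(c(u, v, w), tab2)
  expect_equal(perturbation_params(net2, "xa", tab2)$n, 0L)
  expect_error(perturbation_params(net, u, tab), "already in")
})

test_that("the analytical prediction evaluates the topology formula", {
  expect_equal(predict_perturbation(list(n = 1, m = 0, sigma_G = 1, e = 1)),
               list(p_hat = 1, valid = TRUE))
  expect_equal(
    predict_perturbation(list(n = 1, m = 1, sigma_G = 2, e = 1))$p_hat,
    1 / 3
  )
  # innovation limit: vanishes for overwhelming background strength
  expect_lt(predict_perturbation(list(n = 1, m = 0, sigma_G = 1e6,
                                      e = 1))$p_hat, 3e-6)
  # m = 0: strictly decreasing in s = sigma_G / e
  s <- seq(0.2, 20, by = 0.2)
  p0 <- sapply(s, function(si) {
    predict_perturbation(list(n = 2, m = 0, sigma_G = si, e = 1))$p_hat
  })
  expect_true(all(diff(p0) < 0))
  # m = 1, n = 1: interior maximum in s
  p1 <- sapply(s, function(si) {
    predict_perturbation(list(n = 1, m = 1, sigma_G = si, e = 1))$p_hat
  })
  imax <- which.max(p1)
  expect_gt(imax, 1)
  expect_lt(imax, length(p1))
  # out-of-validity values reported as-is with the flag down
  out <- predict_perturbation(list(n = 3, m = 4, sigma_G = 1, e = 1))
  expect_lt(out$p_hat, 0)
  expect_false(out$valid)
  expect_error(predict_perturbation(list(n = 1, m = 0, sigma_G = 0, e = 1)),
               "sigma_G")
  expect_error(predict_perturbation(list(n = 1, m = 0, sigma_G = 1, e = 0)),
               "e must")
})

test_that("direct in-degree perturbation obeys the generalized formula", {
  # on any instance where all target fraction changes are positive:
  # p = 2 e n (sigma - D_T) / (sigma (sigma + n e)),
  # D_T = total prior in-degree of the added catalyst's targets
  set.seed(11)
  checked <- 0L
  while (checked < 100L) {
    tab <- random_alpha_table(L = 5, n_pos = 10)
    pool <- unique(make_species(sample(letters[1:5], 8, replace = TRUE),
                                sample(letters[1:5], 8, replace = TRUE)))
    if (length(pool) < 4L) next
    species <- pool[-1]
    a <- pool[1]
    net <- build_network(species, tab)
    sigma <- sum(net$A[net$A > 0])
    if (sigma <= 0) next
    pa <- split_species(a)
    rates_in <- tab$alpha[pa$igs, net$tag]
    targets <- which(rates_in > 0)
    n <- length(targets)
    if (n == 0L) next
    # the formula requires a uniform rate e into all targets; enforce it
    # by overwriting the added catalyst's igs row
    e <- max(rates_in[targets])
    tab$alpha[pa$igs, ] <- ifelse(tab$alpha[pa$igs, ] > 0, e, 0)
    net <- build_network(species, tab)
    sigma <- sum(net$A[net$A > 0])
    rates_in <- tab$alpha[pa$igs, net$tag]
    targets <- which(rates_in > 0)
    D_T <- sum(rowSums(net$A)[targets])
    # validity: every target's fraction must increase
    d_t <- rowSums(net$A)[targets]
    if (any(d_t >= sigma / n)) next
    p_direct <- indegree_perturbation_direct(net$species, a, tab)
    p_formula <- 2 * e * n * (sigma - D_T) / (sigma * (sigma + n * e))
    expect_equal(p_direct, p_formula, tolerance = 1e-10)
    checked <- checked + 1L
  }
})

test_that("landscape scans find exactly the single-addition pairs", {
  tab <- default_rate_table()
  comps <- list()
  comps[[network_key(c("GC", "CG"))]] <- c(GC = 0.5, CG = 0.5)
  comps[[network_key(c("GC", "CG", "AU"))]] <- c(GC = 0.45, CG = 0.45,
                                                 AU = 0.10)
  recs <- enumerate_perturbation_pairs(comps)
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$added_species, "AU")
  expect_equal(recs$p,
               perturbation(comps[[1]], comps[[2]], c("GC", "CG")))
  # no nested pairs: empty result
  comps2 <- list()
  comps2[[network_key(c("GC", "CG"))]] <- c(GC = 0.5, CG = 0.5)
  comps2[[network_key(c("AU", "UA"))]] <- c(AU = 0.5, UA = 0.5)
  expect_equal(nrow(enumerate_perturbation_pairs(comps2)), 0L)
  # full subset landscape: record count equals the brute-force pair count
  sp4 <- c("GC", "CG", "AU", "UA")
  subsets <- unlist(lapply(1:4, function(k) {
    combn(sp4, k, simplify = FALSE)
  }), recursive = FALSE)
  comps3 <- list()
  for (ss in subsets) {
    comps3[[network_key(ss)]] <- stats::setNames(rep(1 / length(ss),
                                                     length(ss)), ss)
  }
  recs3 <- enumerate_perturbation_pairs(comps3, table = tab)
  brute <- 0L
  for (i in seq_along(subsets)) {
    for (j in seq_along(subsets)) {
      si <- subsets[[i]]
      sj <- subsets[[j]]
      if (length(sj) == length(si) + 1L && all(si %in% sj)) brute <- brute + 1L
    }
  }
  expect_equal(nrow(recs3), brute)
  expect_true(all(c("n", "m", "sigma_G", "e", "p_hat", "valid") %in%
                    names(recs3)))
})

test_that("per-network mean perturbation matches direct re-aggregation", {
  expect_equal(mean_perturbation(data.frame(G_id = "g", Gp_id = "gp",
                                            p = 0.4))$mean_p, 0.4)
  expect_equal(mean_perturbation(data.frame(G_id = "g",
                                            p = c(0.2, 0.4)))$mean_p, 0.3)
  set.seed(13)
  recs <- data.frame(G_id = sample(paste0("g", 1:8), 50, replace = TRUE),
                     p = runif(50, 0, 2))
  got <- mean_perturbation(recs)
  want <- tapply(recs$p, recs$G_id, mean)
  expect_equal(got$mean_p, as.numeric(want[got$G_id]))
})
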