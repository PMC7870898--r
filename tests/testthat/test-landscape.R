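make_droplets <- function(n, networks, seed = 1) {
  # random droplet table over a named list of fixed compositions; Dirichlet
  # noise keeps fractions on the simplex
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    key <- sample(names(networks), 1)
    f <- networks[[key]]
    noisy <- stats::rgamma(length(f), shape = 50 * f + 0.1)
    noisy <- noisy / sum(noisy)
    data.frame(droplet_id = sprintf("d%04d", i), species = names(f),
               fraction = noisy, yield_uM = runif(1, 0.01, 0.2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("aggregation groups droplets by species set and conserves counts", {
  nets <- list()
  nets[[network_key(c("GC", "CG"))]] <- c(GC = 0.6, CG = 0.4)
  nets[[network_key(c("AU", "UA", "GC"))]] <- c(AU = 0.2, UA = 0.3, GC = 0.5)
  dr <- make_droplets(100, nets, seed = 2)
  agg <- aggregate_networks(dr)
  expect_equal(length(unique(agg$network_id)), 2L)
  # total droplet count preserved
  reps <- unique(agg[, c("network_id", "n_replicates")])
  expect_equal(sum(reps$n_replicates), 100L)
  # mean fractions sum to 1 within each network
  sums <- tapply(agg$mean_fraction, agg$network_id, sum)
  expect_equal(as.vector(sums), rep(1, 2), tolerance = 1e-12)
  # mean, sd and SEM match a brute-force recomputation for one cell
  key <- network_key(c("GC", "CG"))
  ids <- unique(dr$droplet_id[!dr$droplet_id %in%
                                dr$droplet_id[dr$species %in% c("AU", "UA")]])
  gc_vals <- dr$fraction[dr$species == "GC" & dr$droplet_id %in% ids]
  got <- agg[agg$network_id == key & agg$species == "GC", ]
  expect_equal(got$mean_fraction, mean(gc_vals))
  expect_equal(got$sd_fraction, sd(gc_vals))
  ya <- tapply(dr$yield_uM[dr$droplet_id %in% ids],
               dr$droplet_id[dr$droplet_id %in% ids], `[`, 1)
  expect_equal(got$mean_yield_uM, mean(ya))
  expect_equal(got$sem_yield, sd(ya) / sqrt(length(ya)))
  # three droplets of one network give a single 3-replicate record
  one <- make_droplets(3, nets[1], seed = 3)
  agg1 <- aggregate_networks(one)
  expect_equal(unique(agg1$n_replicates), 3L)
  expect_equal(length(unique(agg1$network_id)), 1L)
})

test_that("rank conservation flags pairs whose ordering flips", {
  # identical ranking everywhere: nothing flips
  land <- do.call(rbind, lapply(1:6, function(i) {
    data.frame(network_id = paste0("n", i), species = c("GC", "AU"),
               mean_fraction = c(0.7, 0.3))
  }))
  rc <- rank_conservation(land)
  expect_equal(as.numeric(rc), 0)
  # one pair flipped in 2 of 10 networks (20% >= 10%): non-conserved
  land2 <- do.call(rbind, lapply(1:10, function(i) {
    up <- i <= 2
    data.frame(network_id = paste0("n", i), species = c("GC", "AU"),
               mean_fraction = if (up) c(0.3, 0.7) else c(0.7, 0.3))
  }))
  rc2 <- rank_conservation(land2)
  expect_equal(as.numeric(rc2), 1)
  expect_true(attr(rc2, "pairs")$non_conserved[1])
  expect_equal(attr(rc2, "pairs")$minority_share[1], 0.2)
  # a flip rarer than the threshold stays conserved
  land3 <- do.call(rbind, lapply(1:20, function(i) {
    up <- i <= 1
    data.frame(network_id = paste0("n", i), species = c("GC", "AU"),
               mean_fraction = if (up) c(0.3, 0.7) else c(0.7, 0.3))
  }))
  expect_equal(as.numeric(rank_conservation(land3)), 0)
  # independent catalysts with fixed rates: ranking is forced, nothing flips
  fixed <- c(GC = 0.5, CG = 0.3, AU = 0.2)
  land4 <- do.call(rbind, lapply(1:8, function(i) {
    sp <- sort(sample(names(fixed), sample(2:3, 1)))
    f <- fixed[sp] / sum(fixed[sp])
    data.frame(network_id = network_key(sp), species = sp,
               mean_fraction = unname(f))
  }))
  expect_equal(as.numeric(rank_conservation(land4)), 0)
  expect_error(rank_conservation(land[land$network_id == "n1", ]),
               "co-occurs|two distinct")
})

test_that("yield ranking filters by replicates and orders ascending", {
  land <- data.frame(
    network_id = c("a", "b", "c", "d"),
    size = 4,
    species = "GC",  # single representative row per network
    mean_fraction = 1,
    sd_fraction = 0,
    n_replicates = c(12, 9, 30, 11),
    mean_yield_uM = c(0.1, 0.05, 0.3, 0.2),
    sem_yield = 0.01
  )
  rk <- yield_ranking(land, size = 4, min_replicates = 10)
  expect_equal(rk$network_id, c("a", "d", "c"))  # 9-replicate net excluded
  expect_equal(rk$rank, 1:3)
  expect_equal(attr(rk, "fold_range"), 3)
  expect_equal(nrow(yield_ranking(land, size = 7)), 0L)
})

test_that("the trade-off test matches hypergeometric enumeration", {
  # balanced table: no association
  rec <- data.frame(p = rep(c(1, 1, 0.1, 0.1), each = 5),
                    yield_uM = rep(c(0.2, 0.02, 0.2, 0.02), each = 5))
  res <- tradeoff_test(rec)
  expect_equal(unname(res$table[1, 1]), 5)
  expect_equal(res$odds_ratio, 1, tolerance = 1e-6)
  # perfect trade-off: p-value equals the one-sided hypergeometric tail
  rec2 <- data.frame(p = c(rep(1, 10), rep(0.1, 10)),
                     yield_uM = c(rep(0.02, 10), rep(0.2, 10)))
  res2 <- tradeoff_test(rec2)
  expect_equal(unname(res2$table[1, 1]), 0)
  expect_equal(res2$p_value, hyper_tail_le(0, res2$table), tolerance = 1e-12)
  expect_equal(res2$odds_ratio, 0)
  # random small tables: implementation equals direct tail enumeration
  set.seed(17)
  for (i in 1:20) {
    n <- sample(8:40, 1)
    rec3 <- data.frame(p = sample(c(0.1, 1), n, replace = TRUE),
                       yield_uM = sample(c(0.02, 0.2), n, replace = TRUE))
    if (length(unique(rec3$p)) < 2 || length(unique(rec3$yield_uM)) < 2) next
    res3 <- tradeoff_test(rec3)
    expect_equal(res3$p_value, hyper_tail_le(res3$table[1, 1], res3$table),
                 tolerance = 1e-10)
  }
  # degenerate margin: warning and p = 1
  rec4 <- data.frame(p = rep(0.1, 6), yield_uM = rep(c(0.02, 0.2), 3))
  expect_warning(res4 <- tradeoff_test(rec4), "degenerate")
  expect_equal(res4$p_value, 1)
})

test_that("background-strength/yield correlation behaves on known inputs", {
  tab <- default_rate_table()
  keys <- list(c("GC", "CG"), c("GC", "AU"), c("AU", "UA"),
               c("GC", "CG", "AU"), c("GC", "CG", "AU", "UA"),
               c("AC", "CA"), c("GA", "AG"), c("GC", "UA"))
  sigma <- vapply(keys, function(k) background_strength(k, tab), 0)
  land <- do.call(rbind, lapply(seq_along(keys), function(i) {
    sp <- keys[[i]]
    data.frame(network_id = network_key(sp), size = length(sp), species = sp,
               mean_fraction = 1 / length(sp), sd_fraction = 0,
               n_replicates = 11, mean_yield_uM = 2 * sigma[i],
               sem_yield = 0.001)
  }))
  res <- sigma_yield_correlation(land, tab, min_bin = 1)
  expect_equal(res$r, 1, tolerance = 1e-12)
  # shuffling yields against sigma destroys the correlation on average
  set.seed(19)
  rs <- replicate(100, {
    land2 <- land
    perm <- sample(unique(land$network_id))
    y <- stats::setNames(2 * sigma, unique(land$network_id))
    land2$mean_yield_uM <- unname(y[perm][match(land2$network_id,
                                                unique(land$network_id))])
    sigma_yield_correlation(land2, tab, min_bin = 1)$r
  })
  expect_lt(abs(mean(rs)), 0.2)
  expect_gt(stats::quantile(rs, 0.975), 0)
  expect_lt(stats::quantile(rs, 0.025), 0)
  expect_error(sigma_yield_correlation(land[1:2, ], tab), "three")
})

test_that("kinetic-model landscapes reproduce the sigma-yield association", {
  tab <- default_rate_table()
  set.seed(23)
  keys <- unique(replicate(40, {
    network_key(sample(azoarcus_species(), 4))
  }))
  # keep networks with nonzero production (a defined composition)
  keys <- keys[vapply(keys, function(k) {
    sum(build_network(key_species(k), tab)$b) > 0
  }, TRUE)]
  land <- do.call(rbind, lapply(keys, function(k) {
    sp <- key_species(k)
    net <- build_network(sp, tab)
    data.frame(network_id = k, size = 4, species = sp,
               mean_fraction = unname(predict_fractions(net)),
               sd_fraction = 0, n_replicates = 11,
               mean_yield_uM = predict_yield(net), sem_yield = 0.001)
  }))
  res <- sigma_yield_correlation(land, tab, min_bin = 2)
  expect_gt(res$r, 0)
})

test_that("model-measurement correlation pools matched fraction pairs", {
  tab <- default_rate_table()
  set.seed(29)
  keys <- unique(replicate(200, network_key(sample(azoarcus_species(),
                                                   sample(3:5, 1)))))
  keys <- keys[vapply(keys, function(k) {
    sum(build_network(key_species(k), tab)$b) > 0
  }, TRUE)]
  pred <- do.call(rbind, lapply(keys, function(k) {
    sp <- key_species(k)
    data.frame(network_id = k, species = sp,
               fraction = unname(predict_fractions(build_network(sp, tab))))
  }))
  ident <- model_measurement_correlation(pred, pred, min_bin = 1)
  expect_equal(ident$r, 1, tolerance = 1e-12)
  # multinomial resampling at depth 100 keeps the correlation high
  meas <- do.call(rbind, lapply(split(pred, pred$network_id), function(d) {
    counts <- as.vector(stats::rmultinom(1, 100, d$fraction))
    d$fraction <- counts / sum(counts)
    d
  }))
  res <- model_measurement_correlation(pred, meas)
  expect_gt(res$r, 0.9)
  expect_equal(res$n, nrow(pred))
  disjoint <- pred
  disjoint$network_id <- paste0("x_", disjoint$network_id)
  expect_error(model_measurement_correlation(pred[1:3, ], disjoint[4:6, ]),
               "overlap")
})
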