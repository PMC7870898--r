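# Aggregation of droplet-level compositions into a network landscape and
# the landscape-level statistics (rank conservation, yield ranking,
# growth-variation trade-off, connectivity correlations).

#' Aggregate droplet measurements into network records
#'
#' Groups droplets by identical species set and computes per-network mean
#' and standard deviation of species fractions, replicate counts, and mean
#' yield with its standard error.
#'
#' @param droplets Long data frame with one row per droplet x species:
#'   columns `droplet_id`, `species`, `fraction`, and optionally `yield_uM`
#'   (constant within a droplet). Each droplet's rows define its species
#'   set; species a droplet lacks entirely are treated as absent, not zero.
#' @return Long data frame (one row per network x species) with columns
#'   `network_id`, `size`, `species`, `mean_fraction`, `sd_fraction`,
#'   `n_replicates`, `mean_yield_uM`, `sem_yield`, ordered by network key.
#' @export
aggregate_networks <- function(droplets) {
  stopifnot(is.data.frame(droplets),
            all(c("droplet_id", "species", "fraction") %in% names(droplets)))
  has_yield <- "yield_uM" %in% names(droplets)
  by_drop <- split(droplets, droplets$droplet_id)
  keys <- vapply(by_drop, function(d) network_key(d$species), "")
  by_net <- split(by_drop, keys)
  rows <- lapply(names(by_net), function(key) {
    drops <- by_net[[key]]
    sp <- key_species(key)
    frac_mat <- vapply(drops, function(d) {
      stats::setNames(d$fraction, d$species)[sp]
    }, numeric(length(sp)))
    frac_mat <- matrix(frac_mat, nrow = length(sp),
                       dimnames = list(sp, NULL))
    n_rep <- length(drops)
    yields <- if (has_yield) {
      vapply(drops, function(d) d$yield_uM[1L], 0)
    } else {
      rep(NA_real_, n_rep)
    }
    data.frame(
      network_id = key,
      size = length(sp),
      species = sp,
      mean_fraction = rowMeans(frac_mat),
      sd_fraction = apply(frac_mat, 1L, stats::sd),
      n_replicates = n_rep,
      mean_yield_uM = mean(yields),
      sem_yield = stats::sd(yields) / sqrt(n_rep),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$network_id, out$species), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of species pairs with non-conserved ranking
#'
#' If catalysts accumulated independently, the within-network ranking of
#' any two species' fractions would be identical across all networks
#' containing both. For every unordered species pair co-occurring in at
#' least two networks, this computes the share of those networks showing
#' the minority orientation (strict inequality; exact ties count as
#' conserved) and classifies the pair as non-conserved when that share
#' reaches `flip_threshold`. Returns the fraction of non-conserved pairs.
#'
#' @param landscape Data frame from [aggregate_networks()] (columns
#'   `network_id`, `species`, `mean_fraction`).
#' @param flip_threshold Minimum minority share for a pair to count as
#'   non-conserved (default 0.10 = "differed in at least 10% of networks").
#' @return Fraction in `[0, 1]`, with attribute `pairs`: a data frame with
#'   one row per evaluated pair (`species_1`, `species_2`, `n_networks`,
#'   `minority_share`, `non_conserved`).
#' @export
rank_conservation <- function(landscape, flip_threshold = 0.10) {
  comps <- .as_composition_list(landscape)
  all_sp <- sort(unique(unlist(lapply(comps, names))))
  if (length(all_sp) < 2L) stop("need at least two distinct species")
  pair_rows <- list()
  for (i in seq_len(length(all_sp) - 1L)) {
    for (j in seq.int(i + 1L, length(all_sp))) {
      u <- all_sp[i]
      v <- all_sp[j]
      both <- vapply(comps, function(cc) u %in% names(cc) && v %in% names(cc),
                     TRUE)
      n_both <- sum(both)
      if (n_both < 2L) next
      diffs <- vapply(comps[both], function(cc) cc[[u]] - cc[[v]], 0)
      n_gt <- sum(diffs > 0)
      n_lt <- sum(diffs < 0)
      minority <- min(n_gt, n_lt) / n_both
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        species_1 = u, species_2 = v, n_networks = n_both,
        minority_share = minority,
        non_conserved = minority >= flip_threshold,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(pair_rows) == 0L) {
    stop("no species pair co-occurs in at least two networks")
  }
  pairs <- do.call(rbind, pair_rows)
  frac <- mean(pairs$non_conserved)
  attr(frac, "pairs") <- pairs
  frac
}

#' Rank networks of one size by mean yield
#'
#' Filters the landscape to networks of the given size with at least
#' `min_replicates` droplet replicates and ranks them from lowest to
#' highest mean yield (ties broken by network key).
#'
#' @param landscape Data frame from [aggregate_networks()].
#' @param size Species count of the networks to rank.
#' @param min_replicates Minimum replicate count to include (default 10).
#' @return Data frame `network_id`, `n_replicates`, `mean_yield_uM`,
#'   `sem_yield`, `rank`, with attribute `fold_range` = max/min mean yield.
#' @export
yield_ranking <- function(landscape, size, min_replicates = 10) {
  stopifnot(is.data.frame(landscape),
            all(c("network_id", "size", "n_replicates", "mean_yield_uM")
                %in% names(landscape)))
  nets <- unique(landscape[, c("network_id", "size", "n_replicates",
                               "mean_yield_uM", "sem_yield")])
  nets <- nets[nets$size == size & nets$n_replicates >= min_replicates, ,
               drop = FALSE]
  nets <- nets[order(nets$mean_yield_uM, nets$network_id), , drop = FALSE]
  nets$rank <- seq_len(nrow(nets))
  rownames(nets) <- NULL
  out <- nets[, c("network_id", "n_replicates", "mean_yield_uM",
                  "sem_yield", "rank")]
  attr(out, "fold_range") <- if (nrow(out) > 0 && min(out$mean_yield_uM) > 0) {
    max(out$mean_yield_uM) / min(out$mean_yield_uM)
  } else {
    NA_real_
  }
  out
}

#' Test the trade-off between strong perturbability and high yield
#'
#' Cross-classifies perturbation records by strong perturbation
#' (`p > p_threshold`) and high yield (`yield > yield_threshold_uM`) and
#' tests, with a one-sided Fisher exact test, whether strongly perturbable
#' high-yield networks are rarer than expected under independence. The
#' odds ratio is the conditional maximum-likelihood estimate with its 95%
#' confidence interval.
#'
#' @param records Data frame with numeric columns `p` and `yield_uM`.
#' @param p_threshold Perturbation cut (default 0.8).
#' @param yield_threshold_uM Yield cut in uM (default 0.08).
#' @return List with `table` (2x2 contingency, strong x high-yield),
#'   `p_value`, `odds_ratio`, `conf_int`, `n`. A degenerate margin raises
#'   a warning and returns `p_value = 1`.
#' @export
tradeoff_test <- function(records, p_threshold = 0.8,
                          yield_threshold_uM = 0.08) {
  stopifnot(is.data.frame(records),
            all(c("p", "yield_uM") %in% names(records)))
  records <- records[is.finite(records$p) & is.finite(records$yield_uM), ,
                     drop = FALSE]
  strong <- factor(records$p > p_threshold, levels = c(TRUE, FALSE))
  high <- factor(records$yield_uM > yield_threshold_uM,
                 levels = c(TRUE, FALSE))
  tab <- table(strong = strong, high_yield = high)
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    warning("degenerate contingency table: an entire margin is empty")
    return(list(table = tab, p_value = 1, odds_ratio = NA_real_,
                conf_int = c(NA_real_, NA_real_), n = nrow(records)))
  }
  # alternative "less": fewer strong-and-high-yield than independence
  ft <- stats::fisher.test(tab, alternative = "less")
  list(table = tab, p_value = ft$p.value,
       odds_ratio = unname(ft$estimate),
       conf_int = unname(stats::fisher.test(tab)$conf.int),
       n = nrow(records))
}

#' Background strength of a species set
#'
#' Sum of the rates of all catalytic interactions present within the
#' network (ordered pairs at or above the edge threshold, self-loops
#' included), in min^-1.
#'
#' @param species Character vector of species codes, or a
#'   `reaction_network`.
#' @param table A [rate_table()] (ignored when `species` is a network).
#' @return `sigma_G` in min^-1.
#' @export
background_strength <- function(species, table = NULL) {
  net <- if (inherits(species, "reaction_network")) {
    species
  } else {
    build_network(species, table)
  }
  sum(net$A[net$A >= net$edge_threshold & net$A > 0])
}

#' Correlation between background strength and network yield
#'
#' Pearson correlation between `sigma_G` and mean yield across networks,
#' with a binned summary following the figure convention (decile bins along
#' `sigma_G`; bins with fewer than `min_bin` points discarded).
#'
#' @param landscape Data frame from [aggregate_networks()].
#' @param table A [rate_table()] used to compute `sigma_G` per network.
#' @param n_bins Number of quantile bins (default 10).
#' @param min_bin Minimum points for a bin to be reported (default 10).
#' @return List with `r`, `p_value`, `n`, `networks` (per-network
#'   `sigma_G` and yield) and `bins` (binned means).
#' @export
sigma_yield_correlation <- function(landscape, table, n_bins = 10,
                                    min_bin = 10) {
  stopifnot(is.data.frame(landscape),
            all(c("network_id", "mean_yield_uM") %in% names(landscape)))
  nets <- unique(landscape[, c("network_id", "mean_yield_uM")])
  if (nrow(nets) < 3L) stop("need at least three networks")
  nets$sigma_G <- vapply(nets$network_id, function(k) {
    background_strength(key_species(k), table)
  }, 0)
  if (stats::sd(nets$sigma_G) == 0 || stats::sd(nets$mean_yield_uM) == 0) {
    stop("undefined correlation: constant sigma_G or yield")
  }
  ct <- stats::cor.test(nets$sigma_G, nets$mean_yield_uM)
  bins <- .bin_means(nets$sigma_G, nets$mean_yield_uM, n_bins, min_bin)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(nets),
       networks = nets, bins = bins)
}

.bin_means <- function(x, y, n_bins, min_bin) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2L) return(data.frame())
  bin <- cut(x, breaks = br, include.lowest = TRUE)
  counts <- tapply(y, bin, length)
  keep <- !is.na(counts) & counts >= min_bin
  data.frame(
    bin = names(counts)[keep],
    mid = tapply(x, bin, mean)[keep],
    mean_y = tapply(y, bin, mean)[keep],
    n = as.integer(counts[keep]),
    row.names = NULL
  )
}

#' Correlation between model-predicted and measured fractions
#'
#' Pools matched (network, species) fraction pairs and reports their
#' Pearson correlation, with decile-binned means of the measured fractions
#' along the predicted axis (bins with fewer than `min_bin` points
#' discarded, per the figure convention).
#'
#' @param predicted,measured Long data frames with columns `network_id`,
#'   `species` and `fraction` (or `mean_fraction`).
#' @param n_bins,min_bin Binning as in [sigma_yield_correlation()].
#' @return List with `r`, `n`, `pairs`, `bins`.
#' @export
model_measurement_correlation <- function(predicted, measured, n_bins = 10,
                                          min_bin = 10) {
  pr <- .fraction_frame(predicted, "predicted")
  me <- .fraction_frame(measured, "measured")
  pairs <- merge(pr, me, by = c("network_id", "species"))
  if (nrow(pairs) == 0L) stop("no overlapping (network, species) keys")
  r <- stats::cor(pairs$predicted, pairs$measured)
  bins <- .bin_means(pairs$predicted, pairs$measured, n_bins, min_bin)
  list(r = r, n = nrow(pairs), pairs = pairs, bins = bins)
}

.fraction_frame <- function(df, value_name) {
  if (!is.data.frame(df)) {
    comps <- .as_composition_list(df)
    df <- do.call(rbind, lapply(names(comps), function(k) {
      data.frame(network_id = k, species = names(comps[[k]]),
                 fraction = as.vector(comps[[k]]), stringsAsFactors = FALSE)
    }))
  }
  fcol <- intersect(c("fraction", "mean_fraction"), names(df))[1]
  if (is.na(fcol)) stop("need a fraction or mean_fraction column")
  out <- df[, c("network_id", "species")]
  out[[value_name]] <- df[[fcol]]
  out
}
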