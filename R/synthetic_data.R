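# Seeded generators emulating the droplet-fusion experiment: the
# entropy-maximizing fragment-combination design, droplet fusion and
# barcoded-sequencing simulation, and titration data.

#' Simulate a doped-catalyst titration
#'
#' Initial rates of covalent ribozyme formation as a linear function of
#' doped covalent catalyst concentration, `v0 = alpha * x + beta`, with
#' additive Gaussian measurement noise.
#'
#' @param alpha Slope (min^-1).
#' @param beta Intercept (uM min^-1).
#' @param x Doped concentrations in uM, all `>= 0`.
#' @param noise_sd Gaussian noise standard deviation (uM min^-1), `>= 0`.
#' @param seed Optional integer seed.
#' @return Data frame with columns `x` and `v0`.
#' @export
simulate_titration <- function(alpha, beta, x, noise_sd = 0, seed = NULL) {
  if (any(x < 0)) stop("doped concentrations must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  v0 <- alpha * x + beta + stats::rnorm(length(x), sd = noise_sd)
  data.frame(x = x, v0 = v0)
}

# eigenvalue summaries of the union network induced by a set of species,
# memoized per network key inside `cache` (an environment)
.network_lambdas <- function(species, table, cache) {
  key <- network_key(species)
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  net <- build_network(species, table)
  ev <- eigen(net$A, only.values = TRUE)$values
  if (is.complex(ev)) {
    ev <- ev[order(Re(ev), decreasing = TRUE)]
    ev <- Re(ev)
  } else {
    ev <- sort(ev, decreasing = TRUE)
  }
  l1 <- ev[1L]
  gap <- if (length(ev) > 1L) ev[1L] - ev[2L] else 0
  out <- c(l1 = l1, gap = gap)
  cache[[key]] <- out
  out
}

.random_assignment <- function(n_combinations, total_slots, species_pool) {
  sizes <- rep(1L, n_combinations)
  extra <- total_slots - n_combinations
  max_size <- length(species_pool)
  while (extra > 0L) {
    open <- which(sizes < max_size)
    pick <- open[sample.int(length(open), 1L)]
    sizes[pick] <- sizes[pick] + 1L
    extra <- extra - 1L
  }
  lapply(sizes, function(s) sort(sample(species_pool, s)))
}

.histogram_entropy <- function(x, n_bins) {
  rng <- range(x)
  if (diff(rng) == 0) return(0)
  br <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  p <- tabulate(cut(x, breaks = br, include.lowest = TRUE), nbins = n_bins)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

.score_assignment <- function(combos, table, n_fusion_sims, fusion_k,
                              n_bins, cache) {
  n_c <- length(combos)
  ks <- sample(fusion_k, n_fusion_sims, replace = TRUE)
  l1 <- numeric(n_fusion_sims)
  gap <- numeric(n_fusion_sims)
  keys <- character(n_fusion_sims)
  for (i in seq_len(n_fusion_sims)) {
    tubes <- sample.int(n_c, ks[i], replace = TRUE)
    sp <- unique(unlist(combos[tubes]))
    lam <- .network_lambdas(sp, table, cache)
    l1[i] <- lam["l1"]
    gap[i] <- lam["gap"]
    keys[i] <- network_key(sp)
  }
  h1 <- .histogram_entropy(l1, n_bins)
  h2 <- .histogram_entropy(gap, n_bins)
  list(score = h1 + h2, entropy_lambda1 = h1, entropy_gap = h2,
       n_distinct = length(unique(keys)))
}

#' Choose the total fragment-slot count maximizing network diversity
#'
#' First design stage: for each candidate total slot count, random
#' fragment assignments are simulated through random droplet fusions and
#' the number of distinct networks formed is averaged; the slot count with
#' the highest mean diversity is selected.
#'
#' @param candidates Integer vector of total slot counts to evaluate.
#' @param table A [rate_table()]; default [default_rate_table()].
#' @param n_combinations Number of fragment mixtures (default 24).
#' @param n_assignments Random assignments averaged per candidate.
#' @param n_fusion_sims Simulated fusions per assignment.
#' @param fusion_k Fusion-count support (default 1..5, uniform).
#' @param species_pool Species to draw from (default the 16 MN species).
#' @param seed Optional integer seed.
#' @return Data frame `total_slots`, `mean_distinct_networks`, with
#'   attribute `best` (the argmax slot count).
#' @export
choose_total_slots <- function(candidates, table = default_rate_table(),
                               n_combinations = 24, n_assignments = 5,
                               n_fusion_sims = 1000, fusion_k = 1:5,
                               species_pool = azoarcus_species(),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(candidates < n_combinations)) {
    stop("infeasible slot count: need at least one slot per combination")
  }
  cache <- new.env(parent = emptyenv())
  means <- vapply(candidates, function(slots) {
    mean(vapply(seq_len(n_assignments), function(i) {
      combos <- .random_assignment(n_combinations, slots, species_pool)
      n_c <- length(combos)
      keys <- vapply(seq_len(n_fusion_sims), function(j) {
        tubes <- sample.int(n_c, sample(fusion_k, 1L), replace = TRUE)
        network_key(unique(unlist(combos[tubes])))
      }, "")
      length(unique(keys))
    }, 0))
  }, 0)
  out <- data.frame(total_slots = candidates,
                    mean_distinct_networks = means)
  attr(out, "best") <- candidates[which.max(means)]
  out
}

#' Design fragment combinations by entropy maximization
#'
#' Distributes `total_slots` fragment slots (with redundancy) over
#' `n_combinations` mixtures and selects, among random assignments, the
#' one maximizing the summed Shannon entropies of the distributions of the
#' expected growth rate (first eigenvalue of the network rate matrix) and
#' transient time (first minus second eigenvalue) over networks formed by
#' simulated random droplet fusions. Defaults are desk-scale
#' (`n_candidates = 1000`, `n_fusion_sims = 1000`); the original
#' experiment screened 100,000 candidates over 10,000 fusions.
#'
#' @param table A [rate_table()]; default [default_rate_table()].
#' @param n_combinations Number of fragment mixtures (default 24).
#' @param total_slots Total fragment slots across mixtures (default 50).
#' @param n_candidates Random assignments evaluated.
#' @param n_fusion_sims Simulated fusions per assignment.
#' @param fusion_k Fusion-count support (default 1..5, uniform).
#' @param n_bins Fixed-width histogram bins for the entropy scores.
#' @param species_pool Species to draw from (default the 16 MN species).
#' @param seed Optional integer seed.
#' @return Object of class `combination_design`: list with `combinations`
#'   (named list of species vectors), `total_slots`, `scores` (entropy
#'   components, total score, distinct-network count of the winner), and
#'   `n_candidates`.
#' @export
design_combinations <- function(table = default_rate_table(),
                                n_combinations = 24, total_slots = 50,
                                n_candidates = 1000, n_fusion_sims = 1000,
                                fusion_k = 1:5, n_bins = 20,
                                species_pool = azoarcus_species(),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (total_slots < n_combinations) {
    stop("infeasible slot count: need at least one slot per combination")
  }
  if (total_slots > n_combinations * length(species_pool)) {
    stop("infeasible slot count: more slots than distinct species fit")
  }
  cache <- new.env(parent = emptyenv())
  best <- NULL
  candidate_scores <- numeric(n_candidates)
  for (cand in seq_len(n_candidates)) {
    combos <- .random_assignment(n_combinations, total_slots, species_pool)
    sc <- .score_assignment(combos, table, n_fusion_sims, fusion_k,
                            n_bins, cache)
    candidate_scores[cand] <- sc$score
    if (is.null(best) || sc$score > best$scores$score) {
      best <- list(combinations = combos, scores = sc)
    }
  }
  names(best$combinations) <- sprintf("c%02d", seq_len(n_combinations))
  structure(
    list(combinations = best$combinations, total_slots = total_slots,
         scores = best$scores, candidate_scores = candidate_scores,
         n_candidates = n_candidates, n_fusion_sims = n_fusion_sims),
    class = "combination_design"
  )
}

#' @export
print.combination_design <- function(x, ...) {
  cat("Combination design:", length(x$combinations), "mixtures,",
      x$total_slots, "slots; entropy score",
      signif(x$scores$score, 4), "\n")
  invisible(x)
}

#' Reporter map of a combination design
#'
#' Hairpin reporter ids co-encapsulated with each fragment mixture, mapped
#' to the species the mixture encodes; this is the `reporter_map` consumed
#' by [pipeline_config()].
#'
#' @param design A [design_combinations()] result.
#' @return Named list of species vectors.
#' @export
design_reporter_map <- function(design) {
  stopifnot(inherits(design, "combination_design"))
  design$combinations
}

#' Read / write combination designs as JSON
#'
#' @param design A `combination_design` to write.
#' @param file Path to a JSON file.
#' @return The design ([read_design()]) or `file`, invisibly.
#' @export
write_design <- function(design, file) {
  stopifnot(inherits(design, "combination_design"))
  jsonlite::write_json(
    list(combinations = design$combinations,
         total_slots = design$total_slots,
         scores = design$scores[c("score", "entropy_lambda1",
                                  "entropy_gap", "n_distinct")]),
    file, auto_unbox = TRUE, digits = NA
  )
  invisible(file)
}

#' @rdname write_design
#' @export
read_design <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  structure(
    list(combinations = as.list(obj$combinations),
         total_slots = obj$total_slots,
         scores = as.list(obj$scores),
         n_candidates = NA_integer_, n_fusion_sims = NA_integer_),
    class = "combination_design"
  )
}

#' Simulation configuration for the droplet experiment
#'
#' @param n_droplets Number of fused droplets to simulate.
#' @param fusion_probs Probabilities of fusing 1..5 small droplets
#'   (default uniform; must sum to 1).
#' @param mean_ribozyme_umis Mean ribozyme UMIs per droplet (Poisson).
#' @param mean_hairpin_umis Mean hairpin UMIs per retained reporter
#'   (Poisson).
#' @param mean_reads_per_umi Mean reads per genuine UMI; counts are
#'   `1 + Poisson(mean - 1)`.
#' @param error_umi_rate Poisson mean of spurious singleton-read UMIs per
#'   droplet (sequencing noise removed by the read filter).
#' @param t Incubation time in minutes.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_droplets = 1000,
                              fusion_probs = rep(0.2, 5),
                              mean_ribozyme_umis = 200,
                              mean_hairpin_umis = 30,
                              mean_reads_per_umi = 5,
                              error_umi_rate = 2,
                              t = 60) {
  stopifnot(n_droplets >= 1, length(fusion_probs) >= 1,
            all(fusion_probs >= 0),
            abs(sum(fusion_probs) - 1) < 1e-9,
            mean_ribozyme_umis > 0, mean_hairpin_umis > 0,
            mean_reads_per_umi >= 1, error_umi_rate >= 0, t > 0)
  structure(
    list(n_droplets = n_droplets, fusion_probs = fusion_probs,
         mean_ribozyme_umis = mean_ribozyme_umis,
         mean_hairpin_umis = mean_hairpin_umis,
         mean_reads_per_umi = mean_reads_per_umi,
         error_umi_rate = error_umi_rate, t = t),
    class = "simulation_config"
  )
}

#' Simulate the droplet-fusion sequencing experiment
#'
#' For each simulated fused droplet: the number of small droplets is drawn
#' from the fusion distribution, fragment mixtures are drawn with
#' replacement from the design, their union defines the reaction network,
#' and the true composition and yield are computed with the kinetic model
#' at incubation time. Hairpin UMIs are emitted per encoded reporter and
#' ribozyme UMIs are drawn multinomially from the true fractions, each
#' with a reads-per-UMI count; spurious low-count error UMIs exercise the
#' read filter. The ground truth is returned alongside the UMI table.
#'
#' @param design A [design_combinations()] result (or any
#'   `combination_design`).
#' @param table A [rate_table()].
#' @param config A [simulation_config()].
#' @param seed Optional integer seed.
#' @return List with `umi_records` (data frame in the
#'   [dedup_umis()] schema), `truth` (long data frame `droplet_id`,
#'   `species`, `fraction`, `yield_uM`, `network_id`, `n_fused`), and
#'   `reporter_map`.
#' @export
simulate_experiment <- function(design, table, config = simulation_config(),
                                seed = NULL) {
  stopifnot(inherits(design, "combination_design"),
            inherits(table, "rate_table"),
            inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  combos <- design$combinations
  n_c <- length(combos)
  all_species <- sort(unique(unlist(combos)))
  frac_cache <- new.env(parent = emptyenv())
  network_truth <- function(sp) {
    key <- network_key(sp)
    hit <- frac_cache[[key]]
    if (!is.null(hit)) return(hit)
    net <- build_network(sp, table)
    # a species set without any catalytic pairing accumulates no covalent
    # ribozymes; such droplets sequence (almost) no ribozyme UMIs and are
    # later rejected by the pipeline thresholds
    f <- tryCatch(predict_fractions(net, config$t), error = function(e) {
      stats::setNames(rep(0, length(net$species)), net$species)
    })
    y <- if (sum(f) > 0) predict_yield(net, config$t) else 0
    out <- list(fractions = f, yield = y, key = key)
    frac_cache[[key]] <- out
    out
  }
  umi_rows <- vector("list", config$n_droplets)
  truth_rows <- vector("list", config$n_droplets)
  umi_counter <- 0L
  new_umis <- function(n) {
    ids <- sprintf("u%08x", umi_counter + seq_len(n))
    umi_counter <<- umi_counter + n
    ids
  }
  ks <- sample(seq_along(config$fusion_probs), config$n_droplets,
               replace = TRUE, prob = config$fusion_probs)
  for (d in seq_len(config$n_droplets)) {
    bc <- sprintf("bc%06d", d)
    tubes <- sample.int(n_c, ks[d], replace = TRUE)
    reporters <- sort(unique(names(combos)[tubes]))
    sp <- sort(unique(unlist(combos[tubes])))
    tr <- network_truth(sp)
    # hairpin UMIs per encoded reporter
    hp_n <- stats::rpois(length(reporters), config$mean_hairpin_umis)
    hp_n <- pmax(hp_n, 1L)
    hp_total <- sum(hp_n)
    # ribozyme UMIs ~ multinomial(depth, true fractions)
    depth <- stats::rpois(1L, config$mean_ribozyme_umis)
    rb_counts <- if (depth > 0L && sum(tr$fractions) > 0) {
      as.vector(stats::rmultinom(1L, depth, tr$fractions))
    } else {
      integer(length(sp))
    }
    mol <- c(rep(reporters, hp_n), rep(sp, rb_counts))
    n_mol <- length(mol)
    reads <- 1L + stats::rpois(n_mol, config$mean_reads_per_umi - 1)
    # spurious singleton UMIs on random species
    n_err <- stats::rpois(1L, config$error_umi_rate)
    if (n_err > 0L) {
      mol <- c(mol, sample(all_species, n_err, replace = TRUE))
      reads <- c(reads, rep(1L, n_err))
      n_mol <- n_mol + n_err
    }
    umi_rows[[d]] <- data.frame(
      droplet_barcode = bc, molecule_id = mol, umi = new_umis(n_mol),
      read_count = reads, stringsAsFactors = FALSE
    )
    truth_rows[[d]] <- data.frame(
      droplet_id = bc, species = sp, fraction = as.vector(tr$fractions),
      yield_uM = tr$yield, network_id = tr$key, n_fused = ks[d],
      stringsAsFactors = FALSE
    )
  }
  list(
    umi_records = do.call(rbind, umi_rows),
    truth = do.call(rbind, truth_rows),
    reporter_map = combos
  )
}
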