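# Network growth by single-species accretion: per-step perturbations,
# cumulative series, inflexion detection and sharpness, catalytic
# innovations, and the chemistry-density ensemble study.

#' Construct an abstract IGS/tag chemistry
#'
#' An abstract chemistry has `L` IGS letters and `L` tag letters, hence an
#' `L x L` grid of possible species, and a designated pool of "specific"
#' (IGS, tag) letter pairs that carry catalytic rate; all other pairs are
#' inert. The pool pairs letter i's IGS with letter i+1's tag (a cyclic
#' matching, the abstract analogue of base-pair complementarity), capped at
#' 24 pairs. Catalytic density is varied by random removal among the pool:
#' `density` is the retained fraction of pool pairs, and the resulting
#' probability that one random species catalyzes another
#' (`catalytic_density` = retained pairs / L^2) is recorded alongside.
#'
#' A two-tier rate structure mirrors the concrete chemistry's strong (G.C,
#' C.G) versus weak (A.U, U.A) hierarchy: `n_strong` retained pairs carry
#' `rate` and the rest `rate * weak_ratio`. With `n_strong = NULL` (the
#' default) all pairs are uniform at `rate`, as in the density study.
#'
#' @param L Alphabet size (letters `l01`, `l02`, ...).
#' @param n_pairs Pool size before removal (default `min(L, 24)`).
#' @param density Fraction of the pool retained, in (0, 1].
#' @param rate Catalytic rate e of a specific pair (min^-1).
#' @param n_strong Number of retained pairs designated strong, or `NULL`
#'   for a uniform-rate chemistry.
#' @param weak_ratio Rate ratio of non-strong to strong pairs.
#' @param beta_ratio `beta = beta_ratio * alpha` for the induced table.
#' @return Object of class `chemistry`: list with `L`, `letters`, `pairs`
#'   (data frame `igs`, `tag`, `rate`, `strong`), `density`,
#'   `catalytic_density`, `table` (the induced [rate_table()]), `species`
#'   (all L^2 codes).
#' @export
#' @examples
#' chem <- make_chemistry(L = 6, density = 1)
#' chem$catalytic_density
make_chemistry <- function(L = 24, n_pairs = min(L, 24), density = 1,
                           rate = 0.02, n_strong = NULL, weak_ratio = 0.3,
                           beta_ratio = 0.1) {
  stopifnot(L >= 2, n_pairs >= 1, n_pairs <= L * L,
            density > 0, density <= 1, rate > 0)
  letters_ <- sprintf("l%02d", seq_len(L))
  pool <- data.frame(
    igs = letters_[seq_len(n_pairs)],
    tag = letters_[(seq_len(n_pairs) %% L) + 1L],
    stringsAsFactors = FALSE
  )
  n_keep <- max(1L, round(density * n_pairs))
  keep <- sort(sample.int(n_pairs, n_keep))
  pairs <- pool[keep, , drop = FALSE]
  if (is.null(n_strong)) {
    pairs$rate <- rate
    pairs$strong <- TRUE
  } else {
    stopifnot(n_strong >= 0, n_strong <= nrow(pairs))
    strong_idx <- sample.int(nrow(pairs), n_strong)
    pairs$strong <- seq_len(nrow(pairs)) %in% strong_idx
    pairs$rate <- ifelse(pairs$strong, rate, rate * weak_ratio)
  }
  rownames(pairs) <- NULL
  alpha <- matrix(0, L, L, dimnames = list(letters_, letters_))
  alpha[cbind(pairs$igs, pairs$tag)] <- pairs$rate
  table <- rate_table(alpha, alpha * beta_ratio)
  grid <- expand.grid(tag = letters_, igs = letters_, stringsAsFactors = FALSE)
  structure(
    list(L = L, letters = letters_, pairs = pairs, density = density,
         catalytic_density = nrow(pairs) / L^2, table = table,
         species = sort(make_species(grid$igs, grid$tag))),
    class = "chemistry"
  )
}

#' @export
print.chemistry <- function(x, ...) {
  cat("Abstract chemistry:", x$L, "x", x$L, "species grid,",
      nrow(x$pairs), "specific pair(s), catalytic density",
      signif(x$catalytic_density, 3), "\n")
  invisible(x)
}

#' Strong IGS/tag pair types of a rate table
#'
#' The pairs carrying the table's maximal first-order rate; for the
#' concrete chemistry these are C.G and G.C.
#'
#' @param table A [rate_table()].
#' @param tol Relative tolerance on equality with the maximum.
#' @return Data frame with columns `igs`, `tag`.
#' @export
strong_pairs <- function(table, tol = 1e-9) {
  stopifnot(inherits(table, "rate_table"))
  a <- table$alpha
  mx <- max(a)
  if (mx <= 0) {
    return(data.frame(igs = character(), tag = character()))
  }
  idx <- which(a >= mx * (1 - tol), arr.ind = TRUE)
  data.frame(igs = rownames(a)[idx[, 1L]], tag = colnames(a)[idx[, 2L]],
             stringsAsFactors = FALSE)
}

#' Simulate one network-growth trajectory
#'
#' Starting from a uniform random set of `start_size` species, one species
#' is added at a time (uniformly without replacement from the pool) up to
#' `end_size`. Each addition's perturbation `p` is computed with
#' [perturbation()] on the common species set before the addition, using
#' in-degree compositions (fast, matching the analytical theory) or, on
#' request, kinetic-model compositions. Steps with zero composition mass
#' (no catalysis yet) contribute `p = 0` and a warning.
#'
#' @param pool Species pool: a `chemistry`, a character vector of species
#'   codes, or `NULL` for the concrete 16-species set.
#' @param table [rate_table()] of the chemistry; taken from a `chemistry`
#'   pool automatically, default [default_rate_table()] otherwise.
#' @param start_size,end_size Initial and final species counts.
#' @param composition `"indegree"` (default) or `"kinetic"`.
#' @param t Incubation time for kinetic compositions (min).
#' @param seed Optional integer seed for reproducibility.
#' @return Object of class `trajectory`: list with `start_species`,
#'   `steps` (data frame `step`, `added_species`, `n_targets`, `p`, `P`,
#'   `innovation`), `pool_size`, `table`.
#' @export
#' @examples
#' traj <- grow_trajectory(start_size = 3, end_size = 8, seed = 1)
#' traj$steps
grow_trajectory <- function(pool = NULL, table = NULL, start_size = 3,
                            end_size = 16,
                            composition = c("indegree", "kinetic"),
                            t = 60, seed = NULL) {
  composition <- match.arg(composition)
  if (inherits(pool, "chemistry")) {
    if (is.null(table)) table <- pool$table
    pool <- pool$species
  }
  if (is.null(pool)) pool <- azoarcus_species()
  if (is.null(table)) table <- default_rate_table()
  stopifnot(start_size >= 1, end_size > start_size)
  if (end_size > length(pool)) {
    stop("pool exhausted: end_size exceeds the ", length(pool),
         "-species pool")
  }
  if (!is.null(seed)) set.seed(seed)
  order_all <- sample(pool, end_size)
  start_species <- order_all[seq_len(start_size)]
  additions <- order_all[(start_size + 1L):end_size]
  parts <- split_species(order_all)
  alpha <- table$alpha
  thr <- table$edge_threshold
  sp_list <- strong_pairs(table)
  sp_key <- paste(sp_list$igs, sp_list$tag)

  cur_igs <- parts$igs[seq_len(start_size)]
  cur_tag <- parts$tag[seq_len(start_size)]
  igs_letters <- rownames(alpha)
  igs_count <- stats::setNames(integer(length(igs_letters)), igs_letters)
  for (g in cur_igs) igs_count[g] <- igs_count[g] + 1L

  present_types <- function(igs_count, tags) {
    # strong pair types realized as edges in the current network
    have_igs <- names(igs_count)[igs_count > 0L]
    realized <- sp_key[sp_list$igs %in% have_igs & sp_list$tag %in% tags &
                         alpha[cbind(sp_list$igs, sp_list$tag)] >= thr]
    realized
  }

  K <- length(additions)
  p_vec <- numeric(K)
  n_vec <- integer(K)
  innov <- logical(K)
  zero_mass_steps <- 0L
  seen_types <- present_types(igs_count, cur_tag)

  for (k in seq_len(K)) {
    a_igs <- parts$igs[start_size + k]
    a_tag <- parts$tag[start_size + k]
    # in-degree of current species from current catalysts
    w_tag <- as.vector(igs_count %*% alpha)  # incoming weight per tag letter
    names(w_tag) <- colnames(alpha)
    indeg_before <- w_tag[cur_tag]
    rates_from_a <- alpha[a_igs, cur_tag]
    n_vec[k] <- sum(rates_from_a >= thr & rates_from_a > 0)

    if (composition == "indegree") {
      indeg_after <- indeg_before + alpha[a_igs, cur_tag]
      s_b <- sum(indeg_before)
      s_a <- sum(indeg_after)
      if (s_b <= 0 || s_a <= 0) {
        p_vec[k] <- 0
        zero_mass_steps <- zero_mass_steps + 1L
      } else {
        p_vec[k] <- sum(abs(indeg_after / s_a - indeg_before / s_b))
      }
    } else {
      cur_sp <- make_species(cur_igs, cur_tag)
      new_sp <- make_species(c(cur_igs, a_igs), c(cur_tag, a_tag))
      cb <- tryCatch(predict_fractions(build_network(cur_sp, table), t),
                     error = function(e) NULL)
      ca <- tryCatch(predict_fractions(build_network(new_sp, table), t),
                     error = function(e) NULL)
      if (is.null(cb) || is.null(ca)) {
        p_vec[k] <- 0
        zero_mass_steps <- zero_mass_steps + 1L
      } else {
        p_vec[k] <- perturbation(cb, ca, cur_sp)
      }
    }

    # innovation: the addition realizes a strong pair type absent so far
    cur_igs <- c(cur_igs, a_igs)
    cur_tag <- c(cur_tag, a_tag)
    igs_count[a_igs] <- igs_count[a_igs] + 1L
    types_now <- present_types(igs_count, cur_tag)
    innov[k] <- length(setdiff(types_now, seen_types)) > 0L
    seen_types <- union(seen_types, types_now)
  }
  if (zero_mass_steps > 0L) {
    warning(zero_mass_steps,
            " step(s) had zero composition mass; recorded as p = 0")
  }
  steps <- data.frame(
    step = seq_len(K),
    added_species = additions,
    n_targets = n_vec,
    p = p_vec,
    P = cumsum(p_vec),
    innovation = innov,
    stringsAsFactors = FALSE
  )
  structure(
    list(start_species = start_species, steps = steps,
         pool_size = length(pool), composition = composition, table = table),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Growth trajectory:", length(x$start_species), "->",
      length(x$start_species) + nrow(x$steps), "species,",
      sum(x$steps$innovation), "innovation step(s)\n")
  invisible(x)
}

#' Locate inflexions in a cumulative perturbation series
#'
#' Uses the discrete second difference
#' `d2[k] = P[k+1] - 2 P[k] + P[k-1]`; an inflexion sits at an interior
#' index `k` where `d2` changes sign between `k` and the next nonzero
#' value (touching zero before changing counts). Sharpness is the
#' magnitude of the third-difference stencil at the inflexion,
#' `|P[k+2] - 3 P[k+1] + 3 P[k] - P[k-1]|`. The addition whose
#' perturbation breaks the curvature is step `k + 1`, reported as `step`.
#'
#' @param P Numeric cumulative perturbation series (length >= 4), or a
#'   `trajectory`.
#' @param zero_tol Relative tolerance below which a second difference is
#'   treated as exactly zero (guards against round-off creating spurious
#'   sign changes).
#' @return Data frame with columns `index` (k), `step` (k + 1), and
#'   `sharpness`; zero rows when the series has no curvature change.
#' @export
#' @examples
#' find_inflexions(c(0, 0.1, 0.2, 1.8, 1.9, 2.0))
find_inflexions <- function(P, zero_tol = 1e-8) {
  if (inherits(P, "trajectory")) P <- P$steps$P
  K <- length(P)
  if (K < 4L) stop("cumulative series too short: need at least 4 points")
  ks <- 2:(K - 1L)
  d2 <- P[ks + 1L] - 2 * P[ks] + P[ks - 1L]  # d2[i] is at index ks[i]
  sgn <- sign(d2)
  sgn[abs(d2) < zero_tol * max(abs(P))] <- 0
  out <- list()
  nz <- which(sgn != 0)
  if (length(nz) >= 2L) {
    for (i in seq_len(length(nz) - 1L)) {
      a <- nz[i]
      b <- nz[i + 1L]
      if (sgn[a] != sgn[b]) {
        k <- ks[a]  # last index carrying the old curvature sign
        if (k > K - 2L) next  # stencil needs P[k + 2]
        sharp <- abs(P[k + 2L] - 3 * P[k + 1L] + 3 * P[k] - P[k - 1L])
        out[[length(out) + 1L]] <- data.frame(index = k, step = k + 1L,
                                              sharpness = sharp)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(index = integer(), step = integer(),
                      sharpness = numeric()))
  }
  do.call(rbind, out)
}

#' Flag strong inflexions by ensemble sharpness percentile
#'
#' An inflexion is strong when its sharpness reaches the given percentile
#' of the ensemble's sharpness values (linear-interpolation percentile,
#' default the 75th: "top 25% in sharpness").
#'
#' @param sharpness Numeric vector of sharpness values (>= 1 value).
#' @param percentile Percentile cut in `[0, 100]` (default 75).
#' @return Logical vector of strong flags, with attribute `threshold`.
#' @export
#' @examples
#' classify_strong(1:100)  # strong from 76 upward
classify_strong <- function(sharpness, percentile = 75) {
  if (length(sharpness) == 0L) stop("need at least one sharpness value")
  thr <- unname(stats::quantile(sharpness, probs = percentile / 100,
                                type = 7, names = FALSE))
  out <- sharpness >= thr
  attr(out, "threshold") <- thr
  out
}

#' Label catalytic-innovation steps of a trajectory
#'
#' A step is a catalytic innovation when the added species realizes at
#' least one edge whose (IGS, tag) letter pair belongs to the designated
#' strong pairs (for the concrete chemistry, C.G and G.C) and that pair
#' type was absent from all edges of the network before the addition.
#'
#' @param traj A [grow_trajectory()] result.
#' @return Logical vector, one flag per addition step (as stored in
#'   `traj$steps$innovation`).
#' @export
label_innovations <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  traj$steps$innovation
}

#' Annotate a trajectory's inflexions
#'
#' Convenience wrapper joining [find_inflexions()] output with the
#' trajectory's per-step innovation flags and targeting breadths.
#'
#' @param traj A `trajectory`.
#' @return Data frame `index`, `step`, `sharpness`, `innovation`,
#'   `n_targets`, `p`.
#' @export
trajectory_inflexions <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  infl <- find_inflexions(traj$steps$P)
  if (nrow(infl) == 0L) {
    infl$innovation <- logical()
    infl$n_targets <- integer()
    infl$p <- numeric()
    return(infl)
  }
  infl$innovation <- traj$steps$innovation[infl$step]
  infl$n_targets <- traj$steps$n_targets[infl$step]
  infl$p <- traj$steps$p[infl$step]
  infl
}

#' Ensemble study of growth trajectories across catalytic densities
#'
#' For each density, builds a chemistry by random removal among the pool
#' of specific IGS/tag pairs, simulates `n_traj` growth trajectories, and
#' pools their inflexions. Strong inflexions are classified at the
#' `percentile` sharpness cut within each density's pooled ensemble
#' (per-trajectory classification available by flag). Summaries report,
#' per density: mean targeting breadth of strong-perturbation catalysts
#' versus inflexion rank, waiting time (species additions) between
#' consecutive strong inflexions versus rank, and the distribution of
#' strong-inflexion counts per trajectory.
#'
#' @param L,n_pairs,rate Chemistry construction (see [make_chemistry()]).
#' @param densities Numeric vector of pool-retention fractions.
#' @param n_traj Trajectories per density (default 1000).
#' @param start_size,end_size Trajectory span (defaults 2 -> 100).
#' @param percentile Strong-inflexion sharpness percentile (default 75).
#' @param per_trajectory Classify strong inflexions within each trajectory
#'   instead of the pooled ensemble.
#' @param seed Integer seed; every density and trajectory derives its own
#'   substream deterministically.
#' @return Object of class `trajectory_study`: list with `densities` and,
#'   per density, `chemistry`, `inflexions` (pooled data frame with
#'   trajectory id, rank, sharpness, strong, innovation, n_targets,
#'   waiting), `strong_counts` (per-trajectory table),
#'   `breadth_by_rank`, `waiting_by_rank`, and `per_trajectory` stats.
#' @export
simulate_trajectory_study <- function(L = 24, n_pairs = min(L, 24),
                                      densities = c(0.25, 0.5, 1),
                                      n_traj = 1000, start_size = 2,
                                      end_size = 100, rate = 0.02,
                                      percentile = 75,
                                      per_trajectory = FALSE, seed = NULL) {
  if (end_size > L * L) {
    stop("insufficient species pool: need L^2 >= end_size")
  }
  if (!is.null(seed)) set.seed(seed)
  density_seeds <- sample.int(.Machine$integer.max, length(densities))
  res <- vector("list", length(densities))
  names(res) <- as.character(densities)
  for (di in seq_along(densities)) {
    set.seed(density_seeds[di])
    chem <- make_chemistry(L = L, n_pairs = n_pairs,
                           density = densities[di], rate = rate)
    traj_seeds <- sample.int(.Machine$integer.max, n_traj)
    infl_rows <- vector("list", n_traj)
    innov_counts <- integer(n_traj)
    for (ti in seq_len(n_traj)) {
      traj <- suppressWarnings(
        grow_trajectory(chem, start_size = start_size, end_size = end_size,
                        seed = traj_seeds[ti])
      )
      innov_counts[ti] <- sum(traj$steps$innovation)
      infl <- trajectory_inflexions(traj)
      if (nrow(infl) > 0L) {
        infl$trajectory <- ti
        infl_rows[[ti]] <- infl
      }
    }
    pooled <- do.call(rbind, infl_rows[!vapply(infl_rows, is.null, TRUE)])
    if (is.null(pooled) || nrow(pooled) == 0L) {
      res[[di]] <- list(chemistry = chem, inflexions = NULL,
                        strong_counts = table(factor(integer(n_traj))),
                        innovation_counts = innov_counts,
                        breadth_by_rank = data.frame(),
                        waiting_by_rank = data.frame())
      next
    }
    if (per_trajectory) {
      pooled$strong <- unlist(lapply(split(pooled$sharpness,
                                           pooled$trajectory),
                                     classify_strong,
                                     percentile = percentile),
                              use.names = FALSE)
      pooled <- pooled[order(pooled$trajectory, pooled$step), , drop = FALSE]
    } else {
      pooled$strong <- as.logical(classify_strong(pooled$sharpness,
                                                  percentile = percentile))
    }
    # rank and waiting time among strong inflexions, per trajectory
    strong_df <- pooled[pooled$strong, , drop = FALSE]
    strong_df <- strong_df[order(strong_df$trajectory, strong_df$step), ,
                           drop = FALSE]
    rank_ <- stats::ave(strong_df$step, strong_df$trajectory,
                        FUN = seq_along)
    # waiting time is defined between two consecutive strong inflexions,
    # so the first strong inflexion of a trajectory has none
    prev_step <- stats::ave(strong_df$step, strong_df$trajectory,
                            FUN = function(s) c(NA, s[-length(s)]))
    strong_df$rank <- as.integer(rank_)
    strong_df$waiting <- strong_df$step - prev_step
    n_strong_per_traj <- tabulate(
      factor(strong_df$trajectory, levels = seq_len(n_traj)),
      nbins = n_traj
    )
    breadth_by_rank <- stats::aggregate(
      n_targets ~ rank, data = strong_df, FUN = mean
    )
    breadth_by_rank$n <- stats::aggregate(
      n_targets ~ rank, data = strong_df, FUN = length
    )$n_targets
    w_ok <- strong_df[!is.na(strong_df$waiting), , drop = FALSE]
    waiting_by_rank <- if (nrow(w_ok) > 0L) {
      out <- stats::aggregate(waiting ~ rank, data = w_ok, FUN = mean)
      out$n <- stats::aggregate(waiting ~ rank, data = w_ok,
                                FUN = length)$waiting
      out
    } else {
      data.frame(rank = integer(), waiting = numeric(), n = integer())
    }
    res[[di]] <- list(
      chemistry = chem,
      inflexions = pooled,
      strong = strong_df,
      strong_counts = table(n_strong_per_traj),
      n_strong_per_trajectory = n_strong_per_traj,
      innovation_counts = innov_counts,
      breadth_by_rank = breadth_by_rank,
      waiting_by_rank = waiting_by_rank
    )
  }
  structure(list(densities = densities, per_density = res,
                 n_traj = n_traj, start_size = start_size,
                 end_size = end_size, percentile = percentile),
            class = "trajectory_study")
}

#' @export
print.trajectory_study <- function(x, ...) {
  cat("Trajectory study:", x$n_traj, "trajectories per density,",
      x$start_size, "->", x$end_size, "species\n")
  for (d in names(x$per_density)) {
    pd <- x$per_density[[d]]
    n_inf <- if (is.null(pd$inflexions)) 0L else nrow(pd$inflexions)
    cat("  density", d, ":", n_inf, "inflexions,",
        if (!is.null(pd$strong)) nrow(pd$strong) else 0L, "strong\n")
  }
  invisible(x)
}
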