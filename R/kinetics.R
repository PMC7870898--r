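# Linear kinetic model: xdot_i = sum_j alpha_ij x_j + beta_ij, x(0) = 0.
# Solved exactly through the exponential of the augmented matrix
# [[A, b], [0, 0]], which handles singular A without inversion.

#' Solve the linear kinetic model
#'
#' Covalent catalysts of species j (concentration `x_j`) contribute
#' `alpha_ij * x_j` to the formation rate of species i, noncovalent
#' complexes contribute the constant `beta_ij`; stacking gives
#' `xdot = A x + b` with `x(0) = 0`. The exact solution at time `t` is
#' read off the matrix exponential of the augmented system
#' `[[A, b], [0, 0]]`, valid whether or not `A` is invertible.
#'
#' @param net A [build_network()] reaction network.
#' @param t Time in minutes, `>= 0`.
#' @return Named numeric vector of covalent catalyst concentrations (uM),
#'   one per species, with attribute `t`.
#' @export
#' @examples
#' net <- build_network(c("GC", "CG"), default_rate_table())
#' solve_kinetics(net, 60)
solve_kinetics <- function(net, t) {
  stopifnot(inherits(net, "reaction_network"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop("t must be a single nonnegative time in minutes")
  }
  n <- length(net$species)
  M <- rbind(cbind(net$A, net$b), 0)
  E <- as.matrix(Matrix::expm(Matrix::Matrix(M * t)))
  x <- E[seq_len(n), n + 1L]
  x <- pmax(x, 0)  # clip exponential round-off at magnitudes ~1e-16
  names(x) <- net$species
  attr(x, "t") <- t
  x
}

.check_t_positive <- function(t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t <= 0) {
    stop("t must be a single positive time in minutes")
  }
}

#' Predict species fractions from the kinetic model
#'
#' Fractions are the covalent catalyst concentrations at the incubation
#' time divided by their total, `x_i(t) / sum_j x_j(t)`. The default
#' `t = 60` min matches a 1-h incubation.
#'
#' @inheritParams solve_kinetics
#' @param t Incubation time in minutes, `> 0`.
#' @return Named numeric vector of fractions summing to 1.
#' @export
predict_fractions <- function(net, t = 60) {
  .check_t_positive(t)
  x <- solve_kinetics(net, t)
  total <- sum(x)
  if (total <= 0) {
    stop("undefined composition: no production into any species (all beta 0)")
  }
  f <- as.vector(x) / total
  names(f) <- net$species
  f
}

#' Predict network yield from the kinetic model
#'
#' Total covalent catalyst concentration accumulated by time `t`,
#' `sum_i x_i(t)` in uM; nondecreasing in `t`.
#'
#' @inheritParams solve_kinetics
#' @return Yield in uM.
#' @export
predict_yield <- function(net, t = 60) {
  sum(solve_kinetics(net, t))
}

#' In-degree centrality fractions
#'
#' The weighted in-degree of species i sums the rates of all catalysts
#' present in the network that target it: `c_i = sum_j w(igs_j, tag_i)`
#' with `w` either the first-order `alpha` rates (covalent regime) or the
#' zeroth-order `beta` rates (noncovalent regime). In the beta-only limit
#' of the kinetic model the composition equals the beta-weighted in-degree
#' fractions at every time.
#'
#' @inheritParams solve_kinetics
#' @param weights `"alpha"` or `"beta"`.
#' @return Named numeric vector of fractions summing to 1.
#' @export
indegree_fractions <- function(net, weights = c("alpha", "beta")) {
  stopifnot(inherits(net, "reaction_network"))
  weights <- match.arg(weights)
  c_i <- switch(weights, alpha = rowSums(net$A), beta = net$b)
  total <- sum(c_i)
  if (total <= 0) {
    stop("undefined composition: all in-degree weights are zero")
  }
  f <- c_i / total
  names(f) <- net$species
  f
}

#' Eigenvector centrality fractions
#'
#' Leading eigenvector of the first-order rate matrix `A`, computed by
#' power iteration from the uniform vector and L1-normalized. For a
#' nonnegative `A` with a simple positive dominant eigenvalue this is the
#' long-time direction of the kinetic model.
#'
#' @inheritParams solve_kinetics
#' @param tol Convergence tolerance on the L1 change per iteration.
#' @param max_iter Iteration cap; hitting it flags non-convergence.
#' @return Named numeric fraction vector with attributes `converged`
#'   (logical) and `iterations`. A warning is raised on non-convergence
#'   (e.g. rotational degeneracy of the dominant eigenvalues).
#' @export
eigenvector_fractions <- function(net, tol = 1e-12, max_iter = 10000L) {
  stopifnot(inherits(net, "reaction_network"))
  A <- net$A
  if (all(A == 0)) stop("undefined composition: rate matrix is zero")
  n <- nrow(A)
  v <- rep(1 / n, n)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- as.vector(A %*% v)
    s <- sum(abs(w))
    if (s == 0) {
      # uniform start fell in the null space; restart from a perturbed vector
      v <- stats::runif(n)
      v <- v / sum(v)
      next
    }
    w <- w / s
    if (sum(abs(w - v)) < tol) {
      v <- w
      converged <- TRUE
      break
    }
    v <- w
  }
  if (!converged) {
    warning("power iteration did not converge within ", max_iter,
            " iterations; dominant eigenvalue may be degenerate")
  }
  f <- abs(v) / sum(abs(v))
  names(f) <- net$species
  attr(f, "converged") <- converged
  attr(f, "iterations") <- iter
  f
}

#' Compare in-degree and eigenvector centrality across networks
#'
#' Pools (network, species) fraction pairs from both centralities over a
#' list of networks and reports their Pearson correlation, flagging species
#' that strongly catalyze their own production (self-loop at or above the
#' edge threshold), for which in-degree underestimates the eigenvector
#' fraction.
#'
#' @param nets List of `reaction_network` objects (length >= 2).
#' @return List with `correlation`, `n_pairs`, `skipped` (count of networks
#'   with degenerate compositions), and `pairs`: a data frame with columns
#'   `network`, `species`, `indegree`, `eigenvector`, `strong_self_loop`.
#' @export
compare_centralities <- function(nets) {
  if (!is.list(nets) || length(nets) < 2L) {
    stop("need a list of at least two networks")
  }
  rows <- vector("list", length(nets))
  skipped <- 0L
  for (k in seq_along(nets)) {
    net <- nets[[k]]
    fi <- tryCatch(indegree_fractions(net, "alpha"), error = function(e) NULL)
    fe <- tryCatch(suppressWarnings(eigenvector_fractions(net)),
                   error = function(e) NULL)
    if (is.null(fi) || is.null(fe)) {
      skipped <- skipped + 1L
      message("skipping network ", k, ": degenerate composition")
      next
    }
    self_rate <- diag(net$A)
    rows[[k]] <- data.frame(
      network = k,
      species = net$species,
      indegree = as.vector(fi),
      eigenvector = as.vector(fe),
      strong_self_loop = self_rate >= net$edge_threshold & self_rate > 0,
      stringsAsFactors = FALSE
    )
  }
  pairs <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(pairs) || nrow(pairs) < 2L) {
    stop("not enough non-degenerate networks to correlate")
  }
  if (isTRUE(all.equal(pairs$indegree, pairs$eigenvector, tolerance = 1e-9))) {
    r <- 1  # identical predictors (e.g. all-symmetric networks)
  } else if (stats::sd(pairs$indegree) == 0 ||
             stats::sd(pairs$eigenvector) == 0) {
    warning("a centrality is constant across the pool; correlation undefined")
    r <- NA_real_
  } else {
    r <- stats::cor(pairs$indegree, pairs$eigenvector)
  }
  list(correlation = r, n_pairs = nrow(pairs), skipped = skipped,
       pairs = pairs)
}
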