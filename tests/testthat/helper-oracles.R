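# Shared fixtures and independent oracles, all built in code.

# rate table from an explicit alpha matrix (letters a, b, c, ...)
table_from_alpha <- function(alpha, beta = alpha * 0.1,
                             edge_threshold = NULL) {
  rate_table(alpha, beta, edge_threshold = edge_threshold)
}

# uniform k-cycle in an abstract matching chemistry:
# species (l0i, l0i) with pairs l0i -> l0(i+1)
uniform_cycle <- function(k, rate = 0.02) {
  chem <- make_chemistry(L = k, density = 1, rate = rate)
  sp <- make_species(chem$letters, chem$letters)
  list(species = sp, table = chem$table, rate = rate)
}

# random rate table over `L` letters with `n_pos` positive random pairs
random_alpha_table <- function(L = 5, n_pos = 8, rate_range = c(0.005, 0.03),
                               beta_ratio = 0.1) {
  letters_ <- letters[seq_len(L)]
  alpha <- matrix(0, L, L, dimnames = list(letters_, letters_))
  idx <- sample.int(L * L, min(n_pos, L * L))
  alpha[idx] <- stats::runif(length(idx), rate_range[1], rate_range[2])
  rate_table(alpha, alpha * beta_ratio, edge_threshold = 1e-9)
}

# independent ODE oracle: adaptive numeric integration of xdot = A x + b
ode_solve <- function(net, t, rtol = 1e-10, atol = 1e-12) {
  deriv <- function(tt, x, parms) list(as.vector(net$A %*% x + net$b))
  out <- deSolve::ode(y = rep(0, length(net$species)),
                      times = c(0, t), func = deriv, parms = NULL,
                      rtol = rtol, atol = atol)
  stats::setNames(as.vector(out[nrow(out), -1]), net$species)
}

# in-degree perturbation computed from first principles (no package
# composition code): fractions proportional to column sums of incoming
# alpha rates, renormalized on the pre-addition set
indegree_perturbation_direct <- function(species, a, table) {
  parts <- split_species(c(species, a))
  n_g <- length(species)
  indeg <- function(active_igs, tags) {
    vapply(tags, function(tg) {
      sum(table$alpha[active_igs, tg])
    }, 0)
  }
  before <- indeg(parts$igs[seq_len(n_g)], parts$tag[seq_len(n_g)])
  after <- indeg(parts$igs, parts$tag[seq_len(n_g)])
  sum(abs(after / sum(after) - before / sum(before)))
}

# construct a random instance satisfying the analytical derivation's
# assumptions: the added catalyst's targets receive prior catalysis only
# from the m same-IGS catalysts, each at rate e (total prior target
# in-degree n*m*e), with background strength large enough that all target
# fraction changes stay positive
eq1_instance <- function() {
  L <- 8
  letters_ <- letters[seq_len(L)]
  n <- sample(1:3, 1)
  m <- sample(0:2, 1)
  e <- stats::runif(1, 0.5, 2)
  alpha <- matrix(0, L, L, dimnames = list(letters_, letters_))
  alpha["a", "a"] <- e  # IGS 'a' pairs tag 'a' at rate e, nothing else
  # background pairs among letters 2..L only (never hitting tag 'a')
  others <- letters_[-1]
  repeat {
    alpha[others, others] <- 0
    n_bg <- sample(3:8, 1)
    bg <- cbind(sample(others, n_bg, replace = TRUE),
                sample(others, n_bg, replace = TRUE))
    bg <- bg[!duplicated(paste(bg[, 1], bg[, 2])), , drop = FALSE]
    alpha[bg] <- stats::runif(nrow(bg), 0.2, 1.5)
    # species: m same-IGS catalysts, n targets, a few fillers
    same_igs <- if (m > 0) {
      make_species(rep("a", m), sample(others, m))
    } else {
      character()
    }
    targets <- make_species(sample(others, n), rep("a", n))
    fillers <- unique(make_species(sample(others, 4, replace = TRUE),
                                   sample(others, 4, replace = TRUE)))
    species <- unique(c(same_igs, targets, fillers))
    if (length(unique(species)) <
          length(same_igs) + length(targets)) next
    tab <- rate_table(alpha, alpha * 0.1, edge_threshold = 1e-9)
    net <- build_network(species, tab)
    sigma <- sum(net$A[net$A > 0])
    if (sigma > n * m * e + 0.1 && sigma > 0) {
      a_new <- make_species("a", "a")  # IGS 'a', targets the tag-'a' species
      if (!a_new %in% species) {
        return(list(species = species, a = a_new, table = tab,
                    n = n, m = m, e = e))
      }
    }
  }
}

# one-sided hypergeometric tail by direct enumeration
hyper_tail_le <- function(x11, tab) {
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  N <- sum(tab)
  ks <- 0:x11
  sum(vapply(ks, function(k) {
    stats::dhyper(k, c1, N - c1, r1)
  }, 0))
}
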