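# Compositional perturbation between networks differing by one catalytic
# species, and its analytical in-degree prediction from topology.

#' Compositional perturbation between two networks
#'
#' For networks G and G' sharing the species set `V`, the perturbation is
#' the L1 distance between their compositions renormalized within `V`:
#' `p = sum_{v in V} |y'_v - y_v|`. It is symmetric in its arguments and
#' bounded by `0 <= p <= 2`; the maximum 2 is reached for a full switch in
#' species composition, e.g. fractions (0, 1) to (1, 0) on a two-species
#' common set.
#'
#' @param comp_g,comp_gp Named numeric fraction vectors (compositions of G
#'   and G'); names are species codes.
#' @param V Common species set to compare on. Default: species named in
#'   both compositions.
#' @return The perturbation `p`, dimensionless in `[0, 2]`.
#' @export
#' @examples
#' perturbation(c(u = 0, v = 1), c(u = 1, v = 0))  # full switch: 2
perturbation <- function(comp_g, comp_gp, V = NULL) {
  if (is.null(V)) V <- intersect(names(comp_g), names(comp_gp))
  if (length(V) == 0L) stop("common species set V is empty")
  if (!all(V %in% names(comp_g)) || !all(V %in% names(comp_gp))) {
    stop("V contains species absent from a composition")
  }
  y <- comp_g[V]
  yp <- comp_gp[V]
  if (any(y < 0) || any(yp < 0)) stop("fractions must be nonnegative")
  sy <- sum(y)
  syp <- sum(yp)
  if (sy <= 0 || syp <= 0) {
    stop("undefined perturbation: zero total mass on V in a composition")
  }
  sum(abs(yp / syp - y / sy))
}

#' Topology parameters of a single-species perturbation
#'
#' For the addition of catalyst `a` to network G, extracts the four
#' parameters of the analytical perturbation prediction:
#' * `n` (perturbation breadth): number of species in G whose formation `a`
#'   catalyzes (pairs at or above the edge threshold);
#' * `m` (catalytic novelty, lower m = higher novelty): number of species
#'   already in G sharing `a`'s IGS;
#' * `sigma_G` (background strength, min^-1): sum of the rates of all
#'   catalytic interactions present within G (ordered pairs at or above the
#'   edge threshold, self-loops included);
#' * `e` (min^-1): rate of the reactions catalyzed by `a`, its IGS's
#'   strong-pair `alpha` (the maximal rate over `a`'s IGS row).
#'
#' @param net The unperturbed network G.
#' @param a Species code of the added catalyst, not in G.
#' @param table The [rate_table()] of the chemistry.
#' @return List with `n`, `m`, `sigma_G`, `e`.
#' @export
perturbation_params <- function(net, a, table) {
  stopifnot(inherits(net, "reaction_network"), inherits(table, "rate_table"))
  if (a %in% net$species) stop("species '", a, "' is already in the network")
  pa <- split_species(a)
  if (!pa$igs %in% table$igs_alphabet || !pa$tag %in% table$tag_alphabet) {
    stop("species '", a, "' is outside the table's chemistry")
  }
  thr <- table$edge_threshold
  rates_to_G <- table$alpha[pa$igs, net$tag]
  n <- sum(rates_to_G >= thr & rates_to_G > 0)
  m <- sum(net$igs == pa$igs)
  active <- net$A[net$A >= thr & net$A > 0]
  sigma_G <- sum(active)
  e <- max(table$alpha[pa$igs, ])
  list(n = as.integer(n), m = as.integer(m), sigma_G = sigma_G, e = e)
}

#' Analytical perturbation prediction from topology
#'
#' The in-degree centrality approximation gives, for the addition of a
#' catalyst with breadth `n`, novelty `m`, catalytic rate `e` to a network
#' of background strength `sigma_G` (writing `s = sigma_G / e`):
#'
#' `p_hat = 2 n (1 - n m / s) / (s + n)`
#'
#' For a catalytic innovation (`m = 0`) this reduces to `2 / (1 + s / n)`,
#' strictly decreasing in the normalized background strength. The formula
#' assumes every target's fraction increases on addition; when that fails
#' (`p_hat < 0`) the value is returned as-is with `valid = FALSE` rather
#' than clamped.
#'
#' @param params List with `n`, `m`, `sigma_G`, `e` (see
#'   [perturbation_params()]), or the breadth `n` if the remaining
#'   parameters are given separately.
#' @param m,sigma_G,e Individual parameters when `params` is the scalar `n`.
#' @return List with `p_hat` and `valid`.
#' @export
#' @examples
#' predict_perturbation(list(n = 1, m = 0, sigma_G = 1, e = 1))  # 1.0
predict_perturbation <- function(params, m = NULL, sigma_G = NULL, e = NULL) {
  if (!is.list(params)) {
    params <- list(n = params, m = m, sigma_G = sigma_G, e = e)
  }
  n <- params$n
  m <- params$m
  sigma_G <- params$sigma_G
  e <- params$e
  if (is.null(e) || e <= 0) stop("e must be > 0")
  if (is.null(sigma_G) || sigma_G <= 0) {
    stop("sigma_G must be > 0 (division by the background strength)")
  }
  s <- sigma_G / e
  p_hat <- 2 * n * (1 - n * m / s) / (s + n)
  valid <- is.finite(p_hat) && p_hat >= 0 && p_hat <= 2
  list(p_hat = p_hat, valid = valid)
}

#' Enumerate all single-addition network pairs in a landscape
#'
#' Scans a landscape of network compositions for ordered pairs (G, G') with
#' `species(G') = species(G) + one species a`, and evaluates the measured
#' perturbation for each; with a rate table, the topology parameters and
#' the analytical prediction are attached.
#'
#' @param landscape Either a named list of compositions (named fraction
#'   vectors, list names = [network_key()] of the species set) or a long
#'   data frame with columns `network_id`, `species`, `fraction` (extra
#'   columns ignored), where `network_id` is the network key.
#' @param table Optional [rate_table()] to compute `n`, `m`, `sigma_G`,
#'   `e`, `p_hat` and `valid` per record.
#' @param source Label recorded in the `source` column stating where the
#'   compositions came from (e.g. `"measured"`, `"kinetic"`, `"indegree"`).
#' @return Data frame of perturbation records with columns `G_id`, `Gp_id`,
#'   `added_species`, `p`, `source` and, with a table, `n`, `m`, `sigma_G`,
#'   `e`, `p_hat`, `valid`. Zero rows when no nested pair exists.
#' @export
enumerate_perturbation_pairs <- function(landscape, table = NULL,
                                         source = "measured") {
  comps <- .as_composition_list(landscape)
  keys <- names(comps)
  species_sets <- lapply(keys, key_species)
  names(species_sets) <- keys
  recs <- list()
  for (kp in keys) {
    sp_p <- species_sets[[kp]]
    if (length(sp_p) < 2L) next
    for (a in sp_p) {
      kg <- network_key(setdiff(sp_p, a))
      if (!kg %in% keys) next
      V <- species_sets[[kg]]
      p <- tryCatch(perturbation(comps[[kg]], comps[[kp]], V),
                    error = function(e) NA_real_)
      rec <- data.frame(G_id = kg, Gp_id = kp, added_species = a, p = p,
                        source = source, stringsAsFactors = FALSE)
      if (!is.null(table)) {
        net <- build_network(V, table)
        par <- perturbation_params(net, a, table)
        pred <- tryCatch(predict_perturbation(par),
                         error = function(e) list(p_hat = NA_real_,
                                                  valid = FALSE))
        rec$n <- par$n
        rec$m <- par$m
        rec$sigma_G <- par$sigma_G
        rec$e <- par$e
        rec$p_hat <- pred$p_hat
        rec$valid <- pred$valid
      }
      recs[[length(recs) + 1L]] <- rec
    }
  }
  if (length(recs) == 0L) {
    out <- data.frame(G_id = character(), Gp_id = character(),
                      added_species = character(), p = numeric(),
                      source = character(), stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, recs)
  out <- out[order(out$G_id, out$Gp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.as_composition_list <- function(landscape) {
  if (is.data.frame(landscape)) {
    need <- c("network_id", "species")
    fcol <- intersect(c("fraction", "mean_fraction"), names(landscape))[1]
    if (!all(need %in% names(landscape)) || is.na(fcol)) {
      stop("landscape data frame needs columns network_id, species, ",
           "fraction (or mean_fraction)")
    }
    split_f <- split(stats::setNames(landscape[[fcol]], landscape$species),
                     landscape$network_id)
    return(split_f)
  }
  if (!is.list(landscape) || is.null(names(landscape))) {
    stop("landscape must be a named list of compositions or a data frame")
  }
  landscape
}

#' Mean perturbation per source network
#'
#' Arithmetic mean of the measured perturbation over all G' networks for
#' each network G (the per-network average across all single additions).
#'
#' @param records Data frame from [enumerate_perturbation_pairs()].
#' @return Data frame with `G_id`, `n_records`, `mean_p`.
#' @export
mean_perturbation <- function(records) {
  stopifnot(is.data.frame(records), all(c("G_id", "p") %in% names(records)))
  keep <- !is.na(records$p)
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message("dropping ", dropped, " record(s) with undefined perturbation")
  }
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0L) {
    return(data.frame(G_id = character(), n_records = integer(),
                      mean_p = numeric(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(records$p, by = list(G_id = records$G_id),
                          FUN = function(v) c(n = length(v), mean = mean(v)))
  out <- data.frame(G_id = agg$G_id,
                    n_records = as.integer(agg$x[, "n"]),
                    mean_p = agg$x[, "mean"],
                    stringsAsFactors = FALSE)
  out[order(out$G_id), , drop = FALSE]
}
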