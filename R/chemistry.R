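# ---- species identities -----------------------------------------------------

#' RNA alphabet of the concrete IGS/tag chemistry
#'
#' The Azoarcus-type ribozyme chemistry varies one nucleotide M in the
#' internal guide sequence (IGS, `gMg`) and one nucleotide N in the target
#' tag (`cNu`), each drawn from the four RNA bases.
#'
#' @return Character vector `c("A","C","G","U")`.
#' @export
rna_alphabet <- function() c("A", "C", "G", "U")

#' Watson-Crick partner of an RNA base
#'
#' @param base Character vector of bases from [rna_alphabet()].
#' @return Character vector of complementary bases.
#' @export
#' @examples
#' wc_partner(c("G", "A"))
wc_partner <- function(base) {
  map <- c(A = "U", U = "A", G = "C", C = "G")
  bad <- !base %in% names(map)
  if (any(bad)) {
    stop("unknown base(s): ", paste(unique(base[bad]), collapse = ", "))
  }
  unname(map[base])
}

#' Build species identifiers from IGS and tag letters
#'
#' A catalytic species is identified by the variable letter of its IGS and
#' the variable letter of its tag. For single-character alphabets (the
#' concrete chemistry) the identifier is the two-letter code used throughout
#' the field, e.g. `"GC"` for IGS gGg / tag cCu; multi-character letters
#' (abstract chemistries) are joined with `":"`.
#'
#' @param igs,tag Character vectors of letters (recycled to common length).
#' @return Character vector of species codes.
#' @export
#' @examples
#' make_species("G", "C")
make_species <- function(igs, tag) {
  if (all(nchar(igs) == 1L) && all(nchar(tag) == 1L)) {
    paste0(igs, tag)
  } else {
    paste(igs, tag, sep = ":")
  }
}

#' Split species codes into IGS and tag letters
#'
#' @param species Character vector of species codes from [make_species()].
#' @return Data frame with columns `igs` and `tag`.
#' @export
split_species <- function(species) {
  has_sep <- grepl(":", species, fixed = TRUE)
  igs <- character(length(species))
  tag <- character(length(species))
  if (any(has_sep)) {
    parts <- strsplit(species[has_sep], ":", fixed = TRUE)
    igs[has_sep] <- vapply(parts, `[`, "", 1L)
    tag[has_sep] <- vapply(parts, `[`, "", 2L)
  }
  if (any(!has_sep)) {
    if (any(nchar(species[!has_sep]) != 2L)) {
      stop("species codes without ':' must be two single-letter characters")
    }
    igs[!has_sep] <- substr(species[!has_sep], 1L, 1L)
    tag[!has_sep] <- substr(species[!has_sep], 2L, 2L)
  }
  data.frame(igs = igs, tag = tag, stringsAsFactors = FALSE)
}

#' species_igs and species_tag accessors
#'
#' @param species Character vector of species codes.
#' @return Character vector of IGS (tag) letters.
#' @export
species_igs <- function(species) split_species(species)$igs

#' @rdname species_igs
#' @export
species_tag <- function(species) split_species(species)$tag

#' The 16 species of the concrete MN chemistry
#'
#' All combinations of the IGS letter M and the tag letter N over the four
#' RNA bases, in the canonical lexicographic (igs, tag) order.
#'
#' @return Character vector of 16 species codes.
#' @export
#' @examples
#' azoarcus_species()
azoarcus_species <- function() {
  ab <- rna_alphabet()
  grid <- expand.grid(tag = ab, igs = ab, stringsAsFactors = FALSE)
  sort(make_species(grid$igs, grid$tag))
}

# ---- rate tables ------------------------------------------------------------

#' Construct a catalytic rate table
#'
#' A rate table stores, for every (catalyst IGS letter, product tag letter)
#' pair, the first-order rate `alpha` (min^-1, catalysis by covalent
#' ribozymes, per uM of catalyst) and the zeroth-order rate `beta`
#' (uM min^-1, catalysis by noncovalent fragment complexes), as measured by
#' the titration fit `v0 = alpha * x + beta`. Missing pairs read as zero.
#'
#' @param alpha,beta Numeric matrices with rownames = IGS letters and
#'   colnames = tag letters, or data frames with columns
#'   `igs`, `tag`, `alpha`, `beta` (see [read_rate_table()]).
#' @param edge_threshold Rate (min^-1) at or above which an IGS/tag pair is
#'   drawn as a directed graph edge. Default: half the smallest positive
#'   Watson-Crick `alpha` (RNA alphabets) or half the smallest positive
#'   `alpha` (other alphabets), which keeps strong pairs and drops
#'   wobble/mismatch pairs under the default rates.
#' @return Object of class `rate_table` with elements `alpha`, `beta`
#'   (full matrices over the alphabets), `igs_alphabet`, `tag_alphabet`,
#'   `edge_threshold`.
#' @export
rate_table <- function(alpha, beta, edge_threshold = NULL) {
  if (!is.matrix(alpha) || !is.matrix(beta)) {
    stop("alpha and beta must be matrices (igs rows x tag columns)")
  }
  if (is.null(rownames(alpha)) || is.null(colnames(alpha))) {
    stop("alpha must carry igs rownames and tag colnames")
  }
  if (!identical(dimnames(alpha), dimnames(beta))) {
    stop("alpha and beta must share dimnames")
  }
  if (any(alpha < 0) || any(beta < 0)) stop("all rates must be >= 0")
  tab <- structure(
    list(
      alpha = alpha,
      beta = beta,
      igs_alphabet = rownames(alpha),
      tag_alphabet = colnames(alpha),
      edge_threshold = edge_threshold
    ),
    class = "rate_table"
  )
  if (is.null(edge_threshold)) {
    tab$edge_threshold <- .default_edge_threshold(tab)
  } else if (edge_threshold < 0) {
    stop("edge_threshold must be >= 0")
  }
  tab
}

.default_edge_threshold <- function(table) {
  a <- table$alpha
  if (setequal(table$igs_alphabet, rna_alphabet()) &&
      setequal(table$tag_alphabet, rna_alphabet())) {
    wc <- a[cbind(rna_alphabet(), wc_partner(rna_alphabet()))]
    pos <- wc[wc > 0]
  } else {
    pos <- a[a > 0]
  }
  if (length(pos) == 0L) return(0)
  min(pos) / 2
}

#' Default placeholder rate table for the concrete chemistry
#'
#' Watson-Crick pairs carry the only appreciable rates, with G.C and C.G the
#' strongest, A.U and U.A weaker (ratio 0.3), and wobble (G.U, U.G) and
#' mismatched pairs zero. Magnitudes are placeholders chosen so that a 1-h
#' incubation of small networks yields total covalent catalyst on the
#' 0.01-1 uM scale; quantitative analyses of measured chemistries should
#' supply a table of measured rates via [read_rate_table()].
#'
#' @param alpha_strong `alpha` of G.C and C.G in min^-1.
#' @param weak_ratio Ratio of A.U/U.A rates to the strong rates.
#' @param beta_ratio `beta` = `beta_ratio * alpha` (uM min^-1).
#' @param edge_threshold Passed to [rate_table()].
#' @return A `rate_table`.
#' @export
#' @examples
#' tab <- default_rate_table()
#' pair_rate("G", "C", tab)
default_rate_table <- function(alpha_strong = 0.02, weak_ratio = 0.3,
                               beta_ratio = 0.1, edge_threshold = NULL) {
  ab <- rna_alphabet()
  alpha <- matrix(0, 4, 4, dimnames = list(ab, ab))
  alpha["G", "C"] <- alpha_strong
  alpha["C", "G"] <- alpha_strong
  alpha["A", "U"] <- alpha_strong * weak_ratio
  alpha["U", "A"] <- alpha_strong * weak_ratio
  rate_table(alpha, alpha * beta_ratio, edge_threshold = edge_threshold)
}

#' Look up the rates of one IGS/tag pair
#'
#' @param igs,tag Single letters from the table's alphabets.
#' @param table A [rate_table()].
#' @return Named numeric vector `c(alpha = , beta = )`.
#' @export
pair_rate <- function(igs, tag, table) {
  stopifnot(inherits(table, "rate_table"))
  if (!igs %in% table$igs_alphabet) {
    stop("igs letter '", igs, "' not in alphabet")
  }
  if (!tag %in% table$tag_alphabet) {
    stop("tag letter '", tag, "' not in alphabet")
  }
  c(alpha = table$alpha[igs, tag], beta = table$beta[igs, tag])
}

#' Read / write rate tables as CSV
#'
#' The CSV schema is `igs,tag,alpha,beta` with a header; pairs absent from
#' the file read as zero rate.
#'
#' @param file Path to a CSV file.
#' @param igs_alphabet,tag_alphabet Alphabets; default the letters observed.
#' @param edge_threshold Passed to [rate_table()].
#' @return A `rate_table` ([read_rate_table()]) or `file`, invisibly.
#' @export
#' @examples
#' f <- system.file("extdata", "placeholder_rates.csv",
#'                  package = "autocatnet")
#' read_rate_table(f)
read_rate_table <- function(file, igs_alphabet = NULL, tag_alphabet = NULL,
                            edge_threshold = NULL) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("igs", "tag", "alpha", "beta")
  if (!all(need %in% names(df))) {
    stop("rate table CSV needs columns: ", paste(need, collapse = ", "))
  }
  if (is.null(igs_alphabet)) igs_alphabet <- sort(unique(df$igs))
  if (is.null(tag_alphabet)) tag_alphabet <- sort(unique(df$tag))
  alpha <- matrix(0, length(igs_alphabet), length(tag_alphabet),
                  dimnames = list(igs_alphabet, tag_alphabet))
  beta <- alpha
  alpha[cbind(df$igs, df$tag)] <- df$alpha
  beta[cbind(df$igs, df$tag)] <- df$beta
  rate_table(alpha, beta, edge_threshold = edge_threshold)
}

#' @rdname read_rate_table
#' @param table A `rate_table` to write.
#' @export
write_rate_table <- function(table, file) {
  stopifnot(inherits(table, "rate_table"))
  grid <- expand.grid(tag = table$tag_alphabet, igs = table$igs_alphabet,
                      stringsAsFactors = FALSE)
  df <- data.frame(
    igs = grid$igs, tag = grid$tag,
    alpha = table$alpha[cbind(grid$igs, grid$tag)],
    beta = table$beta[cbind(grid$igs, grid$tag)]
  )
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @export
print.rate_table <- function(x, ...) {
  cat("Catalytic rate table:", length(x$igs_alphabet), "IGS x",
      length(x$tag_alphabet), "tag letters\n")
  cat("edge threshold:", x$edge_threshold, "min^-1\n")
  cat("alpha (min^-1):\n")
  print(x$alpha)
  invisible(x)
}

# ---- reaction networks ------------------------------------------------------

#' Build a reaction network from a species set and a rate table
#'
#' The network induced by a species set carries the rate matrix
#' `A[i, j] = alpha(igs_j, tag_i)` (catalysis of species i's formation by
#' covalent catalysts of species j, min^-1) and the constant production
#' vector `b[i] = sum_j beta(igs_j, tag_i)` (catalysis by noncovalent
#' complexes, uM min^-1). Directed edges j -> i are drawn where
#' `alpha(igs_j, tag_i) >= edge_threshold`. Species are canonically ordered
#' lexicographically by (igs, tag), so construction is order-independent.
#'
#' @param species Nonempty character vector of species codes.
#' @param table A [rate_table()].
#' @return Object of class `reaction_network` with elements `species`,
#'   `igs`, `tag`, `A`, `b`, `edges` (data frame `from`, `to`, `rate`),
#'   `edge_threshold`.
#' @export
#' @examples
#' net <- build_network(c("GC", "CG", "AU"), default_rate_table())
#' net$edges
build_network <- function(species, table) {
  stopifnot(inherits(table, "rate_table"))
  species <- unique(species)
  if (length(species) == 0L) stop("species set must be nonempty")
  parts <- split_species(species)
  bad <- !(parts$igs %in% table$igs_alphabet & parts$tag %in% table$tag_alphabet)
  if (any(bad)) {
    stop("species outside the table's chemistry: ",
         paste(species[bad], collapse = ", "))
  }
  ord <- order(parts$igs, parts$tag)
  species <- species[ord]
  igs <- parts$igs[ord]
  tag <- parts$tag[ord]
  n <- length(species)
  # A[i, j]: column j = catalyst, row i = product
  A <- matrix(table$alpha[cbind(rep(igs, each = n), rep(tag, times = n))],
              nrow = n, ncol = n, dimnames = list(species, species))
  Bmat <- matrix(table$beta[cbind(rep(igs, each = n), rep(tag, times = n))],
                 nrow = n, ncol = n)
  b <- rowSums(Bmat)
  names(b) <- species
  idx <- which(A >= table$edge_threshold & A > 0, arr.ind = TRUE)
  edges <- data.frame(
    from = species[idx[, "col"]],
    to = species[idx[, "row"]],
    rate = A[idx],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(species = species, igs = igs, tag = tag, A = A, b = b,
         edges = edges, edge_threshold = table$edge_threshold),
    class = "reaction_network"
  )
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Reaction network:", length(x$species), "species,",
      nrow(x$edges), "edges\n")
  cat("species:", paste(x$species, collapse = ", "), "\n")
  invisible(x)
}

#' Canonical key of a species set
#'
#' Networks are keyed by their sorted species codes joined with `"+"`; the
#' key identifies a network independently of input order.
#'
#' @param species Character vector of species codes.
#' @return Single string.
#' @export
network_key <- function(species) paste(sort(unique(species)), collapse = "+")

#' Species encoded in a network key
#'
#' @param key String produced by [network_key()].
#' @return Character vector of species codes.
#' @export
key_species <- function(key) strsplit(key, "+", fixed = TRUE)[[1L]]

#' Export a network as edge-list and node tables
#'
#' Writes the directed edge list (`from`, `to`, `rate`) as TSV and,
#' optionally, a node table (`species`, `igs`, `tag`, `b`).
#'
#' @param net A `reaction_network`.
#' @param edge_file Path for the TSV edge list.
#' @param node_file Optional path for the TSV node table.
#' @return `edge_file`, invisibly.
#' @export
write_network <- function(net, edge_file, node_file = NULL) {
  stopifnot(inherits(net, "reaction_network"))
  utils::write.table(net$edges, edge_file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(node_file)) {
    nodes <- data.frame(species = net$species, igs = net$igs, tag = net$tag,
                        b = unname(net$b))
    utils::write.table(nodes, node_file, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(edge_file)
}

# ---- titration fits ---------------------------------------------------------

#' Fit catalytic rates from a doped-catalyst titration
#'
#' The initial rate of covalent ribozyme formation depends linearly on the
#' concentration of doped covalent catalyst, `v0 = alpha * x + beta`:
#' the slope `alpha` quantifies catalysis by covalent ribozymes and the
#' intercept `beta` catalysis by noncovalent fragment complexes. Fitted by
#' ordinary least squares.
#'
#' @param x Doped covalent catalyst concentrations (uM), all `>= 0`, with at
#'   least two distinct values. May also be a data frame with columns
#'   `x` and `v0` (then `v0` is ignored).
#' @param v0 Initial formation rates (uM min^-1), same length as `x`.
#' @return List with `alpha`, `beta`, `se_alpha`, `se_beta`,
#'   `sigma` (residual standard deviation), `r_squared`, `df_residual`,
#'   and the underlying `lm` fit.
#' @export
#' @examples
#' fit <- fit_titration(c(0, 0.5, 1), 0.2 * c(0, 0.5, 1) + 0.05)
#' c(fit$alpha, fit$beta)
fit_titration <- function(x, v0 = NULL) {
  if (is.data.frame(x)) {
    v0 <- x$v0
    x <- x$x
  }
  if (length(x) != length(v0)) stop("x and v0 must have equal lengths")
  if (any(x < 0)) stop("doped concentrations must be >= 0")
  if (length(x) < 2L || length(unique(x)) < 2L) {
    stop("degenerate design: need >= 2 distinct doped concentrations")
  }
  fit <- stats::lm(v0 ~ x)
  sm <- suppressWarnings(summary(fit))  # silence the zero-residual notice
  co <- sm$coefficients
  list(
    alpha = unname(co["x", "Estimate"]),
    beta = unname(co["(Intercept)", "Estimate"]),
    se_alpha = unname(co["x", "Std. Error"]),
    se_beta = unname(co["(Intercept)", "Std. Error"]),
    sigma = sm$sigma,
    r_squared = sm$r.squared,
    df_residual = fit$df.residual,
    fit = fit
  )
}
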