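# Independent oracles: everything here rebuilds matrices and statistics from
# first principles, sharing no code with the package implementation.

# Build a mol_graph by hand from an atom vector and a bond table.
make_graph <- function(elements, bonds, n_h = rep(0L, length(elements)),
                       smiles = "<synthetic>") {
  structure(
    list(
      atoms = tibble::tibble(element = elements,
                             formal_charge = 0L,
                             n_h = as.integer(n_h)),
      bonds = tibble::tibble(i = as.integer(bonds$i), j = as.integer(bonds$j),
                             order = as.integer(bonds$order),
                             aromatic = bonds$aromatic),
      smiles = smiles
    ),
    class = "mol_graph"
  )
}

# Permute the atom indexing of a mol_graph.
shuffle_graph <- function(g, perm) {
  inv <- order(perm)   # new index of old atom k is inv[k]
  b <- g$bonds
  bi <- inv[b$i]; bj <- inv[b$j]
  swap <- bi > bj
  tmp <- bi[swap]; bi[swap] <- bj[swap]; bj[swap] <- tmp
  make_graph(g$atoms$element[perm],
             data.frame(i = bi, j = bj, order = b$order,
                        aromatic = b$aromatic),
             n_h = g$atoms$n_h[perm], smiles = g$smiles)
}

# Dense adjacency from the bond list, written independently.
oracle_adjacency <- function(g, weighted = FALSE) {
  n <- nrow(g$atoms)
  A <- matrix(0, n, n)
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    w <- if (!weighted) 1 else if (g$bonds$aromatic[k]) 1.5 else g$bonds$order[k]
    A[i, j] <- w; A[j, i] <- w
  }
  A
}

oracle_laplacian_spectrum <- function(g) {
  A <- oracle_adjacency(g)
  eigen(diag(colSums(A)) - A, symmetric = TRUE)
}

oracle_burden <- function(g, props) {
  n <- nrow(g$atoms)
  w <- props$vdw_volume[match(g$atoms$element, props$element)]
  deg <- colSums(oracle_adjacency(g))
  B <- matrix(0.001, n, n)
  diag(B) <- w
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    o <- if (g$bonds$aromatic[k]) 1.5 else g$bonds$order[k]
    v <- 0.1 * o + if (deg[i] == 1 || deg[j] == 1) 0.01 else 0
    B[i, j] <- v; B[j, i] <- v
  }
  B
}

# Barysz distance matrix via Floyd-Warshall on reciprocal-weight edge lengths.
oracle_barysz <- function(g, props) {
  n <- nrow(g$atoms)
  w <- props$polarizability[match(g$atoms$element, props$element)]
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (k in seq_len(nrow(g$bonds))) {
    i <- g$bonds$i[k]; j <- g$bonds$j[k]
    o <- if (g$bonds$aromatic[k]) 1.5 else g$bonds$order[k]
    len <- 1 / (o * w[i] * w[j])
    D[i, j] <- min(D[i, j], len); D[j, i] <- D[i, j]
  }
  for (m in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, m] + D[m, j] < D[i, j]) D[i, j] <- D[i, m] + D[m, j]
  }
  diag(D) <- 1 - 1 / w
  D
}

oracle_harary <- function(g, props) {
  D <- oracle_barysz(g, props)
  sum(1 / D[upper.tri(D)])
}

# Literal n-refit leave-one-out loop.
oracle_q2_loo <- function(data, response, refit) {
  y <- data[[response]]
  press <- 0
  for (i in seq_len(nrow(data))) {
    m <- refit(data[-i, , drop = FALSE])
    press <- press + (y[i] - predict(m, data[i, , drop = FALSE]))^2
  }
  1 - press / sum((y - mean(y))^2)
}

# Closed-form interventional Shapley values for a linear model.
oracle_linear_shap <- function(model, background, query) {
  mu <- colMeans(as.data.frame(background)[model$descriptors])
  t(apply(as.matrix(as.data.frame(query)[model$descriptors]), 1,
          function(x) model$coefficients * (x - mu)))
}

# A deterministic bank of parsed fixture molecules for property tests.
fixture_graphs <- local({
  cache <- NULL
  function(n = 20) {
    if (is.null(cache)) {
      path <- system.file("extdata", "fixture_smiles.csv",
                          package = "cuticleqspr")
      lib <- utils::read.csv(path)
      smiles <- lib$smiles[seq(1, nrow(lib), length.out = 25)]
      cache <<- lapply(smiles, parse_smiles)
    }
    cache[seq_len(n)]
  }
})
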