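#' Laplacian last-eigenvector descriptor VE1_L
#'
#' Builds the graph Laplacian `L = D - A` of the hydrogen-depleted heavy-atom
#' graph (unweighted adjacency, diagonal degree) and returns the sum of
#' absolute coefficients of the unit-norm eigenvector belonging to the "last"
#' Laplacian eigenvalue. With eigenvalues sorted ascending the last one is the
#' largest; that convention (the usual one in the descriptor software this
#' nomenclature comes from) is the default, with the smallest
#' nonzero eigenvalue (Fiedler vector) selectable.
#'
#' The value is invariant to the eigenvector's overall sign by construction.
#' When the selected eigenvalue is (numerically) degenerate, the eigenvector
#' is chosen deterministically: candidates within `1e-9` of the selected
#' eigenvalue are sign-canonicalized (first nonzero component positive),
#' sorted lexicographically, and the last one is used.
#'
#' @param g A `mol_graph`.
#' @param which `"largest"` (default) or `"smallest_nonzero"`.
#' @return A positive scalar for any connected graph with at least 2 atoms.
#' @examples
#' \donttest{
#' ve1_laplacian(parse_smiles("CC"))  # P2 graph: sqrt(2)
#' }
#' @export
ve1_laplacian <- function(g, which = c("largest", "smallest_nonzero")) {
  which <- match.arg(which)
  n <- nrow(g$atoms)
  if (n < 2L) {
    abort("VE1_L is undefined for a single-atom graph (no spanning structure).")
  }
  A <- adjacency_matrix(g)
  L <- diag(rowSums(A)) - A
  e <- eigen(L, symmetric = TRUE)   # eigenvalues in decreasing order
  target <- if (which == "largest") max(e$values) else {
    nz <- e$values[e$values > 1e-9]
    if (!length(nz)) abort("No nonzero Laplacian eigenvalue (edgeless graph).")
    min(nz)
  }
  v <- .select_eigenvector(e, target)
  sum(abs(v))
}

#' Adjacency spectral positive sum SpPos_A
#'
#' Sum of the strictly positive eigenvalues of the unweighted heavy-atom
#' adjacency matrix. For bipartite (odd-cycle-free) graphs the spectrum is
#' symmetric, so this equals half the graph energy.
#'
#' @param g A `mol_graph`.
#' @return A non-negative scalar (0 for a single atom).
#' @export
sppos_adjacency <- function(g) {
  n <- nrow(g$atoms)
  if (n == 0L) abort("Empty graph.")
  if (nrow(g$bonds) == 0L) return(0)
  ev <- eigen(adjacency_matrix(g), symmetric = TRUE, only.values = TRUE)$values
  sum(ev[ev > 0])
}

#' Burden matrix second-largest eigenvalue SpMax2_Bh(v)
#'
#' Builds the symmetric Burden matrix weighted by carbon-normalized van der
#' Waals volume: diagonal entries are the atomic weights; entries for bonded
#' pairs are `0.1 *` conventional bond order (aromatic = 1.5), incremented by
#' `0.01` when either endpoint has heavy-atom degree 1; all remaining
#' off-diagonal entries are `0.001`. Returns the second-largest eigenvalue.
#'
#' @param g A `mol_graph` with at least 2 heavy atoms.
#' @param props Atom property table, see [atom_properties()].
#' @param bond_scale,terminal_increment,nonbonded Burden matrix constants;
#'   the defaults are the published Burden/BCUT convention.
#' @return The second-largest eigenvalue of the Burden matrix.
#' @examples
#' \donttest{
#' spmax2_burden(parse_smiles("CC"))  # analytic: 1 - 0.11 = 0.89
#' }
#' @export
spmax2_burden <- function(g, props = atom_properties(), bond_scale = 0.1,
                          terminal_increment = 0.01, nonbonded = 0.001) {
  B <- burden_matrix(g, props, bond_scale, terminal_increment, nonbonded)
  ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  if (length(ev) < 2L) abort("SpMax2 needs at least 2 heavy atoms.")
  ev[2L]
}

#' @rdname spmax2_burden
#' @export
burden_matrix <- function(g, props = atom_properties(), bond_scale = 0.1,
                          terminal_increment = 0.01, nonbonded = 0.001) {
  w <- .atom_weights(g, props, "vdw_volume")
  n <- nrow(g$atoms)
  B <- matrix(nonbonded, n, n)
  diag(B) <- w
  if (nrow(g$bonds)) {
    deg <- heavy_degree(g)
    off <- bond_scale * bond_order(g$bonds) +
      terminal_increment * (deg[g$bonds$i] == 1L | deg[g$bonds$j] == 1L)
    B[cbind(g$bonds$i, g$bonds$j)] <- off
    B[cbind(g$bonds$j, g$bonds$i)] <- off
  }
  B
}

#' Harary-like index from the polarizability-weighted Barysz matrix, H_Dz(p)
#'
#' Each bond `(i, j)` with conventional order `pi` (aromatic = 1.5) gets edge
#' length `(w_C * w_C) / (pi * w_i * w_j)` with `w` the atomic polarizability
#' (carbon-normalized, so `w_C = 1`); the off-diagonal Barysz entry `Dz[i, j]`
#' is the weighted shortest-path distance, and the diagonal is
#' `1 - w_C / w_i`. The descriptor is the half-sum of reciprocal off-diagonal
#' distances, `sum_{i<j} 1 / Dz[i, j]` — on an all-carbon single-bond
#' skeleton it collapses to the classical Harary index.
#'
#' @param g A connected `mol_graph`.
#' @param props Atom property table, see [atom_properties()].
#' @return A positive scalar (0 for a single atom).
#' @examples
#' \donttest{
#' harary_barysz(parse_smiles("CCC"))  # path P3: 1 + 1 + 1/2 = 2.5
#' }
#' @export
harary_barysz <- function(g, props = atom_properties()) {
  D <- barysz_matrix(g, props)
  n <- nrow(D)
  if (n < 2L) return(0)
  sum(1 / D[upper.tri(D)])
}

#' @rdname harary_barysz
#' @export
barysz_matrix <- function(g, props = atom_properties()) {
  w <- .atom_weights(g, props, "polarizability")
  n <- nrow(g$atoms)
  if (n == 1L) return(matrix(1 - 1 / w, 1, 1))
  len <- 1 / (bond_order(g$bonds) * w[g$bonds$i] * w[g$bonds$j])
  if (any(!is.finite(len)) || any(len <= 0)) {
    abort("Corrupt property table: non-positive Barysz edge length.")
  }
  ig <- igraph::graph_from_edgelist(cbind(g$bonds$i, g$bonds$j),
                                    directed = FALSE)
  D <- igraph::distances(ig, weights = len)
  if (any(!is.finite(D))) abort("Graph is not connected.")
  diag(D) <- 1 - 1 / w
  unname(D)
}

# Deterministic eigenvector choice for a possibly degenerate eigenvalue:
# sign-canonicalize all candidate eigenvectors (first component larger than
# 1e-12 in absolute value made positive), order them lexicographically, and
# take the last. Reduces to "the" eigenvector in the non-degenerate case.
.select_eigenvector <- function(e, target, tol = 1e-9) {
  cand <- which(abs(e$values - target) < tol)
  vecs <- lapply(cand, function(k) {
    v <- e$vectors[, k]
    nz <- which(abs(v) > 1e-12)[1]
    if (!is.na(nz) && v[nz] < 0) v <- -v
    v
  })
  if (length(vecs) == 1L) return(vecs[[1]])
  ord <- do.call(order, as.data.frame(t(vapply(vecs, identity,
                                               numeric(length(vecs[[1]]))))))
  vecs[[ord[length(ord)]]]
}

#' Compute the six modeled descriptors for a table of compounds
#'
#' Batch driver: parses every SMILES and computes `VE1_L`, `SpPos_A`,
#' `SpMax2_Bh(v)`, `H_Dz(p)`, `LLS_01` and `LLS_02`. Rows that fail to parse
#' (or contain elements outside the property table) are collected into a
#' failure report rather than silently dropped.
#'
#' @param data A data frame with (at least) a SMILES column.
#' @param smiles,id Tidy-eval columns holding the SMILES string and the
#'   compound identifier (defaults `smiles`, `compound_id`; if the id column
#'   is absent, row numbers are used).
#' @param props Atom property table ([atom_properties()]).
#' @param rules Lead-like rule sets ([lls_rulesets()]).
#' @return A tibble with columns `compound_id`, `smiles`, `VE1_L`, `SpPos_A`,
#'   `SpMax2_Bh(v)`, `H_Dz(p)`, `LLS_01`, `LLS_02`. Failed rows are attached
#'   as a tibble in attribute `"failures"` (columns `compound_id`, `smiles`,
#'   `error`).
#' @examples
#' \donttest{
#' mol_descriptors(tibble::tibble(smiles = c("c1ccccc1", "CC")))
#' }
#' @export
mol_descriptors <- function(data, smiles = smiles, id = compound_id,
                            props = atom_properties(), rules = lls_rulesets()) {
  smi <- rlang::enquo(smiles)
  idq <- rlang::enquo(id)
  smi_vec <- as.character(rlang::eval_tidy(smi, data))
  id_vec <- tryCatch(rlang::eval_tidy(idq, data), error = function(e) NULL)
  if (is.null(id_vec)) id_vec <- as.character(seq_along(smi_vec))
  id_vec <- as.character(id_vec)

  cols <- descriptor_names()
  rows <- vector("list", length(smi_vec))
  fails <- list()
  for (k in seq_along(smi_vec)) {
    res <- tryCatch({
      g <- parse_smiles(smi_vec[[k]])
      vals <- c(
        ve1_laplacian(g),
        sppos_adjacency(g),
        spmax2_burden(g, props),
        harary_barysz(g, props),
        leadlike_score(g, rules$congreve6),
        leadlike_score(g, rules$monge8)
      )
      names(vals) <- cols
      vals
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- tibble(
        compound_id = id_vec[[k]], smiles = smi_vec[[k]],
        error = conditionMessage(res)
      )
    } else {
      rows[[k]] <- tibble(compound_id = id_vec[[k]], smiles = smi_vec[[k]],
                          !!!as.list(res))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(compound_id = character(), smiles = character())
    for (cl in cols) out[[cl]] <- numeric()
  }
  attr(out, "failures") <- dplyr::bind_rows(fails)
  out
}

#' Names of the six modeled descriptors, in canonical column order
#' @return A character vector of length 6.
#' @export
descriptor_names <- function() {
  c("VE1_L", "SpPos_A", "SpMax2_Bh(v)", "H_Dz(p)", "LLS_01", "LLS_02")
}
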