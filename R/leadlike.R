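#' Lead-like rule sets for the LLS_01 and LLS_02 descriptors
#'
#' Two configurable rule sets from the drug-discovery lead-likeness
#' literature. `LLS_01` uses a 6-rule, rule-of-three style set (after
#' Congreve's fragment criteria); `LLS_02` an 8-rule extended lead-like set
#' (after Monge's library-design criteria). A molecule's score is the
#' fraction of rules it satisfies, so a compound meeting every rule scores 1
#' and each additional violation lowers the score by `1/k`.
#'
#' The primary literature does not fix every numeric threshold at the
#' precision needed for bit-reproducibility, so all bounds live in this
#' config block and can be overridden; only the fraction-of-rules arithmetic
#' is treated as fixed.
#'
#' @param congreve6,monge8 Optional replacement rule tables with columns
#'   `property`, `min`, `max` (use `-Inf`/`Inf` for one-sided rules).
#'   Recognized properties: `mw`, `logp`, `hbd`, `hba`, `rotatable_bonds`,
#'   `rings`, `tpsa`, `heavy_atoms`.
#' @return A named list of two rule tibbles, `congreve6` and `monge8`.
#' @examples
#' lls_rulesets()$monge8
#' @export
lls_rulesets <- function(congreve6 = NULL, monge8 = NULL) {
  rule <- function(property, min, max) tibble(property = property, min = min, max = max)
  default6 <- dplyr::bind_rows(
    rule("mw", -Inf, 300),
    rule("logp", -Inf, 3),
    rule("hbd", -Inf, 3),
    rule("hba", -Inf, 3),
    rule("rotatable_bonds", -Inf, 3),
    rule("tpsa", -Inf, 60)
  )
  default8 <- dplyr::bind_rows(
    rule("mw", 160, 480),
    rule("logp", -4, 4.2),
    rule("hbd", -Inf, 5),
    rule("hba", -Inf, 9),
    rule("rotatable_bonds", -Inf, 10),
    rule("rings", -Inf, 4),
    rule("tpsa", -Inf, 140),
    rule("heavy_atoms", 6, 50)
  )
  check <- function(r, label) {
    if (is.null(r)) return(invisible())
    need <- c("property", "min", "max")
    if (!all(need %in% names(r))) {
      abort(paste0("Rule set '", label, "' must have columns property/min/max."))
    }
  }
  check(congreve6, "congreve6"); check(monge8, "monge8")
  list(congreve6 = congreve6 %||% default6, monge8 = monge8 %||% default8)
}

#' Score a molecule against a lead-like rule set
#'
#' @param g A `mol_graph`.
#' @param rules One rule tibble from [lls_rulesets()].
#' @return The fraction of satisfied rules, a value in `{0, 1/k, ..., 1}`.
#' @export
leadlike_score <- function(g, rules) {
  props <- molecular_properties(g)
  known <- names(props)
  missing <- setdiff(rules$property, known)
  if (length(missing)) {
    abort(paste0("Rule(s) reference unknown molecular properties: ",
                 paste(missing, collapse = ", ")))
  }
  if (any(is.na(rules$min)) || any(is.na(rules$max))) {
    abort("Unconfigured rule: every rule needs finite-or-Inf min and max.")
  }
  vals <- unlist(props[rules$property])
  ok <- vals >= rules$min & vals <= rules$max
  sum(ok) / nrow(rules)
}

#' Molecular properties used by the lead-like rules
#'
#' Molecular weight, H-bond donor/acceptor counts, estimated logP and
#' topological polar surface area come from OpenBabel (\pkg{ChemmineOB};
#' the logP is OpenBabel's atom-contribution estimate). Rotatable-bond count
#' (acyclic single non-aromatic bonds between non-terminal heavy atoms),
#' ring count (cycle rank of the heavy-atom graph) and heavy-atom count are
#' computed from the graph itself.
#'
#' @param g A `mol_graph`.
#' @return A named list: `mw`, `logp`, `tpsa`, `hbd`, `hba`,
#'   `rotatable_bonds`, `rings`, `heavy_atoms`, plus `logp_estimator`
#'   metadata naming the estimator.
#' @export
molecular_properties <- function(g) {
  stopifnot(inherits(g, "mol_graph"))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(g$smiles))
  p <- suppressWarnings(ChemmineR::propOB(sdf))
  n <- nrow(g$atoms)
  rot <- 0L
  if (nrow(g$bonds) > 1L) {
    ig <- igraph::graph_from_edgelist(cbind(g$bonds$i, g$bonds$j),
                                      directed = FALSE)
    bridge_ids <- igraph::bridges(ig)
    is_bridge <- seq_len(nrow(g$bonds)) %in% as.integer(bridge_ids)
    deg <- heavy_degree(g)
    rot <- sum(g$bonds$order == 1L & !g$bonds$aromatic & is_bridge &
                 deg[g$bonds$i] >= 2L & deg[g$bonds$j] >= 2L)
  }
  list(
    mw = as.numeric(p$MW),
    logp = as.numeric(p$logP),
    tpsa = as.numeric(p$TPSA),
    hbd = as.numeric(p$HBD),
    hba = as.numeric(p$HBA1),
    rotatable_bonds = as.integer(rot),
    rings = nrow(g$bonds) - n + 1L,
    heavy_atoms = n,
    logp_estimator = "openbabel-atom-contribution"
  )
}
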