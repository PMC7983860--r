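#' Build a validated bipartite ceRNA network
#'
#' Assembles gene nodes, miRNA nodes and miRNA:gene interaction edges into a
#' `cerna_network` object, the central data structure of the package. The
#' network is strictly bipartite: every edge connects one miRNA to one gene.
#' Gene and miRNA expression values share one arbitrary abundance unit (for
#' example normalized counts); a miRNA's expression is interpreted as the
#' total repressive activity it distributes over its targets.
#'
#' Optional per-edge interaction factors modulate the distribution:
#' * `energy` — binding free energy in kcal/mol, must be `<= 0` (more negative
#'   means stronger binding);
#' * `seed_type_effect` — positive unitless multiplier for the seed pairing
#'   class of the site;
#' * `region_effect` — positive unitless multiplier for the binding location
#'   on the transcript (5'UTR/CDS/3'UTR), applied to degradation only.
#'
#' Absent factors default to a neutral normalized value of 1, in which case the
#' affinity-weighted distribution reduces exactly to plain
#' expression-proportional sharing.
#'
#' @param gene_expr data frame with columns `id`, `expression` (non-negative).
#' @param mirna_expr data frame with columns `id`, `expression` (non-negative).
#' @param edges data frame with columns `mirna`, `gene` and optionally
#'   `energy`, `seed_type_effect`, `region_effect`.
#' @param normalize if `TRUE` (default), [normalize_factors()] is applied so
#'   the returned network carries ready-to-use normalized factors and
#'   affinities.
#' @param drop_isolated_mirnas if `TRUE`, miRNAs without any edge are removed
#'   with a warning instead of triggering a validation error. Genes without
#'   edges are always allowed (they are simply never repressed).
#'
#' @return A `cerna_network`: a list with elements `genes`, `mirnas` (data
#'   frames `id`, `expression`) and `edges` (data frame with raw and
#'   normalized factor columns plus `affinity`).
#'
#' @examples
#' genes <- data.frame(id = c("G1", "G2"), expression = c(100, 300))
#' mirnas <- data.frame(id = "M1", expression = 50)
#' edges <- data.frame(mirna = "M1", gene = c("G1", "G2"))
#' net <- build_network(genes, mirnas, edges)
#' distribute_mirna(net)
#' @export
build_network <- function(gene_expr, mirna_expr, edges,
                          normalize = TRUE, drop_isolated_mirnas = FALSE) {
  gene_expr <- as.data.frame(gene_expr)
  mirna_expr <- as.data.frame(mirna_expr)
  edges <- as.data.frame(edges)

  check_expr_table(gene_expr, "gene_expr")
  check_expr_table(mirna_expr, "mirna_expr")

  if (!all(c("mirna", "gene") %in% names(edges))) {
    stop("`edges` must have columns `mirna` and `gene`", call. = FALSE)
  }
  if (nrow(edges) == 0L) {
    stop("edge table is empty: no miRNA has any target", call. = FALSE)
  }

  gene_ids <- as.character(gene_expr$id)
  mirna_ids <- as.character(mirna_expr$id)
  all_ids <- c(gene_ids, mirna_ids)
  if (anyDuplicated(all_ids)) {
    stop("node ids must be unique across genes and miRNAs: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "),
         call. = FALSE)
  }

  e_mirna <- as.character(edges$mirna)
  e_gene <- as.character(edges$gene)
  bad_m <- setdiff(e_mirna, mirna_ids)
  bad_g <- setdiff(e_gene, gene_ids)
  if (length(bad_m)) {
    stop("edges reference unknown miRNA id(s): ",
         paste(bad_m, collapse = ", "), call. = FALSE)
  }
  if (length(bad_g)) {
    stop("edges reference unknown gene id(s): ",
         paste(bad_g, collapse = ", "), call. = FALSE)
  }
  key <- paste(e_mirna, e_gene, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate edge: ", sub("\r", " -> ", dup), call. = FALSE)
  }

  isolated <- setdiff(mirna_ids, e_mirna)
  if (length(isolated)) {
    if (drop_isolated_mirnas) {
      warning("dropping miRNA(s) with no targets: ",
              paste(isolated, collapse = ", "), call. = FALSE)
      mirna_expr <- mirna_expr[!(mirna_ids %in% isolated), , drop = FALSE]
      mirna_ids <- as.character(mirna_expr$id)
    } else {
      stop("miRNA(s) with no targets are not allowed: ",
           paste(isolated, collapse = ", "), call. = FALSE)
    }
  }

  edge_tab <- data.frame(
    mirna = e_mirna,
    gene = e_gene,
    energy = factor_column(edges, "energy"),
    seed_type_effect = factor_column(edges, "seed_type_effect"),
    region_effect = factor_column(edges, "region_effect"),
    energy_norm = 1,
    seed_norm = 1,
    region_norm = 1,
    affinity = 1,
    stringsAsFactors = FALSE
  )

  net <- structure(
    list(
      genes = data.frame(id = gene_ids,
                         expression = as.numeric(gene_expr$expression),
                         stringsAsFactors = FALSE),
      mirnas = data.frame(id = mirna_ids,
                          expression = as.numeric(mirna_expr$expression),
                          stringsAsFactors = FALSE),
      edges = edge_tab
    ),
    class = "cerna_network"
  )
  if (normalize) net <- normalize_factors(net) else net
}

check_override <- function(x, known, what) {
  if (is.null(names(x)) || any(names(x) == "")) {
    stop("`", what, "` must be a named numeric vector", call. = FALSE)
  }
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop("`", what, "` has unknown node id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

check_expr_table <- function(tab, what) {
  if (!all(c("id", "expression") %in% names(tab))) {
    stop("`", what, "` must have columns `id` and `expression`", call. = FALSE)
  }
  expr <- suppressWarnings(as.numeric(tab$expression))
  if (anyNA(expr)) {
    stop("`", what, "` has non-numeric expression values", call. = FALSE)
  }
  if (any(expr < 0)) {
    stop("`", what, "` has negative expression for: ",
         paste(tab$id[expr < 0], collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

factor_column <- function(edges, name) {
  if (name %in% names(edges)) as.numeric(edges[[name]]) else rep(NA_real_, nrow(edges))
}

#' @export
print.cerna_network <- function(x, ...) {
  has_factors <- any(!is.na(x$edges$energy)) ||
    any(!is.na(x$edges$seed_type_effect)) || any(!is.na(x$edges$region_effect))
  cat("ceRNA network: ", nrow(x$genes), " genes, ", nrow(x$mirnas),
      " miRNAs, ", nrow(x$edges), " interactions",
      if (has_factors) " (with interaction factors)" else "", "\n", sep = "")
  invisible(x)
}

#' Normalize per-edge interaction factors and recompute affinities
#'
#' Raw factors are rescaled to `(0, 1]` so that the most favourable value of
#' each factor maps to 1:
#' * binding energies (all `<= 0`) are divided by the most negative energy in
#'   the network, so the strongest binding gets weight 1 and weaker binding a
#'   proportionally smaller weight;
#' * seed-type and region multipliers are divided by their column maximum.
#'
#' Edges whose raw factor is missing get a neutral normalized value of 1
#' (absence of evidence must not silence an interaction). A factor column that
#' is entirely zero or constant carries no contrast, so all its normalized
#' values are set to 1 with a warning. The affinity of each edge is the
#' product of its normalized energy and normalized seed-type effect; the
#' normalized region effect is kept separate because it scales degradation,
#' not sequestration.
#'
#' @param network a `cerna_network`.
#' @return The network with `energy_norm`, `seed_norm`, `region_norm` and
#'   `affinity` recomputed.
#' @export
normalize_factors <- function(network) {
  stopifnot(inherits(network, "cerna_network"))
  ed <- network$edges

  if (any(ed$energy > 0, na.rm = TRUE)) {
    stop("binding energies must be <= 0 kcal/mol", call. = FALSE)
  }
  if (any(ed$seed_type_effect <= 0, na.rm = TRUE) ||
      any(ed$region_effect <= 0, na.rm = TRUE)) {
    stop("seed_type_effect and region_effect must be positive", call. = FALSE)
  }

  ed$energy_norm <- norm_by_min(ed$energy, "energy")
  ed$seed_norm <- norm_by_max(ed$seed_type_effect, "seed_type_effect")
  ed$region_norm <- norm_by_max(ed$region_effect, "region_effect")
  ed$affinity <- ed$energy_norm * ed$seed_norm

  network$edges <- ed
  network
}

# divide by the most negative value; a constant/zero column is uninformative
norm_by_min <- function(x, name) {
  obs <- x[!is.na(x)]
  if (length(obs) == 0L) return(rep(1, length(x)))
  lo <- min(obs)
  if (lo == 0 || length(unique(obs)) == 1L) {
    if (lo == 0 || length(obs) > 1L) {
      warning("`", name, "` column is constant; normalized values set to 1",
              call. = FALSE)
    }
    return(rep(1, length(x)))
  }
  ifelse(is.na(x), 1, x / lo)
}

norm_by_max <- function(x, name) {
  obs <- x[!is.na(x)]
  if (length(obs) == 0L) return(rep(1, length(x)))
  hi <- max(obs)
  if (hi == 0 || length(unique(obs)) == 1L) {
    if (hi == 0 || length(obs) > 1L) {
      warning("`", name, "` column is constant; normalized values set to 1",
              call. = FALSE)
    }
    return(rep(1, length(x)))
  }
  ifelse(is.na(x), 1, x / hi)
}

#' Distribute each miRNA's repressive activity over its targets
#'
#' Implements the proportional-sharing model at the heart of the package.
#' The repression count `RC[i,j]` an miRNA `j` exerts on target `i` is
#'
#' \deqn{RC_{ij} = Exp(miRNA)_j \frac{AF_{ij}\,Exp(Target)_i}
#'   {\sum_{k \in targets(j)} AF_{kj}\,Exp(Target)_k}}
#'
#' so the whole expression of a miRNA is divided among its targets in
#' proportion to affinity-weighted target abundance. When every affinity is 1
#' this is plain expression-proportional sharing. By construction the
#' repression counts of a miRNA sum exactly to its expression (conservation).
#'
#' A miRNA whose entire target pool sits at zero expression sequesters
#' nowhere: its repression counts are all 0 (free miRNA) and the affected
#' miRNA ids are attached as attribute `free_mirnas` and reported via
#' [message()].
#'
#' @param network a `cerna_network`.
#' @param gene_expressions optional named numeric vector overriding the
#'   network's gene expressions (used by the simulation cycle).
#' @param mirna_expressions optional named numeric vector overriding the
#'   network's miRNA expressions.
#' @return A `repression_vector`: list with `edge_rc` (data frame `mirna`,
#'   `gene`, `rc`) and `gene_total` (named vector of region-weighted total
#'   repression per gene, 0 for untargeted genes).
#' @export
distribute_mirna <- function(network, gene_expressions = NULL,
                             mirna_expressions = NULL) {
  stopifnot(inherits(network, "cerna_network"))
  gexpr <- stats::setNames(network$genes$expression, network$genes$id)
  if (!is.null(gene_expressions)) {
    check_override(gene_expressions, names(gexpr), "gene_expressions")
    gexpr[names(gene_expressions)] <- gene_expressions
  }
  mexpr <- stats::setNames(network$mirnas$expression, network$mirnas$id)
  if (!is.null(mirna_expressions)) {
    check_override(mirna_expressions, names(mexpr), "mirna_expressions")
    mexpr[names(mirna_expressions)] <- mirna_expressions
  }
  if (any(gexpr < 0) || any(mexpr < 0)) {
    stop("expression values must be non-negative", call. = FALSE)
  }

  ed <- network$edges
  w <- ed$affinity * gexpr[ed$gene]
  denom <- tapply(w, ed$mirna, sum)[ed$mirna]
  rc <- ifelse(denom > 0, mexpr[ed$mirna] * w / denom, 0)

  free <- unique(ed$mirna[denom <= 0 & mexpr[ed$mirna] > 0])
  if (length(free)) {
    message("miRNA(s) with zero-expression target pool left free (RC = 0): ",
            paste(free, collapse = ", "))
  }

  gene_total <- stats::setNames(numeric(nrow(network$genes)), network$genes$id)
  contrib <- tapply(rc * ed$region_norm, ed$gene, sum)
  gene_total[names(contrib)] <- contrib

  structure(
    list(
      edge_rc = data.frame(mirna = ed$mirna, gene = ed$gene,
                           rc = as.numeric(rc), stringsAsFactors = FALSE),
      gene_total = gene_total
    ),
    free_mirnas = free,
    class = "repression_vector"
  )
}

#' Total repression exerted on each gene
#'
#' Aggregates the cooperative degradation a gene receives from all miRNAs
#' targeting it: the sum over incoming edges of the sequestered repression
#' count multiplied by the edge's normalized region effect. With all region
#' effects neutral this is the plain sum of incoming repression counts.
#' Untargeted genes receive 0.
#'
#' @param repression a `repression_vector` from [distribute_mirna()].
#' @param network the `cerna_network` the repression was computed on.
#' @return Named numeric vector of per-gene total repression.
#' @export
gene_repression <- function(repression, network) {
  stopifnot(inherits(repression, "repression_vector"),
            inherits(network, "cerna_network"))
  ed <- network$edges
  rc <- repression$edge_rc
  if (nrow(rc) != nrow(ed) ||
      !all(paste(rc$mirna, rc$gene) == paste(ed$mirna, ed$gene))) {
    stop("repression vector does not cover the network's edges", call. = FALSE)
  }
  out <- stats::setNames(numeric(nrow(network$genes)), network$genes$id)
  contrib <- tapply(rc$rc * ed$region_norm, ed$gene, sum)
  out[names(contrib)] <- contrib
  out
}
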