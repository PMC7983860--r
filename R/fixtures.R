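# run code under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' The worked-example network: two miRNAs sharing one target
#'
#' An eight-node toy network used throughout the documentation and tests:
#' miRNA M1 (expression 1,000) targets genes G1--G4 and miRNA M2 targets
#' G4--G6, so G4 bridges the two neighbourhoods. Gene expressions are 10,000
#' except G3 at 5,000. M2's expression and the G5/G6 expressions are this
#' package's own fixture assumptions (1,000 and 10,000); they do not affect
#' the M1 neighbourhood arithmetic. No interaction factors are attached, so
#' each miRNA splits in pure proportion to target expression: at steady state
#' M1 distributes 285.7/285.7/142.9/285.7 over G1/G2/G3/G4.
#'
#' @return A `cerna_network` with 8 nodes and 7 edges.
#' @examples
#' net <- make_sample_network()
#' round(distribute_mirna(net)$edge_rc$rc)
#' @export
make_sample_network <- function() {
  build_network(
    gene_expr = data.frame(
      id = paste0("G", 1:6),
      expression = c(10000, 10000, 5000, 10000, 10000, 10000)
    ),
    mirna_expr = data.frame(id = c("M1", "M2"), expression = c(1000, 1000)),
    edges = data.frame(
      mirna = c("M1", "M1", "M1", "M1", "M2", "M2", "M2"),
      gene = c("G1", "G2", "G3", "G4", "G4", "G5", "G6")
    )
  )
}

#' The worked-example network with interaction factors
#'
#' Same topology and expressions as [make_sample_network()] but with
#' per-edge binding energies, seed-type effects and region effects attached,
#' so affinity weighting and region-weighted degradation are exercised. The
#' factor values are synthetic constants chosen by this package (energies in
#' \[-25, -8\] kcal/mol, multipliers in \{0.5, 1\}); supplying neutral values
#' (equal energies, all multipliers 1) reproduces the unweighted network's
#' distribution exactly.
#'
#' @param energies numeric(7) binding energies (kcal/mol, `<= 0`), one per
#'   edge in the order M1-G1..G4, M2-G4..G6.
#' @param seed_effects numeric(7) positive seed-type multipliers.
#' @param region_effects numeric(7) positive region multipliers.
#' @return A `cerna_network` with normalized factors and affinities.
#' @export
make_sample_plus_network <- function(
    energies = c(-12, -20, -9, -25, -15, -10, -8),
    seed_effects = c(0.5, 1, 1, 0.5, 1, 0.5, 1),
    region_effects = c(1, 0.5, 1, 1, 0.5, 1, 0.5)) {
  stopifnot(length(energies) == 7L, length(seed_effects) == 7L,
            length(region_effects) == 7L)
  base <- make_sample_network()
  edges <- base$edges[, c("mirna", "gene")]
  edges$energy <- energies
  edges$seed_type_effect <- seed_effects
  edges$region_effect <- region_effects
  build_network(base$genes, base$mirnas, edges)
}

#' Generate a random bipartite ceRNA network
#'
#' Draws a seeded random bipartite network: each miRNA:gene pair becomes an
#' edge independently with probability `edge_density`, node expressions are
#' drawn log-normal (gene expression is typically right-skewed over orders of
#' magnitude, which the log-normal captures), and optional interaction
#' factors are drawn uniformly from documented ranges. miRNAs that end up
#' with no target are re-drawn (an isolated miRNA is invalid); if the density
#' is too low to connect every miRNA within `max_retries` redraws an error is
#' raised.
#'
#' @param n_genes,n_mirnas node counts.
#' @param edge_density edge probability in `(0, 1]`.
#' @param meanlog,sdlog log-normal expression parameters for genes
#'   (defaults `log(5000)`, 1).
#' @param mirna_meanlog,mirna_sdlog log-normal parameters for miRNAs
#'   (defaults `log(1000)`, 1).
#' @param with_factors draw per-edge energies/seed/region factors?
#' @param energy_range energy draw range (kcal/mol), default `c(-25, -8)`.
#' @param seed integer seed; identical seeds give identical networks.
#' @param max_retries redraw attempts per isolated miRNA (default 100).
#' @return A `cerna_network`.
#' @export
random_cerna_network <- function(n_genes, n_mirnas, edge_density,
                                 meanlog = log(5000), sdlog = 1,
                                 mirna_meanlog = log(1000), mirna_sdlog = 1,
                                 with_factors = FALSE,
                                 energy_range = c(-25, -8),
                                 seed = 1L, max_retries = 100L) {
  stopifnot(n_genes >= 1, n_mirnas >= 1,
            edge_density > 0, edge_density <= 1)
  with_seed(seed, {
    gene_ids <- sprintf("G%03d", seq_len(n_genes))
    mirna_ids <- sprintf("M%03d", seq_len(n_mirnas))

    adj <- matrix(stats::runif(n_mirnas * n_genes) < edge_density,
                  nrow = n_mirnas)
    for (j in seq_len(n_mirnas)) {
      tries <- 0L
      while (!any(adj[j, ])) {
        tries <- tries + 1L
        if (tries > max_retries) {
          stop("could not connect miRNA ", mirna_ids[j], " at density ",
               edge_density, call. = FALSE)
        }
        adj[j, ] <- stats::runif(n_genes) < edge_density
      }
    }
    idx <- which(t(adj), arr.ind = TRUE)  # transpose: order by miRNA then gene
    edges <- data.frame(mirna = mirna_ids[idx[, 2L]],
                        gene = gene_ids[idx[, 1L]],
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$mirna, edges$gene), , drop = FALSE]

    if (with_factors) {
      n <- nrow(edges)
      edges$energy <- stats::runif(n, energy_range[1L], energy_range[2L])
      edges$seed_type_effect <- sample(c(0.5, 1), n, replace = TRUE)
      edges$region_effect <- sample(c(0.5, 1), n, replace = TRUE)
    }

    build_network(
      gene_expr = data.frame(id = gene_ids,
                             expression = stats::rlnorm(n_genes, meanlog, sdlog)),
      mirna_expr = data.frame(id = mirna_ids,
                              expression = stats::rlnorm(n_mirnas, mirna_meanlog,
                                                         mirna_sdlog)),
      edges = edges
    )
  })
}

#' Generate a synthetic expression cohort from a template network
#'
#' Emulates overlaying per-patient expression profiles on one shared
#' interaction template. Every node's template expression is multiplied by
#' independent log-normal noise per sample. Optionally a set of signal nodes
#' receives an additional fold-shift in a designated subset of samples,
#' planting a recoverable group difference for calibration and
#' parameter-recovery studies.
#'
#' @param network template `cerna_network`.
#' @param n_samples number of samples (>= 1).
#' @param noise_sd_log standard deviation of the log-normal noise on the log
#'   scale (0 reproduces the template exactly; default 0.25, i.e. roughly
#'   +/-25% typical sample-to-sample variation).
#' @param seed integer seed.
#' @param signal_nodes optional node ids receiving the planted shift.
#' @param signal_fold fold change applied to signal nodes (default 3).
#' @param signal_samples indices of samples carrying the signal (default: the
#'   first half).
#' @return A `cerna_cohort`: list with `samples` (named list of
#'   `list(gene_expr, mirna_expr)` tables), `signal_nodes`, `signal_samples`.
#' @export
make_cohort <- function(network, n_samples, noise_sd_log = 0.25, seed = 1L,
                        signal_nodes = NULL, signal_fold = 3,
                        signal_samples = NULL) {
  stopifnot(inherits(network, "cerna_network"), n_samples >= 1,
            noise_sd_log >= 0)
  if (!is.null(signal_nodes)) {
    unknown <- setdiff(signal_nodes, c(network$genes$id, network$mirnas$id))
    if (length(unknown)) {
      stop("unknown signal node id(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if (is.null(signal_samples)) signal_samples <- seq_len(n_samples %/% 2)
  }

  with_seed(seed, {
    sample_ids <- sprintf("sample%02d", seq_len(n_samples))
    samples <- lapply(seq_len(n_samples), function(s) {
      noisy <- function(tab) {
        expr <- tab$expression *
          exp(stats::rnorm(nrow(tab), 0, noise_sd_log))
        if (!is.null(signal_nodes) && s %in% signal_samples) {
          hit <- tab$id %in% signal_nodes
          expr[hit] <- expr[hit] * signal_fold
        }
        data.frame(id = tab$id, expression = expr, stringsAsFactors = FALSE)
      }
      list(gene_expr = noisy(network$genes),
           mirna_expr = noisy(network$mirnas))
    })
    names(samples) <- sample_ids
    structure(list(samples = samples,
                   signal_nodes = signal_nodes,
                   signal_samples = if (is.null(signal_nodes)) integer(0)
                                    else sample_ids[signal_samples]),
              class = "cerna_cohort")
  })
}
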