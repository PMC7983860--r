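#' Read a node expression TSV
#'
#' Tab-separated, header required, `.` decimal separator. Two layouts are
#' accepted: `id, expression` (one node class per file) or a combined
#' `id, type, expression` file where `type` is `gene` or `miRNA`. Rows with
#' negative or non-numeric expression raise an error naming the file and
#' 1-based line number.
#'
#' @param path file path.
#' @return Data frame `id`, `expression` (plus `type` for combined files).
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "expression") %in% names(tab))) {
    stop(path, ": expected columns `id` and `expression`", call. = FALSE)
  }
  expr <- suppressWarnings(as.numeric(tab$expression))
  bad <- which(is.na(expr) | expr < 0)
  if (length(bad)) {
    stop(path, ": line ", bad[1L] + 1L,
         ": expression must be a non-negative number (id ",
         tab$id[bad[1L]], ")", call. = FALSE)
  }
  tab$expression <- expr
  tab
}

#' Read a miRNA:gene interaction TSV
#'
#' Columns `mirna`, `gene` and optionally `energy`, `seed_type_effect`,
#' `region_effect`; header required.
#'
#' @param path file path.
#' @return Data frame of edges.
#' @export
read_edges <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mirna", "gene") %in% names(tab))) {
    stop(path, ": expected columns `mirna` and `gene`", call. = FALSE)
  }
  for (col in intersect(c("energy", "seed_type_effect", "region_effect"),
                        names(tab))) {
    val <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(val) & !is.na(tab[[col]]) & tab[[col]] != "")
    if (length(bad)) {
      stop(path, ": line ", bad[1L] + 1L, ": `", col, "` is not numeric",
           call. = FALSE)
    }
    tab[[col]] <- val
  }
  tab
}

#' Read edge and expression files into one or many network instances
#'
#' With only the three main files this returns a single validated network.
#' With `samples_dir` set, every `*.tsv`/`*.txt` file in that directory is
#' read as a combined per-sample expression table (`id, type, expression`)
#' and overlaid on the shared interaction template, mirroring cohorts in
#' which many patients share one interaction network. Expression ids absent
#' from the edge list stay in the network as untargeted gene nodes (allowed,
#' with a warning from validation where relevant); miRNAs without targets
#' are dropped with a warning.
#'
#' @param edges,gene_expr,mirna_expr file paths.
#' @param samples_dir optional directory of per-sample expression files.
#' @return A `cerna_network`, or a named list of them (one per sample file).
#' @export
read_inputs <- function(edges, gene_expr, mirna_expr, samples_dir = NULL) {
  edge_tab <- read_edges(edges)
  template <- build_network(read_expression(gene_expr),
                            read_expression(mirna_expr),
                            edge_tab, drop_isolated_mirnas = TRUE)
  if (is.null(samples_dir)) return(template)

  files <- sort(list.files(samples_dir, pattern = "\\.(tsv|txt)$",
                           full.names = TRUE))
  if (!length(files)) {
    stop("no per-sample expression files (*.tsv, *.txt) in ", samples_dir,
         call. = FALSE)
  }
  nets <- lapply(files, function(f) {
    tab <- read_expression(f)
    if (!"type" %in% names(tab)) {
      stop(f, ": per-sample files need columns `id`, `type`, `expression`",
           call. = FALSE)
    }
    overlay_expression(template,
                       gene_expr = tab[tab$type == "gene", , drop = FALSE],
                       mirna_expr = tab[tab$type == "miRNA", , drop = FALSE])
  })
  names(nets) <- sub("\\.(tsv|txt)$", "", basename(files))
  nets
}

#' Write a network's expression and edge tables
#'
#' Writes the standard TSV trio (`<prefix>_edges.tsv`,
#' `<prefix>_gene_expr.tsv`, `<prefix>_mirna_expr.tsv`) so a network can be
#' round-tripped through [read_inputs()]. Raw factor columns are written only
#' when present.
#'
#' @param network a `cerna_network`.
#' @param prefix output path prefix.
#' @return Invisibly, the three file paths.
#' @export
write_network <- function(network, prefix) {
  stopifnot(inherits(network, "cerna_network"))
  ed <- network$edges
  fac <- c("energy", "seed_type_effect", "region_effect")
  keep <- c("mirna", "gene", fac[colSums(!is.na(ed[fac])) > 0])
  paths <- c(edges = paste0(prefix, "_edges.tsv"),
             gene_expr = paste0(prefix, "_gene_expr.tsv"),
             mirna_expr = paste0(prefix, "_mirna_expr.tsv"))
  write_tsv(ed[, keep, drop = FALSE], paths["edges"])
  write_tsv(network$genes, paths["gene_expr"])
  write_tsv(network$mirnas, paths["mirna_expr"])
  invisible(paths)
}

# deterministic TSV writer: fixed column order, 6 significant digits, "." decimals
write_tsv <- function(tab, path) {
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) {
    ifelse(is.na(x), NA, format(signif(x, 6), trim = TRUE, scientific = FALSE))
  })
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write a screening table
#'
#' Deterministic output: rows sorted by `(sample_id, node_id)`, numeric
#' columns at 6 significant digits. An empty table yields a header-only file.
#'
#' @param tables a `screen_table`.
#' @param path output path.
#' @export
write_screen_table <- function(tables, path) {
  stopifnot(is.data.frame(tables))
  ord <- order(tables$sample_id, tables$node_id)
  cols <- c("sample_id", "node_id", "node_class", "perturbed_count",
            "efficiency", "cycles_run")
  write_tsv(tables[ord, cols, drop = FALSE], path)
}

#' Write significance thresholds as a key-value text file
#'
#' @param thresholds a `significance_thresholds` object.
#' @param path output path.
#' @export
write_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "significance_thresholds"))
  lines <- c(
    paste0("min_perturbed_nodes\t", thresholds$min_perturbed_nodes),
    paste0("min_samples\t", thresholds$min_samples),
    paste0("method\t", thresholds$method)
  )
  mp <- thresholds$mixture_params
  if (!is.null(mp)) {
    fmt <- function(x) paste(format(signif(x, 6), trim = TRUE), collapse = ",")
    lines <- c(lines,
               paste0("mixture_weights\t", fmt(mp$weights)),
               paste0("mixture_means\t", fmt(mp$means)),
               paste0("mixture_variances\t", fmt(mp$variances)),
               paste0("log_likelihood\t",
                      format(signif(thresholds$fit_metric, 6), trim = TRUE)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write per-trigger perturbation metrics
#'
#' @param result a `perturbation_result`.
#' @param path output path.
#' @export
write_perturbation_result <- function(result, path) {
  stopifnot(inherits(result, "perturbation_result"))
  tab <- data.frame(
    trigger_id = paste(result$trigger_id, collapse = ","),
    fold = paste(format(result$fold, trim = TRUE), collapse = ","),
    perturbed_count = result$perturbed_count,
    efficiency = result$efficiency,
    cycles_run = result$cycles_run,
    converged = result$converged,
    stringsAsFactors = FALSE
  )
  write_tsv(tab, path)
}

#' Write a simulation trajectory as a long table
#'
#' One row per `(cycle, node)` with the node's expression at that cycle.
#'
#' @param trajectory a `simulation_trajectory`.
#' @param path output path.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "simulation_trajectory"))
  rows <- lapply(trajectory, function(st) {
    expr <- c(st$gene_expression, st$mirna_expression)
    data.frame(cycle = st$cycle, node = names(expr),
               expression = as.numeric(expr), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$cycle, tab$node), , drop = FALSE]
  write_tsv(tab, path)
}

#' Export a network for external graph viewers
#'
#' GraphML carries node attributes (`class`, `expression`, optionally
#' `percent_change`) and edge attributes (`rc` — the steady-state repression
#' count — and `affinity`); SIF writes one `miRNA represses gene` line per
#' edge. Both open directly in Cytoscape-compatible tools.
#'
#' @param network a `cerna_network`.
#' @param path output path.
#' @param format `"graphml"` or `"sif"`.
#' @param deltas optional named percent changes (from
#'   [perturbation_metrics()]'s `per_node_delta`) stored as a node attribute.
#' @return Invisibly, `path`.
#' @export
export_graph <- function(network, path, format = c("graphml", "sif"),
                         deltas = NULL) {
  stopifnot(inherits(network, "cerna_network"))
  format <- match.arg(format)
  if (format == "sif") {
    writeLines(paste(network$edges$mirna, "represses", network$edges$gene),
               path)
    return(invisible(path))
  }
  rv <- distribute_mirna(network)
  nodes <- data.frame(
    name = c(network$mirnas$id, network$genes$id),
    class = rep(c("miRNA", "gene"),
                c(nrow(network$mirnas), nrow(network$genes))),
    expression = c(network$mirnas$expression, network$genes$expression),
    stringsAsFactors = FALSE
  )
  if (!is.null(deltas)) {
    nodes$percent_change <- ifelse(nodes$name %in% names(deltas),
                                   deltas[nodes$name], 0)
  }
  edges <- data.frame(from = network$edges$mirna, to = network$edges$gene,
                      rc = rv$edge_rc$rc, affinity = network$edges$affinity,
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
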