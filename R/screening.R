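#' Screen every node of a network as a candidate trigger
#'
#' Each gene and each miRNA in turn is used as the trigger of a full
#' perturbation simulation, and its perturbed count (number of other nodes
#' whose expression changes by at least `limit` percent) and perturbation
#' efficiency (mean absolute percent change over those nodes) are recorded.
#' The screen is deterministic given its inputs and the rows are sorted by
#' node id, so the table is identical regardless of iteration order or any
#' parallel chunking a caller may layer on top.
#'
#' @param network a `cerna_network`.
#' @param fold trigger fold change applied to each node in turn (default 3).
#' @param max_cycles,tolerance passed to [run_simulation()].
#' @param limit perturbation limit in percent (default 0.1).
#' @param sample_id label stored in the `sample_id` column (default
#'   `"sample1"`).
#' @return A `screen_table` data frame with columns `sample_id`, `node_id`,
#'   `node_class` (`"gene"` or `"miRNA"`), `perturbed_count`, `efficiency`,
#'   `cycles_run`.
#' @export
screen_all_nodes <- function(network, fold = 3, max_cycles = 30L,
                             tolerance = 1e-6, limit = 0.1,
                             sample_id = "sample1") {
  stopifnot(inherits(network, "cerna_network"), fold > 0)
  nodes <- data.frame(
    id = c(network$genes$id, network$mirnas$id),
    class = rep(c("gene", "miRNA"),
                c(nrow(network$genes), nrow(network$mirnas))),
    stringsAsFactors = FALSE
  )
  nodes <- nodes[order(nodes$id), , drop = FALSE]

  res <- lapply(seq_len(nrow(nodes)), function(i) {
    trig <- stats::setNames(fold, nodes$id[i])
    traj <- run_simulation(network, trig, max_cycles = max_cycles,
                           tolerance = tolerance)
    met <- suppressWarnings(perturbation_metrics(traj, limit = limit))
    data.frame(sample_id = sample_id,
               node_id = nodes$id[i],
               node_class = nodes$class[i],
               perturbed_count = met$perturbed_count,
               efficiency = met$efficiency,
               cycles_run = met$cycles_run,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("screen_table", "data.frame")
  out
}

#' Overlay per-sample expression values on an interaction template
#'
#' Real cohorts share one miRNA:target interaction template while each sample
#' contributes its own expression profile. This swaps the expressions of an
#' existing network for per-sample values; interaction factors and topology
#' are untouched. Ids present in the tables but absent from the network are
#' ignored with a warning; network nodes missing from the tables keep their
#' template expression.
#'
#' @param network template `cerna_network`.
#' @param gene_expr,mirna_expr data frames with columns `id`, `expression`.
#' @return A `cerna_network` with the overlaid expressions.
#' @export
overlay_expression <- function(network, gene_expr, mirna_expr) {
  stopifnot(inherits(network, "cerna_network"))
  check_expr_table(gene_expr, "gene_expr")
  check_expr_table(mirna_expr, "mirna_expr")

  overlay_one <- function(tab, nodes, what) {
    ids <- as.character(tab$id)
    unknown <- setdiff(ids, nodes$id)
    if (length(unknown)) {
      warning("ignoring ", what, " id(s) absent from the network: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    }
    keep <- ids %in% nodes$id
    nodes$expression[match(ids[keep], nodes$id)] <-
      as.numeric(tab$expression)[keep]
    nodes
  }
  network$genes <- overlay_one(gene_expr, network$genes, "gene")
  network$mirnas <- overlay_one(mirna_expr, network$mirnas, "miRNA")
  network
}

#' Screen all nodes across a cohort of samples
#'
#' Runs [screen_all_nodes()] on one network instance per sample, built by
#' overlaying each sample's expression profile on the shared interaction
#' template, and binds the per-sample tables.
#'
#' @param network template `cerna_network`.
#' @param cohort a cohort as produced by [make_cohort()], or any named list
#'   of `list(gene_expr =, mirna_expr =)` pairs.
#' @param ... passed to [screen_all_nodes()].
#' @return A `screen_table` covering all samples.
#' @export
screen_cohort <- function(network, cohort, ...) {
  samples <- if (!is.null(cohort$samples)) cohort$samples else cohort
  stopifnot(length(samples) >= 1L, !is.null(names(samples)))
  tabs <- lapply(names(samples), function(sid) {
    inst <- overlay_expression(network, samples[[sid]]$gene_expr,
                               samples[[sid]]$mirna_expr)
    screen_all_nodes(inst, sample_id = sid, ...)
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  class(out) <- c("screen_table", "data.frame")
  out
}

#' Construct a significance-thresholds object
#'
#' Containers of the two cutoffs that define a significantly perturbing node:
#' the minimum perturbed-node count a trigger must reach within a sample, and
#' the minimum number of samples in which it must reach that count. Usually
#' produced by [fit_significance_threshold()], but can be built directly when
#' cutoffs come from elsewhere.
#'
#' @param min_perturbed_nodes integer >= 1.
#' @param min_samples integer >= 1.
#' @param mixture_params optional list of fitted mixture parameters
#'   (`weights`, `means`, `variances`).
#' @param fit_metric optional log-likelihood of the fit.
#' @param method how the cutoffs were obtained (`"mixture"`, `"quantile"`,
#'   `"manual"`).
#' @return A `significance_thresholds` object.
#' @export
significance_thresholds <- function(min_perturbed_nodes, min_samples,
                                    mixture_params = NULL, fit_metric = NA_real_,
                                    method = "manual") {
  stopifnot(min_perturbed_nodes >= 1, min_samples >= 1)
  if (!is.null(mixture_params) && !is.null(mixture_params$weights)) {
    stopifnot(abs(sum(mixture_params$weights) - 1) < 1e-8)
  }
  structure(
    list(min_perturbed_nodes = as.integer(ceiling(min_perturbed_nodes)),
         min_samples = as.integer(ceiling(min_samples)),
         mixture_params = mixture_params,
         fit_metric = fit_metric,
         method = method),
    class = "significance_thresholds"
  )
}

#' @export
print.significance_thresholds <- function(x, ...) {
  cat("Significance thresholds (", x$method, "): perturbed count >= ",
      x$min_perturbed_nodes, " in >= ", x$min_samples, " sample(s)\n",
      sep = "")
  invisible(x)
}

#' Calibrate significance thresholds with a finite Gaussian mixture
#'
#' The pooled per-node, per-sample distribution of perturbation statistics is
#' typically a mixture of a large background regime (most triggers barely
#' move the network) and a small high-impact regime. A finite Gaussian
#' mixture (default 2 components, EM via \pkg{mclust}) is fitted to the
#' pooled values; the perturbed-count cutoff is the smallest value whose
#' posterior probability of belonging to the highest-mean component exceeds
#' 0.5. The sample cutoff is then derived the same way from the per-node
#' distribution of "number of samples reaching the count cutoff". When EM
#' degenerates (component collapse, all values identical, no posterior
#' crossover in range) the cutoff falls back to the 95th percentile with a
#' warning.
#'
#' @param tables a `screen_table` spanning one or more samples.
#' @param n_components number of mixture components (default 2).
#' @param statistic which column the count cutoff is fitted on:
#'   `"perturbed_count"` (default) or `"efficiency"`.
#' @return A `significance_thresholds` object whose `mixture_params` holds
#'   the fitted weights, means and variances of the count fit.
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_significance_threshold <- function(tables, n_components = 2L,
                                       statistic = c("perturbed_count",
                                                     "efficiency")) {
  statistic <- match.arg(statistic)
  stopifnot(is.data.frame(tables), statistic %in% names(tables))
  if (length(unique(tables$sample_id)) < 2L) {
    stop("threshold calibration needs a screen over >= 2 samples",
         call. = FALSE)
  }

  x <- as.numeric(tables[[statistic]])
  count_fit <- mixture_cutpoint(x, n_components)

  pass <- tables[[statistic]] >= count_fit$cut
  n_pass <- tapply(pass, tables$node_id, sum)
  sample_fit <- mixture_cutpoint(as.numeric(n_pass), n_components)

  significance_thresholds(
    min_perturbed_nodes = max(1, count_fit$cut),
    min_samples = max(1, sample_fit$cut),
    mixture_params = count_fit$params,
    fit_metric = count_fit$loglik,
    method = if (count_fit$method == "mixture" &&
                 sample_fit$method == "mixture") "mixture" else "quantile"
  )
}

# smallest value whose posterior for the highest-mean component exceeds 0.5;
# falls back to the 95th percentile when EM cannot separate components
mixture_cutpoint <- function(x, n_components) {
  fallback <- function(reason) {
    warning("mixture fit degenerate (", reason,
            "); falling back to the 95th-percentile cut", call. = FALSE)
    list(cut = as.numeric(stats::quantile(x, 0.95, names = FALSE)),
         params = NULL, loglik = NA_real_, method = "quantile")
  }
  if (length(unique(x)) < 2L * n_components) return(fallback("too few distinct values"))

  fit <- tryCatch(
    Mclust(x, G = n_components, modelNames = c("E", "V"), verbose = FALSE),
    error = function(e) NULL
  )
  if (is.null(fit)) return(fallback("EM failed"))

  means <- as.numeric(fit$parameters$mean)
  vars <- as.numeric(fit$parameters$variance$sigmasq)
  if (length(vars) == 1L) vars <- rep(vars, n_components)
  weights <- as.numeric(fit$parameters$pro)
  if (any(weights < 1e-8) || diff(range(means)) < 1e-8 * max(1, max(abs(means)))) {
    return(fallback("component collapse"))
  }

  top <- which.max(means)
  grid <- seq(floor(min(x)), ceiling(max(x)),
              by = max(1, floor((max(x) - min(x)) / 10000)))
  dens <- vapply(seq_len(n_components), function(k) {
    weights[k] * stats::dnorm(grid, means[k], sqrt(vars[k]))
  }, numeric(length(grid)))
  post_top <- dens[, top] / rowSums(dens)
  hit <- which(post_top > 0.5)
  if (!length(hit)) return(fallback("no posterior crossover in range"))

  list(cut = grid[hit[1L]],
       params = list(weights = weights, means = means, variances = vars),
       loglik = fit$loglik,
       method = "mixture")
}

#' Select significantly perturbing nodes
#'
#' A node is significant when its perturbed count reaches the count cutoff in
#' at least the required number of samples. With paired sample groups (for
#' example tumour and normal tissue) each selected node is additionally
#' labelled `"all"` when it is significant in every group or
#' `"<group>_specific"` when significant in exactly one.
#'
#' @param tables a `screen_table`.
#' @param thresholds a `significance_thresholds` object.
#' @param sample_groups optional named character vector mapping `sample_id`
#'   to a group label.
#' @return Data frame of selected nodes: `node_id`, `node_class`,
#'   `n_samples_passing` and, when groups are given, `class`.
#' @export
select_significant_nodes <- function(tables, thresholds, sample_groups = NULL) {
  stopifnot(is.data.frame(tables),
            inherits(thresholds, "significance_thresholds"))
  pass <- tables$perturbed_count >= thresholds$min_perturbed_nodes

  summarise <- function(tab, pass) {
    n_pass <- tapply(pass, tab$node_id, sum)
    cls <- tab$node_class[match(names(n_pass), tab$node_id)]
    data.frame(node_id = names(n_pass), node_class = cls,
               n_samples_passing = as.integer(n_pass),
               significant = as.integer(n_pass) >= thresholds$min_samples,
               stringsAsFactors = FALSE)
  }

  if (is.null(sample_groups)) {
    out <- summarise(tables, pass)
    out <- out[out$significant, c("node_id", "node_class",
                                  "n_samples_passing"), drop = FALSE]
    out <- out[order(out$node_id), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }

  missing_grp <- setdiff(unique(tables$sample_id), names(sample_groups))
  if (length(missing_grp)) {
    stop("sample group label missing for: ",
         paste(missing_grp, collapse = ", "), call. = FALSE)
  }
  grp <- sample_groups[tables$sample_id]
  per_group <- lapply(split(seq_len(nrow(tables)), grp), function(idx) {
    summarise(tables[idx, , drop = FALSE], pass[idx])
  })
  groups <- names(per_group)
  sig_in <- sapply(per_group, function(s) {
    stats::setNames(s$significant, s$node_id)[unique(tables$node_id)]
  })
  sig_in[is.na(sig_in)] <- FALSE
  rownames(sig_in) <- unique(tables$node_id)

  any_sig <- rowSums(sig_in) > 0
  label <- ifelse(rowSums(sig_in) == length(groups), "all",
                  paste0(groups[apply(sig_in, 1, which.max)], "_specific"))
  total_pass <- tapply(pass, tables$node_id, sum)[rownames(sig_in)]
  cls <- tables$node_class[match(rownames(sig_in), tables$node_id)]

  out <- data.frame(node_id = rownames(sig_in)[any_sig],
                    node_class = cls[any_sig],
                    n_samples_passing = as.integer(total_pass[any_sig]),
                    class = label[any_sig],
                    stringsAsFactors = FALSE)
  out <- out[order(out$node_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
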