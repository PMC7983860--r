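#' Apply a perturbation trigger to a network at steady state
#'
#' The pre-trigger network is taken to be at steady state: each miRNA's
#' repression is already distributed over its targets and all abundances are
#' stable. A trigger multiplies the expression of one or more nodes by a fold
#' change (`fold > 1` up-regulation, `fold < 1` down-regulation); everything
#' else is left untouched. Triggering a miRNA is allowed — its scaled
#' expression redistributes over its targets in subsequent cycles. The
#' pre-trigger steady-state repression distribution is stored in the returned
#' state so the first cycle can measure how much repression each gene gains or
#' loses.
#'
#' @param network a `cerna_network`.
#' @param triggers named numeric vector mapping node ids to fold changes
#'   (e.g. `c(G2 = 2)`), or `NULL` for an untriggered state (useful for
#'   fixed-point checks).
#' @return A `simulation_state` at cycle 0.
#' @export
apply_trigger <- function(network, triggers = NULL) {
  stopifnot(inherits(network, "cerna_network"))
  gexpr <- stats::setNames(network$genes$expression, network$genes$id)
  mexpr <- stats::setNames(network$mirnas$expression, network$mirnas$id)

  if (!is.null(triggers)) {
    if (is.null(names(triggers)) || any(names(triggers) == "")) {
      stop("`triggers` must be a named numeric vector (id -> fold)",
           call. = FALSE)
    }
    unknown <- setdiff(names(triggers), c(names(gexpr), names(mexpr)))
    if (length(unknown)) {
      stop("unknown trigger node id(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if (any(triggers <= 0)) {
      stop("trigger fold changes must be > 0", call. = FALSE)
    }
  }

  steady <- distribute_mirna(network)

  for (id in names(triggers)) {
    if (id %in% names(gexpr)) {
      gexpr[id] <- gexpr[id] * triggers[[id]]
    } else {
      mexpr[id] <- mexpr[id] * triggers[[id]]
    }
  }

  structure(
    list(
      cycle = 0L,
      gene_expression = gexpr,
      mirna_expression = mexpr,
      initial_gene_expression = stats::setNames(network$genes$expression,
                                                network$genes$id),
      initial_mirna_expression = stats::setNames(network$mirnas$expression,
                                                 network$mirnas$id),
      previous_repression = steady,
      trigger = triggers,
      max_change = NA_real_
    ),
    class = "simulation_state"
  )
}

#' Run one redistribution cycle
#'
#' One cycle of the iterative propagation: (i) every miRNA's repression is
#' redistributed over its targets from the current expressions; (ii) each
#' gene's available expression changes by the repression it lost or gained,
#' `expr_new = max(0, expr_current + (R_prev - R_new))`, applied synchronously
#' to all genes; (iii) the cycle counter advances. miRNA expressions never
#' change during a trajectory — miRNAs are recycled, only targets are
#' degraded — so each miRNA's total distributed repression stays equal to its
#' expression at every cycle. The steady state is an exact fixed point of this
#' map.
#'
#' @param state a `simulation_state`.
#' @param network the `cerna_network` being simulated.
#' @return The updated `simulation_state`; `max_change` holds the largest
#'   absolute per-gene expression change of this cycle.
#' @export
run_cycle <- function(state, network) {
  stopifnot(inherits(state, "simulation_state"),
            inherits(network, "cerna_network"))
  rv_new <- distribute_mirna(network,
                             gene_expressions = state$gene_expression,
                             mirna_expressions = state$mirna_expression)
  r_prev <- state$previous_repression$gene_total
  r_new <- rv_new$gene_total
  ids <- names(state$gene_expression)
  new_expr <- pmax(0, state$gene_expression + (r_prev[ids] - r_new[ids]))
  names(new_expr) <- ids

  state$max_change <- max(abs(new_expr - state$gene_expression))
  state$gene_expression <- new_expr
  state$previous_repression <- rv_new
  state$cycle <- state$cycle + 1L
  state
}

#' Propagate a perturbation to convergence
#'
#' Applies the trigger and iterates [run_cycle()] until either the maximum
#' absolute per-gene expression change of a cycle falls below `tolerance`
#' (convergence to a fixed point) or `max_cycles` is reached
#' (non-convergence, reported but not an error). The full trajectory is
#' returned so intermediate neighbourhood effects — the ripple spreading from
#' the trigger through shared miRNAs and common targets — are inspectable
#' cycle by cycle.
#'
#' @param network a `cerna_network`.
#' @param triggers named fold-change vector as in [apply_trigger()].
#' @param max_cycles maximum number of redistribution cycles (default 30).
#' @param tolerance absolute convergence tolerance on the per-cycle maximum
#'   expression change, in expression units (default 1e-6).
#' @return A `simulation_trajectory`: list of `simulation_state`s from cycle 0
#'   to the last cycle run, with attributes `converged`, `cycles_run` and
#'   `max_change_series`.
#' @export
run_simulation <- function(network, triggers = NULL, max_cycles = 30L,
                           tolerance = 1e-6) {
  stopifnot(max_cycles >= 1L, tolerance >= 0)
  state <- apply_trigger(network, triggers)
  trajectory <- list(state)
  changes <- numeric(0)
  converged <- FALSE
  for (k in seq_len(max_cycles)) {
    state <- run_cycle(state, network)
    trajectory[[k + 1L]] <- state
    changes[k] <- state$max_change
    if (state$max_change < tolerance) {
      converged <- TRUE
      break
    }
  }
  structure(trajectory,
            converged = converged,
            cycles_run = state$cycle,
            max_change_series = changes,
            class = "simulation_trajectory")
}

#' Perturbation metrics for a completed trajectory
#'
#' For every node the percent change of its final expression relative to its
#' pre-trigger expression is computed (`100 * (final - initial) / initial`).
#' Nodes whose absolute percent change reaches `limit` count as perturbed;
#' trigger nodes are always excluded from the perturbed count and from the
#' efficiency. The perturbation efficiency is the mean absolute percent
#' change over the perturbed nodes (0 when none). Non-trigger genes with zero
#' initial expression carry no meaningful percent change; they are excluded
#' and recorded in attribute `excluded_nodes` with a warning.
#'
#' @param trajectory a `simulation_trajectory` from [run_simulation()].
#' @param limit perturbation limit in percent units; a node is affected when
#'   `|percent change| >= limit` (default 0.1).
#' @return A `perturbation_result` list: `trigger_id`, `fold`,
#'   `perturbed_count`, `efficiency` (percent), `per_node_delta` (named
#'   percent changes, trigger included for reference), `cycles_run`,
#'   `converged`.
#' @export
perturbation_metrics <- function(trajectory, limit = 0.1) {
  stopifnot(inherits(trajectory, "simulation_trajectory"),
            length(trajectory) >= 1L, limit >= 0)
  first <- trajectory[[1L]]
  last <- trajectory[[length(trajectory)]]

  initial <- c(first$initial_gene_expression, first$initial_mirna_expression)
  final <- c(last$gene_expression, last$mirna_expression)
  final <- final[names(initial)]

  trigger_ids <- names(first$trigger)
  positive <- initial > 0
  zero_nontrigger <- names(initial)[!positive & !(names(initial) %in% trigger_ids)]
  if (length(zero_nontrigger)) {
    warning("node(s) with zero initial expression excluded from percent ",
            "changes: ", paste(zero_nontrigger, collapse = ", "),
            call. = FALSE)
  }

  delta <- 100 * (final[positive] - initial[positive]) / initial[positive]
  eligible <- delta[!(names(delta) %in% trigger_ids)]
  perturbed <- eligible[abs(eligible) >= limit]

  structure(
    list(
      trigger_id = if (is.null(trigger_ids)) character(0) else trigger_ids,
      fold = if (is.null(first$trigger)) numeric(0) else unname(first$trigger),
      perturbed_count = length(perturbed),
      efficiency = if (length(perturbed)) mean(abs(perturbed)) else 0,
      per_node_delta = delta,
      cycles_run = attr(trajectory, "cycles_run"),
      converged = attr(trajectory, "converged")
    ),
    excluded_nodes = zero_nontrigger,
    class = "perturbation_result"
  )
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat("Perturbation of ", paste(x$trigger_id, collapse = ", "),
      " (fold ", paste(format(x$fold), collapse = ", "), "): ",
      x$perturbed_count, " node(s) perturbed, efficiency ",
      format(x$efficiency, digits = 4), "% over ", x$cycles_run,
      " cycle(s)", if (!isTRUE(x$converged)) " [not converged]", "\n",
      sep = "")
  invisible(x)
}
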