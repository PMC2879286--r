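# Task-pull execution and deterministic merging.
#
# The coordinator turns a partition into a task list, hands tasks to an
# executor, and merges results keyed by task id, so the merged output is
# identical for every processor count and arrival order. Two executors are
# provided behind one contract: "serial" (a plain loop, the reference path)
# and "processes" (a forked worker pool via the base parallel package, one
# fork per task so idle workers pull the next unassigned task). Statistics
# code never knows which executor runs it.

#' Build a task list from a partition
#'
#' @param partition a [partition_linear()] or [partition_pairwise()] result.
#' @param kind computation type label (`"type1"`, `"type2"`, `"type3"`,
#'   `"type4"`).
#' @return list of tasks, each with a dense 0-based `task_id`, the `block`
#'   (an index range or pair block) and `kind`.
#' @export
make_tasks <- function(partition, kind = "type1") {
  blocks <- if (inherits(partition, "linear_partition")) partition$ranges
            else if (inherits(partition, "pairwise_plan")) partition$blocks
            else stop_parameter("partition must be a linear_partition or pairwise_plan")
  lapply(seq_along(blocks), function(i)
    list(task_id = i - 1L, block = blocks[[i]], kind = kind))
}

#' Run tasks under the task-pull discipline
#'
#' Every task is executed exactly once; results are returned ordered by task
#' id regardless of completion order, so downstream merges are independent
#' of scheduling. A worker failure is captured as a `"failed"` result
#' carrying the task id and diagnostic; the remaining tasks still run.
#'
#' @param tasks task list from [make_tasks()].
#' @param worker function of one task returning its result body.
#' @param nprocs processor count `P >= 1`. `P = 1` always uses the plain
#'   sequential loop.
#' @param executor `"serial"` or `"processes"` (forked pool; each idle
#'   worker pulls the next unassigned task).
#' @return list of results ordered by `task_id`, each with `task_id`,
#'   `body`, `status` (`"ok"`/`"failed"`) and `diagnostic`.
#' @export
run_tasks <- function(tasks, worker,
                      nprocs = 1L, executor = c("serial", "processes")) {
  executor <- match.arg(executor)
  if (!is_count(nprocs, 1L)) stop_parameter("nprocs must be a count >= 1")
  if (length(tasks) == 0L) stop_parameter("task list is empty")
  run_one <- function(task) {
    tryCatch(
      list(task_id = task$task_id, body = worker(task),
           status = "ok", diagnostic = NA_character_),
      error = function(e)
        list(task_id = task$task_id, body = NULL,
             status = "failed", diagnostic = conditionMessage(e)))
  }
  results <- if (nprocs == 1L || executor == "serial") {
    lapply(tasks, run_one)
  } else {
    raw <- parallel::mclapply(tasks, run_one, mc.cores = as.integer(nprocs),
                              mc.preschedule = FALSE)
    lapply(seq_along(raw), function(i) {
      r <- raw[[i]]
      if (inherits(r, "try-error") || is.null(r$status))
        list(task_id = tasks[[i]]$task_id, body = NULL, status = "failed",
             diagnostic = paste("worker process failure:",
                                paste(as.character(r), collapse = " ")))
      else r
    })
  }
  results[order(vapply(results, `[[`, integer(1), "task_id"))]
}

#' Merge linearly partitioned table results
#'
#' Concatenates per-range tables in range order, reproducing the row order
#' of the sequential computation.
#'
#' @param results output of [run_tasks()] for a linear partition.
#' @param partition the [partition_linear()] the tasks came from.
#' @return data frame.
#' @export
merge_linear <- function(results, partition) {
  stopifnot(inherits(partition, "linear_partition"))
  failed <- Filter(function(r) r$status != "ok", results)
  if (length(failed) > 0L)
    stop_merge(paste("failed task(s):",
                     paste(vapply(failed, `[[`, integer(1), "task_id"),
                           collapse = ", ")))
  if (length(results) != length(partition$ranges))
    stop_merge(sprintf("expected %d results, got %d",
                       length(partition$ranges), length(results)))
  out <- do.call(rbind, lapply(results, `[[`, "body"))
  rownames(out) <- NULL
  out
}

#' Merge pairwise block results into a symmetric matrix
#'
#' Blocks are placed at their row/column positions. Because both
#' off-diagonal quadrants of each pair are computed, every off-diagonal cell
#' is produced twice (once in each triangle); the duplicates must agree
#' within `tol` — a disagreement signals a worker bug — and the upper-
#' triangle value is kept, so the result is exactly symmetric. With
#' `mirror = TRUE` blocks lying strictly below the diagonal may be absent
#' and are filled by transposition (the `exploit_symmetry` scheduling
#' option).
#'
#' @param results output of [run_tasks()]; each body must be a list with a
#'   `values` submatrix and an `n_shared` submatrix.
#' @param plan the [partition_pairwise()] plan the tasks came from.
#' @param ids identifiers for the matrix rows/columns.
#' @param statistic label stored on the result (`"ibs"`, `"kinship"`,
#'   `"r2"`, `"dprime"`, `"rho"`).
#' @param tol symmetric-duplicate agreement tolerance.
#' @param mirror allow blocks strictly below the diagonal to be missing.
#' @return a [pair_matrix()].
#' @export
merge_pairwise <- function(results, plan, ids = NULL, statistic = "ibs",
                           tol = 1e-12, mirror = FALSE) {
  stopifnot(inherits(plan, "pairwise_plan"))
  failed <- Filter(function(r) r$status != "ok", results)
  if (length(failed) > 0L)
    stop_merge(paste("failed task(s):",
                     paste(vapply(failed, `[[`, integer(1), "task_id"),
                           collapse = ", ")))
  n <- plan$n
  if (is.null(ids)) ids <- as.character(seq_len(n))
  expected <- if (mirror)
    which(!vapply(plan$blocks, block_below_diagonal, logical(1)))
  else seq_along(plan$blocks)
  got <- vapply(results, `[[`, integer(1), "task_id") + 1L
  missing_blocks <- setdiff(expected, got)
  if (length(missing_blocks) > 0L) {
    b <- plan$blocks[[missing_blocks[1L]]]
    stop_merge(sprintf("missing result for block %d (lineage %s)",
                       missing_blocks[1L] - 1L,
                       paste(b$lineage, collapse = ".")))
  }
  V <- matrix(NA_real_, n, n)
  S <- matrix(NA_real_, n, n)
  cover <- matrix(0L, n, n)
  for (r in results) {
    b <- plan$blocks[[r$task_id + 1L]]
    ri <- (b$rows$start + 1L):b$rows$stop
    ci <- (b$cols$start + 1L):b$cols$stop
    body <- r$body
    if (is.null(body$values) ||
        !all(dim(as.matrix(body$values)) == c(length(ri), length(ci))))
      stop_merge(sprintf("block %d result has wrong shape", r$task_id))
    V[ri, ci] <- as.matrix(body$values)
    S[ri, ci] <- as.matrix(body$n_shared)
    cover[ri, ci] <- cover[ri, ci] + 1L
  }
  if (mirror) {
    fill <- cover == 0L & t(cover) == 1L
    V[fill] <- t(V)[fill]
    S[fill] <- t(S)[fill]
    cover[fill] <- 1L
  }
  if (any(cover != 1L))
    stop_merge("pairwise blocks do not cover the grid exactly once")
  both <- !is.na(V) & !is.na(t(V))
  if (any(both)) {
    dev <- max(abs(V[both] - t(V)[both]))
    if (dev > tol)
      stop_consistency(sprintf(
        "symmetric duplicates disagree (max |diff| = %.3g > %.3g)", dev, tol))
  }
  if (any(xor(is.na(V), is.na(t(V)))))
    stop_consistency("asymmetric missingness pattern in merged matrix")
  lw <- lower.tri(V)
  V[lw] <- t(V)[lw]
  S[lw] <- t(S)[lw]
  pair_matrix(ids, V, statistic, S)
}

block_below_diagonal <- function(b) b$rows$start >= b$cols$stop

#' Symmetric pair matrix
#'
#' Container for individual-by-individual or SNP-by-SNP statistics.
#'
#' @param ids ordered identifiers.
#' @param values symmetric numeric matrix.
#' @param statistic label: `"ibs"`, `"kinship"`, `"r2"`, `"dprime"`, `"rho"`.
#' @param n_shared symmetric matrix of pairwise complete-observation counts.
#' @return object of class `pair_matrix`.
#' @export
pair_matrix <- function(ids, values, statistic, n_shared = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop_parameter("values must be square")
  if (length(ids) != nrow(values))
    stop_parameter("ids length must match matrix dimension")
  dimnames(values) <- list(ids, ids)
  if (!is.null(n_shared)) {
    n_shared <- as.matrix(n_shared)
    dimnames(n_shared) <- list(ids, ids)
  }
  structure(list(ids = as.character(ids), values = values,
                 statistic = statistic, n_shared = n_shared),
            class = "pair_matrix")
}

#' @method print pair_matrix
#' @export
print.pair_matrix <- function(x, ...) {
  cat(sprintf("pair_matrix (%s): %d x %d\n", x$statistic,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Parallelization overhead
#'
#' The overhead of running on `P` processors is the parallel wall time minus
#' the ideal time, `time_P_cpus - time_a_cpu / P`: the cost of data
#' partitioning, distribution and merging that parallelism adds.
#'
#' @param time_a_cpu serial (one-processor) duration, >= 0.
#' @param time_P_cpus measured duration on `P` processors, >= 0.
#' @param P processor count, >= 1.
#' @return overhead in the same units as the inputs.
#' @export
overhead <- function(time_a_cpu, time_P_cpus, P) {
  if (any(!is.finite(time_a_cpu)) || any(time_a_cpu < 0) ||
      any(!is.finite(time_P_cpus)) || any(time_P_cpus < 0))
    stop_parameter("times must be non-negative")
  if (any(!is.finite(P)) || any(P < 1)) stop_parameter("P must be >= 1")
  time_P_cpus - time_a_cpu / P
}

#' Predict parallel run time from a reference overhead
#'
#' Constant-overhead extrapolation: `time_a_cpu / P + overhead_ref`. Used to
#' project run times on larger clusters from an overhead measured at a
#' reference processor count.
#'
#' @param time_a_cpu serial duration, >= 0.
#' @param overhead_ref reference overhead (from [overhead()]), >= 0.
#' @param P processor count(s), >= 1; vectorized.
#' @return predicted duration(s).
#' @export
predict_time <- function(time_a_cpu, overhead_ref, P) {
  if (any(!is.finite(time_a_cpu)) || any(time_a_cpu < 0) ||
      any(!is.finite(overhead_ref)) || any(overhead_ref < 0))
    stop_parameter("times must be non-negative")
  if (any(!is.finite(P)) || any(P < 1)) stop_parameter("P must be >= 1")
  time_a_cpu / P + overhead_ref
}

# Shared driver for type-1/2 (linear) statistics: partition the item axis,
# run the kernel per range under the engine, merge in range order.
run_linear_stat <- function(n_items, kernel, nprocs, executor, kind) {
  P <- max(1L, min(as.integer(nprocs), n_items))
  part <- partition_linear(n_items, P)
  tasks <- make_tasks(part, kind)
  worker <- function(task) kernel(task$block$start + 1L, task$block$stop)
  results <- run_tasks(tasks, worker, nprocs = nprocs, executor = executor)
  merge_linear(results, part)
}

# Shared driver for type-3/4 (pairwise) statistics.
run_pairwise_stat <- function(n_items, ids, kernel, statistic, nprocs,
                              executor, side_max = 7000L,
                              exploit_symmetry = FALSE) {
  depth <- pairwise_depth(n_items, max(1L, as.integer(nprocs)),
                          side_max = side_max)
  # a tiny item count caps the feasible depth (every block side nonempty)
  depth <- max(1L, min(depth, as.integer(floor(log2(n_items)))))
  plan <- partition_pairwise(n_items, depth)
  blocks <- plan$blocks
  keep <- if (exploit_symmetry)
    which(!vapply(blocks, block_below_diagonal, logical(1)))
  else seq_along(blocks)
  tasks <- lapply(keep, function(i)
    list(task_id = i - 1L, block = blocks[[i]], kind = statistic))
  worker <- function(task) {
    b <- task$block
    kernel((b$rows$start + 1L):b$rows$stop, (b$cols$start + 1L):b$cols$stop)
  }
  results <- run_tasks(tasks, worker, nprocs = nprocs, executor = executor)
  merge_pairwise(results, plan, ids = ids, statistic = statistic,
                 mirror = exploit_symmetry)
}
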