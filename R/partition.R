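# Data-partitioning algorithms for the four computation types.
#
# Per-SNP and per-individual statistics (types 1-2) use linear partitioning:
# M items over P processors in contiguous chunks of floor(M/P), with the
# integer-division remainder attached to the last chunk (801 items over 4
# processors -> 200/200/200/201). Pairwise statistics (types 3-4) use a
# recursive decomposition of the n-by-n grid into 4^depth near-equal-area
# blocks: the grid is quartered into two diagonal and two off-diagonal
# quadrants; at each further level diagonal blocks are quartered again while
# off-diagonal blocks are cut into four near-equal strips.

index_range <- function(start, stop) {
  if (!(start >= 0L && stop > start)) stop_parameter("invalid index range")
  list(start = as.integer(start), stop = as.integer(stop))
}

range_size <- function(r) r$stop - r$start

#' Linear partition of M items over P processors
#'
#' Contiguous chunks of `floor(M/P)` items; the last chunk absorbs the
#' remainder from integer division, so e.g. 801 items over 4 processors give
#' chunk sizes 200, 200, 200, 201.
#'
#' @param M item count (SNPs or individuals), >= 1.
#' @param P number of subsets/processors, `1 <= P <= M`.
#' @return object of class `linear_partition`: list with `M`, `P`, `ranges`
#'   (half-open 0-based `[start, stop)` ranges) and `sizes`.
#' @export
partition_linear <- function(M, P) {
  if (!is_count(M, 1L) || !is_count(P, 1L))
    stop_parameter("M and P must be counts >= 1")
  if (P > M)
    stop_parameter(sprintf("P (%d) exceeds M (%d): cannot give every processor work",
                           as.integer(P), as.integer(M)))
  M <- as.integer(M); P <- as.integer(P)
  base <- M %/% P
  sizes <- rep(base, P)
  sizes[P] <- M - (P - 1L) * base
  stops <- cumsum(sizes)
  starts <- c(0L, stops[-P])
  ranges <- Map(index_range, starts, stops)
  structure(list(M = M, P = P, ranges = ranges, sizes = as.integer(sizes)),
            class = "linear_partition")
}

#' @method print linear_partition
#' @export
print.linear_partition <- function(x, ...) {
  cat(sprintf("linear_partition: %d items over %d subsets; sizes: %s\n",
              x$M, x$P, paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Recursion depth for pairwise partitioning
#'
#' Chooses the smallest depth `d` such that (a) every block side fits the
#' per-processor memory budget, `ceil(n / 2^d) <= side_max`, and (b) there
#' are at least as many subsets as processors, `4^d >= P`; the depth never
#' drops below 1 (at least 4 subsets). With the default `side_max = 7000`
#' this reproduces the SNP-count rule: chromosomes of up to 14,000 SNPs give
#' 4 subsets, 14,001-28,000 give 16, and 28,001-56,000 give 64.
#'
#' @param n item count (individuals or SNPs), >= 2.
#' @param P number of processors, >= 1.
#' @param side_max largest admissible block side (memory budget), >= 2.
#' @return integer depth `d >= 1`; the plan will have `4^d` blocks.
#' @export
pairwise_depth <- function(n, P, side_max = 7000L) {
  if (!is_count(n, 2L)) stop_parameter("n must be a count >= 2")
  if (!is_count(P, 1L)) stop_parameter("P must be a count >= 1")
  if (!is_count(side_max, 2L)) stop_parameter("side_max must be a count >= 2")
  d_mem <- 1L
  while (ceiling(n / 2^d_mem) > side_max) d_mem <- d_mem + 1L
  d_proc <- 1L
  while (4^d_proc < P) d_proc <- d_proc + 1L
  max(1L, d_mem, d_proc)
}

halve <- function(r) {
  mid <- r$start + (range_size(r) %/% 2L)
  list(index_range(r$start, mid), index_range(mid, r$stop))
}

# Split a range into 4 contiguous near-equal pieces; sizes differ by at most
# one, extra items going to the last pieces.
split4 <- function(r) {
  m <- range_size(r)
  base <- m %/% 4L; extra <- m %% 4L
  sizes <- rep(base, 4L) + c(rep(0L, 4L - extra), rep(1L, extra))
  if (any(sizes == 0L)) stop_parameter("range too small to split into 4")
  stops <- r$start + cumsum(sizes)
  starts <- c(r$start, stops[-4L])
  Map(index_range, starts, stops)
}

pair_block <- function(rows, cols, kind, lineage) {
  list(rows = rows, cols = cols, kind = kind, lineage = as.integer(lineage))
}

quarter_diagonal <- function(block) {
  h <- halve(block$rows)
  list(pair_block(h[[1L]], h[[1L]], "diagonal", c(block$lineage, 1L)),
       pair_block(h[[1L]], h[[2L]], "offdiag",  c(block$lineage, 2L)),
       pair_block(h[[2L]], h[[1L]], "offdiag",  c(block$lineage, 3L)),
       pair_block(h[[2L]], h[[2L]], "diagonal", c(block$lineage, 4L)))
}

strip_offdiag <- function(block) {
  r <- range_size(block$rows); c <- range_size(block$cols)
  if (r >= 4L) {
    parts <- split4(block$rows)
    lapply(1:4, function(i)
      pair_block(parts[[i]], block$cols, "offdiag", c(block$lineage, i)))
  } else if (c >= 4L) {
    parts <- split4(block$cols)
    lapply(1:4, function(i)
      pair_block(block$rows, parts[[i]], "offdiag", c(block$lineage, i)))
  } else if (r >= 2L && c >= 2L) {
    hr <- halve(block$rows); hc <- halve(block$cols)
    lapply(1:4, function(i) {
      ri <- hr[[(i - 1L) %/% 2L + 1L]]; ci <- hc[[(i - 1L) %% 2L + 1L]]
      pair_block(ri, ci, "offdiag", c(block$lineage, i))
    })
  } else {
    stop_parameter("off-diagonal block too small to split into 4")
  }
}

#' Recursive pairwise partitioning of the n-by-n grid
#'
#' Level 1 splits `[0, n)` into two halves (remainder to the second half)
#' and forms four quadrants: two diagonal (top-left, bottom-right) and two
#' off-diagonal. At each further level every diagonal block is quartered
#' into its own four quadrants, and every off-diagonal block is cut into
#' four contiguous near-equal strips. The result is `4^depth` blocks that
#' tile the grid exactly with near-equal areas.
#'
#' @param n item count (individuals or SNPs), `n >= 2^depth`.
#' @param depth recursion depth `d >= 1`; see [pairwise_depth()].
#' @return object of class `pairwise_plan`: list with `n`, `depth` and
#'   `blocks`, each block holding `rows`/`cols` half-open ranges, a `kind`
#'   (`"diagonal"` or `"offdiag"`) and its quadrant `lineage` from the root.
#' @export
partition_pairwise <- function(n, depth) {
  if (!is_count(n, 2L)) stop_parameter("n must be a count >= 2")
  if (!is_count(depth, 1L)) stop_parameter("depth must be a count >= 1")
  if (n < 2^depth)
    stop_parameter(sprintf("n (%d) must be at least 2^depth (%d)",
                           as.integer(n), as.integer(2^depth)))
  root <- pair_block(index_range(0L, n), index_range(0L, n), "diagonal",
                     integer(0))
  blocks <- quarter_diagonal(root)
  d <- 1L
  while (d < depth) {
    blocks <- unlist(lapply(blocks, function(b) {
      if (b$kind == "diagonal") quarter_diagonal(b) else strip_offdiag(b)
    }), recursive = FALSE)
    d <- d + 1L
  }
  structure(list(n = as.integer(n), depth = as.integer(depth),
                 blocks = blocks),
            class = "pairwise_plan")
}

#' @method print pairwise_plan
#' @export
print.pairwise_plan <- function(x, ...) {
  cat(sprintf("pairwise_plan: %d x %d grid, depth %d, %d blocks\n",
              x$n, x$n, x$depth, length(x$blocks)))
  invisible(x)
}

#' Tabulate a pairwise plan
#'
#' One row per block: lineage path, kind, row/col extents and cell count.
#'
#' @param plan a [partition_pairwise()] result.
#' @return data frame.
#' @export
plan_table <- function(plan) {
  stopifnot(inherits(plan, "pairwise_plan"))
  do.call(rbind, lapply(seq_along(plan$blocks), function(i) {
    b <- plan$blocks[[i]]
    data.frame(block = i - 1L,
               lineage = paste(b$lineage, collapse = "."),
               kind = b$kind,
               row_start = b$rows$start, row_stop = b$rows$stop,
               col_start = b$cols$start, col_stop = b$cols$stop,
               cells = range_size(b$rows) * range_size(b$cols),
               stringsAsFactors = FALSE)
  }))
}
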