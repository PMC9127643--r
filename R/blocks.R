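# Item-block balancing for the figure test. Items are ranked by pilot
# median latency; each consecutive rank group of n_blocks items is randomly
# spread across the blocks (one item per block per group), and the
# randomization is repeated many times, keeping the draw whose blocks are
# most similar in median and IQR.

block_objective <- function(item_median, item_iqr, block_id, n_blocks) {
  block_meds <- vapply(seq_len(n_blocks), function(b)
    stats::median(item_median[block_id == b]), numeric(1))
  block_iqrs <- vapply(seq_len(n_blocks), function(b)
    stats::IQR(item_median[block_id == b]), numeric(1))
  term <- function(v, g) {
    if (v <= .Machine$double.eps) return(0)
    if (g <= .Machine$double.eps) return(Inf)
    v / g
  }
  term(stats::var(block_meds), stats::var(item_median)) +
    term(stats::var(block_iqrs), stats::var(item_iqr))
}

#' Design balanced item blocks
#'
#' Implements the stratified block randomization used to remove order
#' effects from the figure test: items are ranked by their pilot median
#' response time; the `n_blocks` items with the lowest medians are randomly
#' assigned one per block, and so on for each following rank group. The
#' randomization is repeated `n_iter` times and the assignment whose blocks
#' have the most similar median and IQR is kept.
#'
#' The balance objective is the across-block variance of the per-block
#' median of item medians plus the across-block variance of the per-block
#' IQR of item medians, each standardized by the corresponding across-item
#' variance. Ties are broken by the lowest iteration index; the search is
#' reproducible from `seed`.
#'
#' @param items data frame with columns `item_id`, `median_rt`, `iqr_rt`
#'   (see [generate_item_bank()]).
#' @param n_blocks number of blocks; must divide the item count.
#' @param n_iter number of random assignments to draw (default 500).
#' @param seed integer seed for the randomization.
#' @param keep_iterations also return every sampled assignment and its
#'   objective (used for auditing the search).
#' @return List of class `block_assignment`: `assignment` (data frame
#'   `item_id`, `block_id`, `rank_group`), `objective_value`,
#'   `chosen_iteration`, `n_iter` and, if requested, `iterations`.
#' @examples
#' bank <- generate_item_bank(sim_config(n_respondents = 10, seed = 3),
#'                            n_pilot = 50)
#' design_item_blocks(bank, seed = 1)$objective_value
#' @export
design_item_blocks <- function(items, n_blocks = 6L, n_iter = 500L,
                               seed = 1L, keep_iterations = FALSE) {
  if (!is.data.frame(items) ||
      !all(c("item_id", "median_rt", "iqr_rt") %in% names(items)))
    sc_config_error("items must carry item_id, median_rt, iqr_rt")
  n <- nrow(items)
  if (!is_count(n_blocks) || n %% n_blocks != 0L)
    sc_config_error("item count must be divisible by n_blocks")
  if (!is_count(n_iter)) sc_config_error("n_iter must be a positive integer")
  if (any(items$median_rt <= 0) || any(items$iqr_rt < 0))
    sc_config_error("item stats must have median_rt > 0 and iqr_rt >= 0")

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  ord <- order(items$median_rt, items$item_id)   # ascending; ties by item_id
  n_groups <- n %/% n_blocks
  rank_group <- rep(seq_len(n_groups), each = n_blocks)

  best <- NULL
  iterations <- if (keep_iterations) vector("list", n_iter) else NULL
  for (it in seq_len(n_iter)) {
    block_id <- integer(n)
    for (g in seq_len(n_groups))
      block_id[ord[rank_group == g]] <- sample.int(n_blocks)
    obj <- block_objective(items$median_rt, items$iqr_rt, block_id, n_blocks)
    if (keep_iterations)
      iterations[[it]] <- list(block_id = block_id, objective = obj)
    if (is.null(best) || obj < best$objective) {
      best <- list(block_id = block_id, objective = obj, iteration = it)
    }
  }
  assignment <- data.frame(item_id = items$item_id, block_id = best$block_id,
                           rank_group = rank_group[order(ord)])
  structure(list(assignment = assignment,
                 objective_value = best$objective,
                 chosen_iteration = best$iteration,
                 n_iter = n_iter, n_blocks = as.integer(n_blocks),
                 iterations = iterations),
            class = "block_assignment")
}

#' @export
print.block_assignment <- function(x, ...) {
  cat("Balanced item-block assignment:", nrow(x$assignment), "items in",
      x$n_blocks, "blocks\n")
  cat(sprintf("  objective %.6g at iteration %d of %d\n",
              x$objective_value, x$chosen_iteration, x$n_iter))
  invisible(x)
}
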