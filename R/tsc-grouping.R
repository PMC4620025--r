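#' Build a topographic grouping matrix
#'
#' Dictionary atoms are arranged on a `grid_rows` x `grid_cols` grid
#' (row-major: atom `j` sits at row `(j - 1) %/% grid_cols + 1`, column
#' `(j - 1) %% grid_cols + 1`). One group is anchored at every grid position
#' and covers the `group_size` x `group_size` window extending down and to
#' the right of its anchor; with `wraparound = TRUE` the grid is a torus, so
#' there are exactly `k = grid_rows * grid_cols` groups and every atom
#' belongs to exactly `group_size^2` of them. Without wraparound only anchors
#' whose window fits inside the grid produce a group.
#'
#' The returned object is the binary group-membership matrix `V` (groups in
#' rows, atoms in columns) that drives the grouped sparsity penalty: nearby
#' atoms share groups, so penalizing group magnitudes couples neighbouring
#' atoms and makes them learn similar features.
#'
#' @param grid_rows,grid_cols Atom-grid dimensions; their product is the
#'   number of dictionary atoms `k`.
#' @param group_size Side length of the square group window (default 3, i.e.
#'   9-member groups).
#' @param wraparound Treat the grid as a torus (default `TRUE`).
#' @return A binary matrix of class `topo_grouping` with attributes
#'   `grid_rows`, `grid_cols`, `group_size`, `wraparound`.
#' @examples
#' V <- build_grouping_matrix(3, 3, group_size = 3)
#' rowSums(V) # every group has 9 members
#' @export
build_grouping_matrix <- function(grid_rows, grid_cols, group_size = 3,
                                  wraparound = TRUE) {
  grid_rows <- stopifnot_scalar_count(grid_rows, "grid_rows")
  grid_cols <- stopifnot_scalar_count(grid_cols, "grid_cols")
  group_size <- stopifnot_scalar_count(group_size, "group_size")
  if (group_size > min(grid_rows, grid_cols)) {
    abort("`group_size` must not exceed either grid dimension")
  }
  k <- grid_rows * grid_cols
  atom_at <- function(r, c) (r - 1L) * grid_cols + c  # row-major atom index

  anchors_r <- if (wraparound) seq_len(grid_rows) else seq_len(grid_rows - group_size + 1L)
  anchors_c <- if (wraparound) seq_len(grid_cols) else seq_len(grid_cols - group_size + 1L)
  G <- length(anchors_r) * length(anchors_c)
  V <- matrix(0L, nrow = G, ncol = k)
  g <- 0L
  for (ar in anchors_r) {
    for (ac in anchors_c) {
      g <- g + 1L
      rr <- ar + seq_len(group_size) - 1L
      cc <- ac + seq_len(group_size) - 1L
      if (wraparound) {
        rr <- (rr - 1L) %% grid_rows + 1L
        cc <- (cc - 1L) %% grid_cols + 1L
      }
      V[g, as.vector(outer(rr, cc, atom_at))] <- 1L
    }
  }
  structure(V, class = c("topo_grouping", "matrix"),
            grid_rows = grid_rows, grid_cols = grid_cols,
            group_size = group_size, wraparound = wraparound)
}
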