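# Elastic fine alignment. Grid block matching between the z-mean images of
# two volumes produces, per block, a small set of candidate matched
# centroids. Mismatches (texture-less blocks, repeated structures) are
# corrected by minimising a truncated-quadratic neighbour-consistency
# energy over the candidate sets:
#
#   min_p sum_{(i,j) in E} min( || p_j - p_i - d_ij ||^2, C )
#
# where p_i is the selected matched centroid of block i and d_ij is the
# preset offset between neighbouring block centres (so mutually consistent
# matches cost zero). The surviving matches drive a thin-plate-spline
# deformation field applied to the whole volume.

#' z-mean projection of a volume
#' @param vol an `image_stack`
#' @return numeric matrix `[y, x]`
#' @export
mean_image <- function(vol) {
  stopifnot(inherits(vol, "image_stack"))
  d <- dim(vol$data)
  matrix(colMeans(matrix(vol$data, d[1], d[2] * d[3])), d[2], d[3])
}

#' Grid block matching with top-k NCC candidates
#'
#' Divides `ref` into a grid of blocks and searches each one in `mov`
#' within `search_px`, keeping the `k_candidates` strongest local NCC
#' peaks so that repeated textures remain multi-modal for the consistency
#' solver. Zero-variance (texture-less) blocks are flagged and carry no
#' candidates.
#'
#' @param ref,mov numeric matrices of identical shape
#' @param block_px block side in pixels
#' @param stride_px grid stride in pixels
#' @param search_px search radius in pixels
#' @param k_candidates candidates kept per node
#' @return a `match_graph`: list with `nodes` (data.frame: `ix`, `iy`,
#'   `cx`, `cy`, `textureless`, `active`), `candidates` (per node,
#'   data.frame `px`, `py`, `score`), grid dims `n_gx`, `n_gy`
#' @export
block_match <- function(ref, mov, block_px = 128, stride_px = 128,
                        search_px = 32, k_candidates = 3) {
  stopifnot(all(dim(ref) == dim(mov)), block_px <= min(dim(ref)),
            search_px >= 1)
  half <- block_px %/% 2
  cxs <- seq(half, ncol(ref) - 1 - (block_px - half - 1), by = stride_px)
  cys <- seq(half, nrow(ref) - 1 - (block_px - half - 1), by = stride_px)
  n_gx <- length(cxs); n_gy <- length(cys)
  nodes <- expand.grid(iy = seq_len(n_gy), ix = seq_len(n_gx))
  nodes$cx <- cxs[nodes$ix]
  nodes$cy <- cys[nodes$iy]
  nodes$textureless <- FALSE
  nodes$active <- TRUE
  candidates <- vector("list", nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    surf <- .ncc_surface(ref, mov, nodes$cx[i], nodes$cy[i], block_px,
                         search_px)
    if (isTRUE(attr(surf, "textureless")) || all(is.na(surf))) {
      nodes$textureless[i] <- TRUE
      candidates[[i]] <- data.frame(px = numeric(0), py = numeric(0),
                                    score = numeric(0))
      next
    }
    cand <- top_ncc_peaks(surf, search_px, k_candidates)
    candidates[[i]] <- data.frame(
      px = nodes$cx[i] + cand$dx,
      py = nodes$cy[i] + cand$dy,
      score = cand$score
    )
  }
  match_graph(nodes, candidates, n_gx, n_gy, block_px, search_px)
}

#' Construct a match graph directly
#'
#' Used by [block_match()] and by tests that need hand-built instances.
#' Nodes live on an `n_gy` x `n_gx` grid; edges connect 4-neighbours.
#' @param nodes data.frame with `ix`, `iy`, `cx`, `cy` and optional
#'   `textureless`, `active`
#' @param candidates list (per node) of data.frames `px`, `py`, `score`
#' @param n_gx,n_gy grid extents
#' @param block_px,stride_px bookkeeping fields
#' @return a `match_graph`
#' @export
match_graph <- function(nodes, candidates, n_gx, n_gy, block_px = NA,
                        stride_px = NA) {
  if (is.null(nodes$textureless)) nodes$textureless <- FALSE
  if (is.null(nodes$active)) nodes$active <- TRUE
  stopifnot(nrow(nodes) == n_gx * n_gy, length(candidates) == nrow(nodes))
  structure(
    list(nodes = nodes, candidates = candidates, n_gx = n_gx, n_gy = n_gy,
         block_px = block_px, stride_px = stride_px),
    class = "match_graph"
  )
}

# Local maxima of an NCC surface, strongest first, lexicographic tie-break.
top_ncc_peaks <- function(surf, search_px, k) {
  side <- nrow(surf)
  s <- surf
  s[is.na(s)] <- -Inf
  is_peak <- matrix(TRUE, side, side)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    shifted <- matrix(-Inf, side, side)
    ys <- max(1, 1 + dy):min(side, side + dy)
    xs <- max(1, 1 + dx):min(side, side + dx)
    shifted[ys, xs] <- s[ys - dy, xs - dx]
    is_peak <- is_peak & (s >= shifted)
  }
  is_peak <- is_peak & is.finite(s)
  idx <- which(is_peak, arr.ind = TRUE)
  if (nrow(idx) == 0) idx <- which(s == max(s), arr.ind = TRUE)
  vals <- s[idx]
  ord <- order(-vals, idx[, 1], idx[, 2])
  take <- head(ord, k)
  list(
    dy = idx[take, 1] - 1 - search_px,
    dx = idx[take, 2] - 1 - search_px,
    score = vals[take]
  )
}

node_index <- function(graph, ix, iy) (ix - 1) * graph$n_gy + iy

# Canonical (right/down) edges between active nodes.
graph_edges <- function(graph) {
  nodes <- graph$nodes
  active <- nodes$active
  edges <- list()
  for (i in seq_len(nrow(nodes))) {
    if (!active[i]) next
    ix <- nodes$ix[i]; iy <- nodes$iy[i]
    if (ix < graph$n_gx) {
      j <- node_index(graph, ix + 1, iy)
      if (active[j]) edges[[length(edges) + 1]] <- c(i, j)
    }
    if (iy < graph$n_gy) {
      j <- node_index(graph, ix, iy + 1)
      if (active[j]) edges[[length(edges) + 1]] <- c(i, j)
    }
  }
  if (length(edges) == 0) matrix(integer(0), ncol = 2)
  else do.call(rbind, edges)
}

edge_cost_matrix <- function(graph, i, j, C) {
  ci <- graph$candidates[[i]]
  cj <- graph$candidates[[j]]
  dx <- graph$nodes$cx[j] - graph$nodes$cx[i]
  dy <- graph$nodes$cy[j] - graph$nodes$cy[i]
  ddx <- outer(ci$px, cj$px, function(a, b) b - a) - dx
  ddy <- outer(ci$py, cj$py, function(a, b) b - a) - dy
  pmin(ddx^2 + ddy^2, C)
}

#' Energy of a candidate assignment
#' @param graph `match_graph`
#' @param assign integer candidate index per node (NA for inactive nodes)
#' @param C truncation threshold (squared pixels)
#' @return scalar objective value
#' @export
match_objective <- function(graph, assign, C) {
  edges <- graph_edges(graph)
  total <- 0
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    m <- edge_cost_matrix(graph, i, j, C)
    total <- total + m[assign[i], assign[j]]
  }
  total
}

# Exact minimisation by transfer-matrix dynamic programming over grid
# columns; feasible when k^rows is small. Inactive nodes act as a single
# zero-cost dummy state. Returns the assignment or NULL when infeasible.
dp_grid_solve <- function(graph, C, unary, state_limit = 256) {
  n_gx <- graph$n_gx; n_gy <- graph$n_gy
  active <- graph$nodes$active
  k <- ifelse(active, vapply(graph$candidates, nrow, integer(1)), 1L)
  transpose <- n_gx < n_gy # DP runs along the longer axis
  rows <- if (transpose) n_gx else n_gy
  cols <- if (transpose) n_gy else n_gx
  if (prod(rep(max(k), rows)) > state_limit) {
    # tighter per-column bound
    feasible <- all(vapply(seq_len(cols), function(col) {
      prod(vapply(seq_len(rows), function(r) {
        k[if (transpose) node_index(graph, r, col) else node_index(graph, col, r)]
      }, integer(1))) <= state_limit
    }, logical(1)))
    if (!feasible) return(NULL)
  }
  node_at <- function(col, row) {
    if (transpose) node_index(graph, row, col) else node_index(graph, col, row)
  }
  ecost <- function(i, j) {
    if (!active[i] || !active[j]) {
      matrix(0, k[i], k[j])
    } else {
      edge_cost_matrix(graph, i, j, C)
    }
  }
  ucost <- function(i, a) if (active[i]) unary[i, a] else rep(0, length(a))
  col_states <- function(col) {
    ks <- vapply(seq_len(rows), function(r) k[node_at(col, r)], integer(1))
    as.matrix(expand.grid(lapply(ks, seq_len)))
  }
  col_cost <- function(col, states) {
    cost <- ucost(node_at(col, 1), states[, 1])
    if (rows > 1) {
      for (r in 2:rows) {
        cost <- cost + ucost(node_at(col, r), states[, r])
        m <- ecost(node_at(col, r - 1), node_at(col, r))
        cost <- cost + m[cbind(states[, r - 1], states[, r])]
      }
    }
    cost
  }
  states_prev <- col_states(1)
  best <- col_cost(1, states_prev)
  back <- vector("list", cols)
  if (cols > 1) {
    for (col in 2:cols) {
      states_cur <- col_states(col)
      trans <- matrix(0, nrow(states_prev), nrow(states_cur))
      for (r in seq_len(rows)) {
        m <- ecost(node_at(col - 1, r), node_at(col, r))
        trans <- trans + m[states_prev[, r], states_cur[, r], drop = FALSE]
      }
      tmp <- trans + best # prev-state cost recycles down columns
      arg <- max.col(-t(tmp), ties.method = "first")
      best <- tmp[cbind(arg, seq_len(nrow(states_cur)))] +
        col_cost(col, states_cur)
      back[[col]] <- list(arg = arg, states = states_cur)
      states_prev <- states_cur
    }
  }
  assign <- rep(NA_integer_, n_gx * n_gy)
  s_idx <- which.min(best)
  for (col in cols:1) {
    states <- if (col == 1) col_states(1) else back[[col]]$states
    for (r in seq_len(rows)) assign[node_at(col, r)] <- states[s_idx, r]
    if (col > 1) s_idx <- back[[col]]$arg[s_idx]
  }
  assign[!active] <- NA_integer_
  assign
}

# Synchronous min-sum belief propagation plus ICM polish over the active
# subgraph. Tracks the best decoded assignment so the reported objective
# trajectory is monotone.
bp_grid_solve <- function(graph, C, unary, max_iter) {
  edges <- graph_edges(graph)
  n <- nrow(graph$nodes)
  active <- which(graph$nodes$active)
  k <- vapply(graph$candidates, nrow, integer(1))
  dir <- rbind(edges, edges[, 2:1, drop = FALSE])
  nd <- nrow(dir)
  cost <- lapply(seq_len(nd), function(e) {
    edge_cost_matrix(graph, dir[e, 1], dir[e, 2], C)
  })
  in_edges <- lapply(seq_len(n), function(i) which(dir[, 2] == i))
  out_edges <- lapply(seq_len(n), function(i) which(dir[, 1] == i))
  msg <- lapply(seq_len(nd), function(e) numeric(k[dir[e, 2]]))
  decode <- function() {
    assign <- rep(NA_integer_, n)
    for (i in active) {
      b <- unary[i, seq_len(k[i])]
      for (e in in_edges[[i]]) b <- b + msg[[e]]
      sc <- graph$candidates[[i]]$score
      assign[i] <- order(b, -sc, seq_len(k[i]))[1]
    }
    assign
  }
  best_assign <- decode()
  best_obj <- match_objective(graph, best_assign, C)
  trajectory <- best_obj
  prev_assign <- best_assign
  for (it in seq_len(max_iter)) {
    new_msg <- msg
    for (e in seq_len(nd)) {
      i <- dir[e, 1]; j <- dir[e, 2]
      b <- unary[i, seq_len(k[i])]
      for (ein in in_edges[[i]]) {
        if (dir[ein, 1] == j) next # exclude the reverse edge
        b <- b + msg[[ein]]
      }
      m <- apply(cost[[e]] + b, 2, min)
      new_msg[[e]] <- m - min(m) # normalise for stability
    }
    msg <- new_msg
    assign <- decode()
    obj <- match_objective(graph, assign, C)
    if (obj < best_obj) {
      best_obj <- obj
      best_assign <- assign
    }
    trajectory <- c(trajectory, best_obj)
    if (identical(assign, prev_assign)) break
    prev_assign <- assign
  }
  assign <- best_assign
  repeat { # ICM polish: coordinate descent until stable
    changed <- FALSE
    for (i in active) {
      costs <- unary[i, seq_len(k[i])]
      for (e in c(out_edges[[i]])) {
        j <- dir[e, 2]
        costs <- costs + cost[[e]][, assign[j]]
      }
      sc <- graph$candidates[[i]]$score
      pick <- order(costs, -sc, seq_len(k[i]))[1]
      if (pick != assign[i]) {
        assign[i] <- pick
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  obj <- match_objective(graph, assign, C)
  if (obj < best_obj) {
    best_obj <- obj
    best_assign <- assign
    trajectory <- c(trajectory, best_obj)
  }
  list(assign = best_assign, objective = best_obj, trajectory = trajectory)
}

#' Select one matched centroid per block by neighbour consistency
#'
#' Minimises the truncated-quadratic consistency energy over each node's
#' candidate set. Small grids are solved exactly by dynamic programming
#' over grid columns; larger ones by synchronous min-sum belief
#' propagation with a coordinate-descent polish. With `C = 0` every
#' pairwise term truncates to zero and ties break towards the highest
#' match score (then lowest candidate index). Deterministic throughout.
#'
#' @param graph a `match_graph`; texture-less nodes should be deactivated
#'   first (see [prune_match_graph()])
#' @param C truncation threshold in squared pixels
#' @param max_iter BP iteration cap
#' @param score_weight optional unary weight `-score_weight * score`
#'   (default 0: the energy is exactly the pairwise objective)
#' @param method `"auto"`, `"exact"` or `"bp"`
#' @return list: `selected` (data.frame `px`, `py`, NA rows for inactive
#'   nodes), `assign`, `objective`, `trajectory` (monotone best-so-far
#'   objective values; degenerate length 1 for the exact path)
#' @export
bp_refine <- function(graph, C = 64, max_iter = 50, score_weight = 0,
                      method = c("auto", "exact", "bp")) {
  method <- match.arg(method)
  stopifnot(C >= 0)
  k <- vapply(graph$candidates, nrow, integer(1))
  bad <- which(graph$nodes$active & k == 0)
  if (length(bad) > 0) {
    stop("bp_refine: nodes with empty candidate lists: ",
         paste(bad, collapse = ", "))
  }
  n <- nrow(graph$nodes)
  unary <- matrix(Inf, n, max(c(k, 1)))
  for (i in which(graph$nodes$active)) {
    unary[i, seq_len(k[i])] <- -score_weight * graph$candidates[[i]]$score
  }
  assign <- NULL
  trajectory <- NULL
  if (method %in% c("auto", "exact")) {
    assign <- dp_grid_solve(graph, C, unary)
    if (is.null(assign) && method == "exact") {
      stop("bp_refine: exact solve infeasible for this grid size")
    }
  }
  if (is.null(assign)) {
    r <- bp_grid_solve(graph, C, unary, max_iter)
    assign <- r$assign
    trajectory <- r$trajectory
  }
  if (C == 0 && score_weight == 0) {
    # all assignments cost 0: documented tie-break by score then index
    for (i in which(graph$nodes$active)) {
      sc <- graph$candidates[[i]]$score
      assign[i] <- order(-sc, seq_len(k[i]))[1]
    }
  }
  obj <- match_objective(graph, assign, C)
  sel <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (is.na(assign[i])) {
      data.frame(px = NA_real_, py = NA_real_)
    } else {
      graph$candidates[[i]][assign[i], c("px", "py")]
    }
  }))
  rownames(sel) <- NULL
  list(selected = sel, assign = assign, objective = obj,
       trajectory = if (is.null(trajectory)) obj else trajectory)
}

#' Deactivate texture-less nodes of a match graph
#'
#' Zero-variance blocks carry no evidence; they are removed from the
#' energy and contribute no TPS control point.
#' @param graph a `match_graph`
#' @return the graph with those nodes deactivated
#' @export
prune_match_graph <- function(graph) {
  k <- vapply(graph$candidates, nrow, integer(1))
  graph$nodes$active <- graph$nodes$active & !graph$nodes$textureless & k > 0
  graph
}
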