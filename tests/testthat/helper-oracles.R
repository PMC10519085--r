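# Independent oracle implementations used to cross-check the package:
# deliberately written with plain loops / direct formulas, not by calling
# the code paths they verify.

# z-concatenate 3D arrays
abind_z <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  total <- sum(vapply(parts, function(p) dim(p)[1], numeric(1)))
  out <- array(0, dim = c(total, d[2], d[3]))
  z <- 0
  for (p in parts) {
    out[z + seq_len(dim(p)[1]), , ] <- p
    z <- z + dim(p)[1]
  }
  out
}

# integer shift with zero fill
shift_img <- function(img, dx, dy) {
  out <- matrix(0, nrow(img), ncol(img))
  for (y in seq_len(nrow(img))) {
    for (x in seq_len(ncol(img))) {
      sy <- y - dy; sx <- x - dx
      if (sy >= 1 && sy <= nrow(img) && sx >= 1 && sx <= ncol(img)) {
        out[y, x] <- img[sy, sx]
      }
    }
  }
  out
}

# least squares affine via explicit normal equations
oracle_affine_fit <- function(src, dst) {
  x <- cbind(src, 1)
  beta <- solve(t(x) %*% x, t(x) %*% dst)
  rbind(t(beta), c(0, 0, 1))
}

# KKT solve of the gap-distribution QP: minimise x' Q x subject to A x = b
oracle_gap_qp <- function(c_intra, c_inter) {
  n <- length(c_intra)
  nv <- 2 * n # order: t1, b1, t2, b2, ...
  ti <- function(i) 2 * i - 1
  bi <- function(i) 2 * i
  Q <- matrix(0, nv, nv)
  add_term <- function(Q, i, j) { # (x_i - x_j)^2
    Q[i, i] <- Q[i, i] + 1; Q[j, j] <- Q[j, j] + 1
    Q[i, j] <- Q[i, j] - 1; Q[j, i] <- Q[j, i] - 1
    Q
  }
  for (i in seq_len(n)) Q <- add_term(Q, ti(i), bi(i))
  for (i in seq_len(n - 1)) Q <- add_term(Q, ti(i + 1), bi(i))
  A <- matrix(0, 2 * n - 1, nv)
  b <- numeric(2 * n - 1)
  for (i in seq_len(n)) {
    A[i, ti(i)] <- 1; A[i, bi(i)] <- 1; b[i] <- c_intra[i]
  }
  for (i in seq_len(n - 1)) {
    A[n + i, bi(i)] <- 1; A[n + i, ti(i + 1)] <- 1; b[n + i] <- c_inter[i]
  }
  kkt <- rbind(cbind(2 * Q, t(A)), cbind(A, matrix(0, nrow(A), nrow(A))))
  rhs <- c(numeric(nv), b)
  sol <- solve(kkt, rhs)[seq_len(nv)]
  list(top = sol[seq(1, nv, 2)], bot = sol[seq(2, nv, 2)])
}

# direct radial-basis TPS evaluation at arbitrary points
oracle_tps_eval <- function(src, disp, pts, lambda = 0) {
  n <- nrow(src)
  U <- function(r2) ifelse(r2 <= 0, 0, 0.5 * r2 * log(r2))
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    K[i, j] <- U(sum((src[i, ] - src[j, ])^2))
  }
  K <- K + diag(lambda, n)
  P <- cbind(1, src)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  coef <- solve(A, rbind(disp, matrix(0, 3, 2)))
  t(apply(pts, 1, function(p) {
    u <- vapply(1:n, function(i) U(sum((p - src[i, ])^2)), numeric(1))
    c(coef[n + 1, 1] + coef[n + 2, 1] * p[1] + coef[n + 3, 1] * p[2] +
        sum(u * coef[1:n, 1]),
      coef[n + 1, 2] + coef[n + 2, 2] * p[1] + coef[n + 3, 2] * p[2] +
        sum(u * coef[1:n, 2]))
  }))
}

# subpixel displacement of `mov` relative to `ref` by exhaustive interior
# NCC search plus parabolic refinement (independent of the package's
# matchers)
best_shift <- function(ref, mov, search = 8) {
  h <- nrow(ref); w <- ncol(ref)
  ys <- (search + 1):(h - search)
  xs <- (search + 1):(w - search)
  a <- ref[ys, xs]; a <- a - mean(a)
  score <- matrix(-Inf, 2 * search + 1, 2 * search + 1)
  for (dy in -search:search) for (dx in -search:search) {
    b <- mov[ys + dy, xs + dx]; b <- b - mean(b)
    score[dy + search + 1, dx + search + 1] <-
      sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }
  pk <- which(score == max(score), arr.ind = TRUE)[1, ]
  sub <- function(m, c, p) {
    den <- m - 2 * c + p
    if (!is.finite(den) || abs(den) < 1e-12) 0 else 0.5 * (m - p) / den
  }
  dy <- pk[1] - search - 1
  dx <- pk[2] - search - 1
  if (abs(dy) < search && abs(dx) < search) {
    dx <- dx + sub(score[pk[1], pk[2] - 1], score[pk[1], pk[2]],
                   score[pk[1], pk[2] + 1])
    dy <- dy + sub(score[pk[1] - 1, pk[2]], score[pk[1], pk[2]],
                   score[pk[1] + 1, pk[2]])
  }
  # NCC peak at (dy, dx) means mov content sits at ref content + (dx, dy)
  unname(c(dx, dy))
}

# exhaustive NCC over a search window for one block (0-based coords)
oracle_ncc_best <- function(ref, mov, cx, cy, block, search) {
  half <- block %/% 2
  rx <- (cx - half):(cx - half + block - 1) + 1
  ry <- (cy - half):(cy - half + block - 1) + 1
  rb <- ref[ry, rx]
  best <- c(NA, NA, -Inf)
  for (dy in -search:search) {
    for (dx in -search:search) {
      mx <- rx + dx; my <- ry + dy
      if (min(mx) < 1 || max(mx) > ncol(mov) || min(my) < 1 ||
            max(my) > nrow(mov)) next
      mb <- mov[my, mx]
      if (sd(as.vector(mb)) < 1e-9 || sd(as.vector(rb)) < 1e-9) next
      ncc <- cor(as.vector(rb), as.vector(mb))
      if (ncc > best[3]) best <- c(dx, dy, ncc)
    }
  }
  best
}

# exhaustive minimisation of the truncated-quadratic consistency energy;
# edge costs are computed directly from the definition and evaluated for
# every assignment by indexing
oracle_bp_minimum <- function(graph, C) {
  k <- vapply(graph$candidates, nrow, integer(1))
  combos <- as.matrix(expand.grid(lapply(k, seq_len)))
  objs <- numeric(nrow(combos))
  nodes <- graph$nodes
  for (i in seq_len(nrow(nodes))) {
    for (j in seq_len(nrow(nodes))) {
      same_col <- nodes$ix[j] == nodes$ix[i] && nodes$iy[j] == nodes$iy[i] + 1
      same_row <- nodes$iy[j] == nodes$iy[i] && nodes$ix[j] == nodes$ix[i] + 1
      if (!(same_col || same_row)) next
      ci <- graph$candidates[[i]]
      cj <- graph$candidates[[j]]
      dx <- nodes$cx[j] - nodes$cx[i]
      dy <- nodes$cy[j] - nodes$cy[i]
      cost <- matrix(0, k[i], k[j])
      for (a in seq_len(k[i])) for (b in seq_len(k[j])) {
        cost[a, b] <- min((cj$px[b] - ci$px[a] - dx)^2 +
                            (cj$py[b] - ci$py[a] - dy)^2, C)
      }
      objs <- objs + cost[cbind(combos[, i], combos[, j])]
    }
  }
  min(objs)
}

# one repeated-texture trial for the consistency-vs-raw-NCC comparison: a
# periodic patch (16 px lattice) inside a distinctive texture, independent
# acquisition noise on both images, known global shift. Returns the mean
# displacement error over interior grid nodes for the raw best-NCC pick
# and for the consistency-refined pick.
decoy_trial <- function(trial, shift = c(2, 1), noise = 0.02) {
  ph <- make_phantom(phantom_spec(c(1, 160, 160), "blobs", seed = 500 + trial))
  clean <- matrix(ph$data[1, , ], 160, 160)
  per <- outer(0:63, 0:63, function(y, x) {
    0.5 + 0.4 * ((y %/% 8 + x %/% 8) %% 2)
  })
  clean[49:112, 49:112] <- per
  set.seed(trial)
  img <- clean + matrix(rnorm(160^2, 0, noise), 160)
  mov <- shift_img(clean, shift[1], shift[2]) +
    matrix(rnorm(160^2, 0, noise), 160)
  g <- prune_match_graph(block_match(img, mov, block_px = 32, stride_px = 32,
                                     search_px = 20, k_candidates = 16))
  interior <- which(g$nodes$active & g$nodes$ix > 1 &
                      g$nodes$ix < max(g$nodes$ix) &
                      g$nodes$iy > 1 & g$nodes$iy < max(g$nodes$iy))
  raw_err <- mean(vapply(interior, function(i) {
    cc <- g$candidates[[i]]
    sqrt((cc$px[1] - g$nodes$cx[i] - shift[1])^2 +
           (cc$py[1] - g$nodes$cy[i] - shift[2])^2)
  }, numeric(1)))
  r <- bp_refine(g, C = 64, method = "bp")
  bp_err <- mean(vapply(interior, function(i) {
    sqrt((r$selected$px[i] - g$nodes$cx[i] - shift[1])^2 +
           (r$selected$py[i] - g$nodes$cy[i] - shift[2])^2)
  }, numeric(1)))
  c(raw = raw_err, bp = bp_err)
}

# random small match graph on an n_gx x n_gy grid
random_match_graph <- function(n_gx, n_gy, k_max = 3, seed = 1,
                               spacing = 10, outlier_prob = 0.3) {
  set.seed(seed)
  nodes <- expand.grid(iy = seq_len(n_gy), ix = seq_len(n_gx))
  nodes$cx <- (nodes$ix - 1) * spacing
  nodes$cy <- (nodes$iy - 1) * spacing
  cands <- lapply(seq_len(nrow(nodes)), function(i) {
    k <- sample.int(k_max, 1)
    data.frame(
      px = nodes$cx[i] + ifelse(runif(k) < outlier_prob,
                                runif(k, -3, 3) * spacing, rnorm(k, 0, 1)),
      py = nodes$cy[i] + ifelse(runif(k) < outlier_prob,
                                runif(k, -3, 3) * spacing, rnorm(k, 0, 1)),
      score = runif(k)
    )
  })
  match_graph(nodes, cands, n_gx, n_gy)
}
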