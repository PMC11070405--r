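# Independent oracles: brute-force recomputations that never share code with
# the implementation paths they check.

# spreadsheet-style agreement statistics from explicit sums (no lm/cor/t.test)
oracle_agreement <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  r <- sxy / sqrt(sxx * syy)
  vx <- sxx / (n - 1)
  vy <- syy / (n - 1)
  ccc <- 2 * (sxy / (n - 1)) / (vx + vy + (mx - my)^2)
  d <- x - y
  md <- sum(d) / n
  sdd <- sqrt(sum((d - md)^2) / (n - 1))
  tstat <- md / (sdd / sqrt(n))
  pct <- abs(d) / ((x + y) / 2) * 100
  list(slope = slope,
       intercept = my - slope * mx,
       r = r,
       ccc = ccc,
       p_value = 2 * stats::pt(-abs(tstat), df = n - 1),
       rmse = sqrt(sum(d^2) / n),
       nrmse_pct = sqrt(sum(d^2) / n) / ((sum(x) + sum(y)) / (2 * n)) * 100,
       ba_mean = md,
       ba_lower = md - 1.96 * sdd,
       ba_upper = md + 1.96 * sdd,
       pct_mean = mean(pct),
       pct_sd = stats::sd(pct))
}

# ICC(2,1) via aov() mean squares, independent of the closed-form row/column
# sums used by the implementation
oracle_icc21 <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  df <- data.frame(value = as.vector(m),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(value ~ subject + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# geodesic distances over the 26-connected graph of a voxel mask via igraph
oracle_dijkstra <- function(mask, seeds_ijk, spacing) {
  dm <- dim(mask)
  idx <- which(mask)
  pos <- integer(length(mask))
  pos[idx] <- seq_along(idx)
  coord <- which(mask, arr.ind = TRUE)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  edges <- NULL
  weights <- NULL
  for (o in seq_len(nrow(offs))) {
    ni <- coord[, 1] + offs[o, 1]
    nj <- coord[, 2] + offs[o, 2]
    nk <- coord[, 3] + offs[o, 3]
    ok <- ni >= 1 & nj >= 1 & nk >= 1 & ni <= dm[1] & nj <= dm[2] & nk <= dm[3]
    lin <- ni[ok] + (nj[ok] - 1) * dm[1] + (nk[ok] - 1) * dm[1] * dm[2]
    ok2 <- mask[lin]
    from <- pos[idx[ok]][ok2]
    to <- pos[lin][ok2]
    keep <- from < to
    edges <- c(edges, rbind(from[keep], to[keep]))
    w <- sqrt(sum((offs[o, ] * spacing)^2))
    weights <- c(weights, rep(w, sum(keep)))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  src <- pos[seeds_ijk[, 1] + (seeds_ijk[, 2] - 1) * dm[1] +
               (seeds_ijk[, 3] - 1) * dm[1] * dm[2]]
  d <- igraph::distances(g, v = src, weights = weights)
  out <- apply(d, 2, min)
  full <- array(Inf, dm)
  full[idx] <- out
  full
}

# random blob mask: union of random spheres, for eikonal stress tests
random_blob_mask <- function(dm, n_spheres = 5, r_range = c(4, 9)) {
  mask <- array(FALSE, dm)
  coords <- which(array(TRUE, dm), arr.ind = TRUE)
  for (s in seq_len(n_spheres)) {
    c0 <- runif(3, 6, dm - 5)
    r <- runif(1, r_range[1], r_range[2])
    sel <- (coords[, 1] - c0[1])^2 + (coords[, 2] - c0[2])^2 +
      (coords[, 3] - c0[3])^2 <= r^2
    mask[coords[sel, , drop = FALSE]] <- TRUE
  }
  mask
}
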