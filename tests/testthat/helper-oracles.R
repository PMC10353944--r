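# Independent brute-force oracles used across the suite. These deliberately
# take the slow, literal route (full enumeration, dense sampling, pixel-wise
# search) so they share no code path with the implementations they check.

# Exact two-sided Mann-Whitney p by literal enumeration of every labeling.
oracle_mwu <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  combos <- utils::combn(length(pooled), nx)
  rs <- apply(combos, 2, function(idx) sum(r[idx]))
  rs_obs <- sum(r[seq_len(nx)])
  p_le <- mean(rs <= rs_obs)
  p_ge <- mean(rs >= rs_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Exact two-sided Wilcoxon signed-rank p by literal enumeration of all 2^n
# sign assignments.
oracle_wsr <- function(x, y) {
  d <- (x - y)[x != y]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(W_all <= W_obs), mean(W_all >= W_obs)))
}

# Two-sided Fisher p from first principles: hypergeometric pmf via choose().
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  supp <- max(0, c1 - r2):min(r1, c1)
  pmf <- choose(r1, supp) * choose(r2, c1 - supp) / choose(N, c1)
  min(1, sum(pmf[pmf <= pmf[supp == a] * (1 + 1e-7)]))
}

# Minimum point-to-polyline distance by dense sampling of the polyline.
oracle_polyline_distance <- function(pt, polyline, n_samples = 1e5) {
  seg <- cbind(polyline[-nrow(polyline), , drop = FALSE],
               polyline[-1, , drop = FALSE])
  lens <- sqrt((seg[, 3] - seg[, 1])^2 + (seg[, 4] - seg[, 2])^2)
  per_seg <- pmax(2, round(n_samples * lens / sum(lens)))
  best <- Inf
  for (i in seq_len(nrow(seg))) {
    tt <- seq(0, 1, length.out = per_seg[i])
    xs <- seg[i, 1] + tt * (seg[i, 3] - seg[i, 1])
    ys <- seg[i, 2] + tt * (seg[i, 4] - seg[i, 2])
    best <- min(best, min(sqrt((pt[1] - xs)^2 + (pt[2] - ys)^2)))
  }
  best
}

# Intersection-over-union of two logical masks.
mask_iou <- function(a, b) sum(a & b) / sum(a | b)

# Match detected adhesion masks to ground-truth masks at an IoU cutoff and
# report precision/recall (greedy one-to-one matching on descending IoU).
match_adhesions <- function(truth_masks, label_img, iou_min = 0.5) {
  labs <- setdiff(unique(as.vector(label_img)), 0)
  if (!length(labs) || !length(truth_masks))
    return(list(precision = 0, recall = 0))
  ious <- matrix(0, length(truth_masks), length(labs))
  for (i in seq_along(truth_masks))
    for (j in seq_along(labs))
      ious[i, j] <- mask_iou(truth_masks[[i]], label_img == labs[j])
  matched <- 0L
  while (TRUE) {
    best <- which(ious == max(ious), arr.ind = TRUE)[1, ]
    if (ious[best[1], best[2]] < iou_min) break
    matched <- matched + 1L
    ious[best[1], ] <- -1
    ious[, best[2]] <- -1
  }
  list(precision = matched / length(labs),
       recall = matched / length(truth_masks))
}

# A wiggly test polyline in the plane.
random_polyline <- function(n_vertices, extent = 100) {
  cbind(x = cumsum(runif(n_vertices, 1, extent / n_vertices)),
        y = runif(n_vertices, 0, extent / 2))
}
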