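# Independent brute-force oracles used to validate the fast metric paths.

random_mask <- function(h, w, p = 0.3) {
  matrix(rbinom(h * w, 1, p), h, w)
}

# Set-overlap formulation on explicit pixel index sets.
oracle_overlap_metrics <- function(pred, gt) {
  A <- which(pred == 1); B <- which(gt == 1)
  inter <- length(intersect(A, B))
  uni <- length(union(A, B))
  n <- length(pred)
  list(
    acc = (inter + (n - uni)) / n,
    dsc = if (length(A) + length(B) == 0) 1 else 2 * inter / (length(A) + length(B)),
    iou = if (uni == 0) 1 else inter / uni
  )
}

# All-pairs directed mean nearest-neighbour distances.
oracle_ahd <- function(pred, gt) {
  pa <- which(pred == 1, arr.ind = TRUE)
  ga <- which(gt == 1, arr.ind = TRUE)
  if (nrow(pa) == 0 || nrow(ga) == 0) return(NA_real_)
  d2 <- outer(ga[, 1], pa[, 1], "-")^2 + outer(ga[, 2], pa[, 2], "-")^2
  g_to_p <- mean(sqrt(apply(d2, 1, min)))
  p_to_g <- mean(sqrt(apply(d2, 2, min)))
  (g_to_p + p_to_g) / 2
}

# Exhaustive pairwise win counting, ties worth one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) wins <- wins + sum(p > neg) + 0.5 * sum(p == neg)
  wins / (length(pos) * length(neg))
}

# One-foreground-pixel mask.
point_mask <- function(h, w, r, c) {
  m <- matrix(0, h, w)
  m[r, c] <- 1
  m
}

# Lightweight pair for split bookkeeping tests.
tiny_pair <- function(id) {
  sample_pair(matrix(0.5, 4, 4), matrix(0, 4, 4), id)
}
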