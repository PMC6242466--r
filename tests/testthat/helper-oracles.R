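# Independent oracles, deliberately written as plain scalar/enumeration code
# so they share nothing with the vectorized implementations they check.

# Direct-formula regularized t for one strain.
oracle_reg_t <- function(ctrl, drug, bg_c, bg_d, conf,
                         df_mode = "regularized") {
  nc <- length(ctrl); nd <- length(drug)
  s2c <- sum((ctrl - mean(ctrl))^2) / (nc - 1)
  s2d <- sum((drug - mean(drug))^2) / (nd - 1)
  vc <- (conf * bg_c + (nc - 1) * s2c) / (conf + nc - 2)
  vd <- (conf * bg_d + (nd - 1) * s2d) / (conf + nd - 2)
  tt <- (mean(drug) - mean(ctrl)) / sqrt(vc / nc + vd / nd)
  df <- if (df_mode == "regularized") nc + nd + 2 * conf - 4 else nc + nd - 2
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

# Hand-coded Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running_min <- 1
  for (i in n:1) {
    val <- min(1, p[o[i]] * n / i)
    running_min <- min(running_min, val)
    adj[o[i]] <- running_min
  }
  adj
}

# Exhaustive-enumeration hypergeometric tail: draw every n-subset of a
# universe of size N whose first K elements are the target; count draws
# with at least k target members.
oracle_hyper_enum <- function(N, K, n, k) {
  if (n == 0) return(if (k <= 0) 1 else 0)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Uniform disc image with flat background; returns image plus brute-force
# centroid and pixel sums.
disc_image <- function(width = 60, height = 60, cx = 30, cy = 30,
                       radius = 5, intensity = 200, background = 10) {
  img <- matrix(background, nrow = height, ncol = width)
  for (y in 0:(height - 1)) {
    for (x in 0:(width - 1)) {
      if ((x - cx)^2 + (y - cy)^2 <= radius^2)
        img[y + 1, x + 1] <- intensity
    }
  }
  img
}

# Brute-force sum of pixel intensities inside an oval (bounding box only).
oracle_oval_sum <- function(img, cx, cy, a, b) {
  s <- 0; n <- 0
  ys <- max(0, floor(cy - b - 1)):min(nrow(img) - 1, ceiling(cy + b + 1))
  xs <- max(0, floor(cx - a - 1)):min(ncol(img) - 1, ceiling(cx + a + 1))
  for (y in ys) {
    for (x in xs) {
      if (((x - cx) / max(a, 0.5))^2 + ((y - cy) / max(b, 0.5))^2 <= 1) {
        s <- s + img[y + 1, x + 1]
        n <- n + 1
      }
    }
  }
  list(sum = s, n = n, mean = s / n)
}

# Small raw density table built directly (not via simulate_screen), with an
# exact per-strain drug effect and no noise.
tiny_table <- function(n_strains = 12, days = 1:2, n_rep = 3,
                       effect = rep(0, n_strains)) {
  strains <- sprintf("S%02d", seq_len(n_strains))
  base <- seq(8, 11, length.out = n_strains)
  rows <- expand.grid(strain_id = strains, condition = c("control", "drug"),
                      replicate = seq_len(n_rep), day = days,
                      stringsAsFactors = FALSE)
  b <- base[match(rows$strain_id, strains)]
  e <- effect[match(rows$strain_id, strains)]
  val <- b + ifelse(rows$condition == "drug", e, 0)
  rows$plate_id <- paste0(rows$condition, "_r", rows$replicate)
  rows$density <- 2^val
  attr(rows, "stage") <- "raw"
  rows
}
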