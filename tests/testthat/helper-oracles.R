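# Independent oracles used across the suite.  Everything here re-derives
# results from first principles (loops, enumeration, closed forms) and must
# not call back into the code paths it checks.

# --- reference forward pass ------------------------------------------------
# stride-2 / pad-1 / 3x3 convolution, weight column k = c*9 + dj*3 + di
oracle_conv <- function(x, W, b, stride = 2L) {
  H <- dim(x)[1]; Wd <- dim(x)[2]; Cin <- dim(x)[3]
  Ho <- (H - 1L) %/% stride + 1L
  Wo <- (Wd - 1L) %/% stride + 1L
  xp <- array(0, c(H + 2L, Wd + 2L, Cin))
  xp[2:(H + 1), 2:(Wd + 1), ] <- x
  out <- array(0, c(Ho, Wo, nrow(W)))
  for (co in seq_len(nrow(W))) {
    acc <- matrix(b[co], Ho, Wo)
    for (ci in seq_len(Cin)) for (dj in 0:2) for (di in 0:2) {
      k <- (ci - 1L) * 9L + dj * 3L + di + 1L
      rows <- seq(1L + di, by = stride, length.out = Ho)
      cols <- seq(1L + dj, by = stride, length.out = Wo)
      acc <- acc + W[co, k] * xp[rows, cols, ci]
    }
    out[, , co] <- acc
  }
  out
}

# 2x area-mean pooling with ceiling dims (partial edge blocks)
oracle_pool2 <- function(a) {
  H <- dim(a)[1]; W <- dim(a)[2]
  Ho <- (H + 1L) %/% 2L; Wo <- (W + 1L) %/% 2L
  out <- array(0, c(Ho, Wo, dim(a)[3]))
  for (cc in seq_len(dim(a)[3]))
    for (j in seq_len(Wo)) for (i in seq_len(Ho)) {
      rows <- (2 * i - 1):min(2 * i, H)
      cols <- (2 * j - 1):min(2 * j, W)
      out[i, j, cc] <- mean(a[rows, cols, cc])
    }
  out
}

# full network forward; masks = list of per-block arrays plus head vector
oracle_forward <- function(params, x, masks = NULL, stem = 0L) {
  for (s in seq_len(stem)) x <- oracle_pool2(x)
  B <- length(params$Wc)
  for (b in seq_len(B)) {
    x <- pmax(oracle_conv(x, params$Wc[[b]], params$bc[[b]]), 0)
    if (!is.null(masks)) x <- x * masks[[b]]
  }
  h <- apply(x, 3, mean)
  if (!is.null(masks)) h <- h * masks[[B + 1]]
  z <- as.vector(params$Wd %*% h + params$bd)
  e <- exp(z - max(z))
  e / sum(e)
}

# replay the seeded dropout masks that the compiled path draws from R's RNG
oracle_masks <- function(config, input_dims) {
  p <- config$dropout_rate
  h <- input_dims[1]; w <- input_dims[2]
  for (s in seq_len(config$stem_pool)) {
    h <- (h + 1L) %/% 2L; w <- (w + 1L) %/% 2L
  }
  masks <- list()
  for (co in config$conv_channels) {
    h <- (h - 1L) %/% 2L + 1L
    w <- (w - 1L) %/% 2L + 1L
    masks[[length(masks) + 1]] <- array((runif(h * w * co) >= p) / (1 - p),
                                        c(h, w, co))
  }
  cB <- config$conv_channels[length(config$conv_channels)]
  c(masks, list((runif(cB) >= p) / (1 - p)))
}

# --- connected components (two-pass union-find) ---------------------------
# counts dark connected components (4-neighbourhood) with area in [lo, hi]
oracle_blob_count <- function(img, dark_threshold = 0.62, lo = 10, hi = 5000) {
  lum <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  m <- lum < dark_threshold
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nextl <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!m[i, j]) next
    up <- if (i > 1 && m[i - 1, j]) lab[i - 1, j] else 0L
    lf <- if (j > 1 && m[i, j - 1]) lab[i, j - 1] else 0L
    if (up == 0L && lf == 0L) {
      nextl <- nextl + 1L
      parent[nextl] <- nextl
      lab[i, j] <- nextl
    } else if (up != 0L && lf != 0L) {
      ru <- find(up); rl <- find(lf)
      parent[max(ru, rl)] <- min(ru, rl)
      lab[i, j] <- min(ru, rl)
    } else {
      lab[i, j] <- max(up, lf)
    }
  }
  if (nextl == 0L) return(0L)
  roots <- vapply(seq_len(nextl), find, 0L)
  sizes <- tapply(rep(1L, sum(m)), roots[lab[m]], sum)
  sum(sizes >= lo & sizes <= hi)
}

# --- pairwise AUC oracle ---------------------------------------------------
oracle_auc <- function(scores, labels, positive = "A") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

oracle_accuracy <- function(df) mean(df$label == df$truth)

# --- exhaustive rejection oracle ------------------------------------------
# global mode: remove the k most-uncertain (ties by slide_id) and recompute
oracle_rejection_global <- function(df, k, metric) {
  df <- df[order(-df$sigma_slide, df$slide_id), , drop = FALSE]
  kept <- if (k == 0) df else df[-seq_len(k), , drop = FALSE]
  if (metric == "accuracy") return(oracle_accuracy(kept))
  if (length(unique(kept$truth)) < 2) return(NA_real_)
  oracle_auc(kept$mu_slide, kept$truth)
}

# class-specific: best metric over every (kA, kB) with kA + kB = k
oracle_rejection_class <- function(df, k, metric) {
  df <- df[order(-df$sigma_slide, df$slide_id), , drop = FALSE]
  ia <- which(df$label == "A"); ib <- which(df$label == "B")
  best <- NA_real_
  for (kA in 0:min(k, length(ia))) {
    kB <- k - kA
    if (kB > length(ib)) next
    drop_idx <- c(head(ia, kA), head(ib, kB))
    kept <- if (length(drop_idx)) df[-drop_idx, , drop = FALSE] else df
    if (nrow(kept) == 0) next
    m <- if (metric == "accuracy") {
      oracle_accuracy(kept)
    } else if (length(unique(kept$truth)) < 2) NA_real_ else {
      oracle_auc(kept$mu_slide, kept$truth)
    }
    if (!is.na(m) && (is.na(best) || m > best)) best <- m
  }
  best
}

# --- misc ------------------------------------------------------------------
# build a minimal diagnosis table for the evaluation functions
fake_diagnoses <- function(mu, sigma, truth, ids = sprintf("s%02d", seq_along(mu))) {
  data.frame(slide_id = ids, level = 0L, n_patches = 1L,
             mu_slide = mu, sigma_slide = sigma, sigma_patch_mean = sigma,
             label = ifelse(mu >= 0.5, "A", "B"), truth = truth,
             stringsAsFactors = FALSE)
}

tiny_model <- function(seed = 3, dropout_rate = 0.4, input_size = 32L,
                       channels = c(3L, 4L)) {
  build_model(model_config(conv_channels = channels, input_size = input_size,
                           dropout_rate = dropout_rate, seed = seed))
}

random_patch <- function(seed, n = 32L) {
  slideuq:::local_seed(seed, array(runif(n * n * 3), c(n, n, 3)))
}
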