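# Independent oracles used across the test files.

# Literal looped implementation of the plain multi-verse optimizer: the
# universe matrix, normalized inflation rates, white/black-hole exchange
# with roulette donor selection, and the wormhole move with the random
# sign branch and the linear/power schedules. Draws are consumed in the
# documented order (r1 matrix; donor uniforms in column-major entry order;
# r2 matrix; r3 batch; r4 batch), so with a shared seed the trajectory
# must agree bitwise with optimize_mvo() at alpha = 0.
reference_mvo <- function(objective, lb, ub, n, M,
                          P_min = 0.5, P_max = 1, chi = 6, seed = 1,
                          shift = 1e-9) {
  d <- length(lb)
  set.seed(seed)
  u0 <- matrix(runif(n * d), n, d)
  X <- sweep(sweep(u0, 2, ub - lb, `*`), 2, lb, `+`)
  f <- apply(X, 1, objective)
  best_i <- which.min(f)
  best <- X[best_i, ]
  best_f <- f[best_i]
  hist <- numeric(M)
  for (m in seq_len(M)) {
    ord <- order(f)
    Xs <- X[ord, , drop = FALSE]
    Fn <- f / sqrt(sum(f^2))
    Fns <- sort(Fn)
    w <- -Fns
    p <- w - min(w) + shift
    cs <- cumsum(p)

    r1 <- matrix(runif(n * d), n, d)
    need <- list()
    for (j in seq_len(d)) {
      for (i in seq_len(n)) {
        if (r1[i, j] < Fn[i]) need[[length(need) + 1L]] <- c(i, j)
      }
    }
    for (e in need) {
      u <- runif(1)
      k <- 1L + sum(cs < u * cs[n])
      X[e[1], e[2]] <- Xs[k, e[2]]
    }

    Pw <- P_min + m * (P_max - P_min) / M
    tdr <- 1 - (m / M)^(1 / chi)
    r2 <- matrix(runif(n * d), n, d)
    fire <- list()
    for (j in seq_len(d)) {
      for (i in seq_len(n)) {
        if (r2[i, j] < Pw) fire[[length(fire) + 1L]] <- c(i, j)
      }
    }
    K <- length(fire)
    r3 <- runif(K)
    r4 <- runif(K)
    for (t in seq_len(K)) {
      i <- fire[[t]][1]; j <- fire[[t]][2]
      step <- tdr * ((ub[j] - lb[j]) * r4[t] + lb[j])
      v <- if (r3[t] < 0.5) best[j] + step else best[j] - step
      X[i, j] <- min(max(v, lb[j]), ub[j])
    }

    f <- apply(X, 1, objective)
    if (min(f) < best_f) {
      best_f <- min(f)
      best <- X[which.min(f), ]
    }
    hist[m] <- best_f
  }
  list(best = best, best_fitness = best_f, history = hist,
       population = X, fitness = f)
}

# Brute-force metric computation straight from the printed formulas,
# independent of compute_metrics() internals.
brute_metrics <- function(TP, TN, FP, FN) {
  c(ACC = (TP + TN) / (TP + TN + FP + FN),
    PPV = TP / (TP + FP),
    SPC = TN / (TN + FP),
    SEN = TP / (TP + FN),
    F1 = 2 * (TP / (TP + FP)) * (TP / (TP + FN)) /
      (TP / (TP + FP) + TP / (TP + FN)),
    MCC = (TP * TN - FP * FN) /
      sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)))
}

# Rank sums by explicit pairwise comparison counting (midranks via the
# count of smaller elements plus half the ties), independent of rank().
brute_rank_sums <- function(a, b) {
  pooled <- c(a, b)
  r <- vapply(pooled, function(x) {
    sum(pooled < x) + (sum(pooled == x) + 1) / 2
  }, numeric(1))
  c(W1 = sum(r[seq_along(a)]), W2 = sum(r[length(a) + seq_along(b)]))
}

# Central finite-difference gradient of the network loss.
numeric_gradient <- function(spec, values, X, y, loss = "mse", h = 1e-6) {
  vapply(seq_along(values), function(i) {
    up <- values; up[i] <- up[i] + h
    dn <- values; dn[i] <- dn[i] - h
    (nn_loss(spec, up, X, y, loss) - nn_loss(spec, dn, X, y, loss)) / (2 * h)
  }, numeric(1))
}

# Small WBCD/WDBC-dialect fixture files written on the fly.
write_wbcd_fixture <- function(path, rows = NULL) {
  if (is.null(rows)) {
    rows <- c(
      "1000025,5,1,1,1,2,1,3,1,1,2",
      "1002945,5,4,4,5,7,10,3,2,1,2",
      "1015425,3,1,1,1,2,2,3,1,1,4"
    )
  }
  writeLines(rows, path)
  path
}

write_wdbc_fixture <- function(path, n = 6, seed = 7) {
  set.seed(seed)
  rows <- vapply(seq_len(n), function(i) {
    lab <- if (i %% 2 == 0) "M" else "B"
    feats <- round(runif(30, 0.1, 30), 4)
    paste(c(84300 + i, lab, feats), collapse = ",")
  }, character(1))
  writeLines(rows, path)
  path
}

sphere <- function(x) sum(x^2)
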