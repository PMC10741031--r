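# Independent oracles and small fixture builders shared across the suite.

# brute-force modified cosine: enumerate every one-to-one pairing of
# candidate peak pairs and take the best total score
oracle_modified_cosine <- function(a, b, tol = 0.01) {
  wa <- sqrt(a$intensity); wa <- wa / sqrt(sum(wa^2))
  wb <- sqrt(b$intensity); wb <- wb / sqrt(sum(wb^2))
  shift <- a$precursor_mz - b$precursor_mz
  pairs <- NULL
  for (i in seq_along(a$mz)) {
    for (j in seq_along(b$mz)) {
      if (abs(a$mz[i] - b$mz[j]) <= tol ||
          abs(a$mz[i] - (b$mz[j] + shift)) <= tol) {
        pairs <- rbind(pairs, c(i, j, wa[i] * wb[j]))
      }
    }
  }
  if (is.null(pairs)) return(list(score = 0, matches = 0L))
  best <- 0; best_n <- 0L
  recurse <- function(k, used_i, used_j, acc, cnt) {
    if (acc > best || (acc == best && cnt > best_n)) {
      best <<- acc; best_n <<- cnt
    }
    if (k > nrow(pairs)) return()
    recurse(k + 1L, used_i, used_j, acc, cnt)
    if (!(pairs[k, 1] %in% used_i) && !(pairs[k, 2] %in% used_j)) {
      recurse(k + 1L, c(used_i, pairs[k, 1]), c(used_j, pairs[k, 2]),
              acc + pairs[k, 3], cnt + 1L)
    }
  }
  recurse(1L, integer(0), integer(0), 0, 0L)
  list(score = best, matches = best_n)
}

# independent one-component PLS (y centred) with the same contiguous-fold CV
oracle_pls1_q2 <- function(X, y_raw, cv_folds) {
  n <- nrow(X)
  y <- y_raw - mean(y_raw)
  fold_id <- sort(rep(seq_len(cv_folds), length.out = n))
  press <- 0
  for (f in seq_len(cv_folds)) {
    test <- fold_id == f
    ytr <- y_raw[!test] - mean(y_raw[!test])
    ctr <- colMeans(X[!test, , drop = FALSE])
    Xtr <- sweep(X[!test, , drop = FALSE], 2, ctr)
    Xte <- sweep(X[test, , drop = FALSE], 2, ctr)
    w <- crossprod(Xtr, ytr); w <- w / sqrt(sum(w^2))
    tt <- Xtr %*% w
    q <- sum(ytr * tt) / sum(tt^2)
    pred <- as.numeric((Xte %*% w) * q) + mean(y_raw[!test]) - mean(y_raw)
    press <- press + sum((y[test] - pred)^2)
  }
  1 - press / sum(y^2)
}

# mean silhouette width from a distance matrix and integer labels
oracle_silhouette <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g) {
      mean(d[i, labels == g])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# a quick toy spectrum
toy_spectrum <- function(id, precursor, mz, intensity = NULL) {
  if (is.null(intensity)) intensity <- rep(100, length(mz))
  msms_spectrum(id, precursor, mz, intensity)
}

# a small family of similar spectra around shared base peaks
toy_family <- function(prefix, base_mz, n, precursor, jitter = 5e-4,
                       seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(k) {
    toy_spectrum(paste0(prefix, k), precursor + (k - 1) * 1e-3,
                 base_mz + stats::rnorm(length(base_mz), 0, jitter),
                 intensity = seq(100, 40, length.out = length(base_mz)))
  })
}

tannic_subset <- function(lib = load_library()) {
  lib[lib$class %in% c("phenolcarboxylic acid", "gallotannin",
                       "ellagitannin", "chebulic ellagitannin"), ]
}
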