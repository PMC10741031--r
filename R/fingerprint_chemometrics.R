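# Chromatographic fingerprint chemometrics: common-peak alignment,
# similarity evaluation, autoscaling, HCA, PCA and OPLS-DA with VIP marker
# selection.

#' Construct a batch-by-peak area table
#'
#' @param areas Numeric matrix, batches in rows, peaks in columns,
#'   non-negative areas (absent peak = 0).
#' @param batch_ids,peak_ids Row / column identifiers (default from
#'   dimnames).
#' @param rt Optional per-peak retention times in minutes.
#' @param common Optional logical vector marking common peaks (present in
#'   every batch); default all `TRUE`.
#' @return An object of class `"peak_table"`.
#' @export
peak_table <- function(areas, batch_ids = rownames(areas),
                       peak_ids = colnames(areas), rt = NULL, common = NULL) {
  areas <- as.matrix(areas)
  if (is.null(batch_ids)) batch_ids <- paste0("S", seq_len(nrow(areas)))
  if (is.null(peak_ids)) peak_ids <- paste0("P", seq_len(ncol(areas)))
  stopifnot(length(batch_ids) == nrow(areas), length(peak_ids) == ncol(areas))
  if (any(areas < 0, na.rm = TRUE)) stop("areas must be non-negative",
                                         call. = FALSE)
  dimnames(areas) <- list(batch_ids, peak_ids)
  if (is.null(common)) common <- rep(TRUE, ncol(areas))
  structure(list(areas = areas, batch_ids = batch_ids, peak_ids = peak_ids,
                 rt = rt, common = common),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat("<peak_table> ", length(x$batch_ids), " batches x ", length(x$peak_ids),
      " peaks (", sum(x$common), " common)\n", sep = "")
  invisible(x)
}

.as_area_matrix <- function(x) {
  if (inherits(x, "peak_table")) x$areas else as.matrix(x)
}

#' Read / write a peak table as CSV
#'
#' Rows are batches, the first column holds the batch id, remaining columns
#' are peak areas.
#'
#' @param x A [peak_table()].
#' @param path CSV path.
#' @return `read_peak_table()` returns a `peak_table`; `write_peak_table()`
#'   the path, invisibly.
#' @export
write_peak_table <- function(x, path) {
  df <- data.frame(batch = x$batch_ids, x$areas, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  peak_table(m)
}

#' Align per-batch peak lists into common peaks
#'
#' Peaks from all batches are clustered on retention time by single linkage;
#' clusters are cut at height `rt_tol`. A cluster contributes one peak per
#' batch (when a batch has several peaks in one cluster the one nearest the
#' cluster median retention time is used and a message is logged). Clusters
#' represented in every batch become common peaks; the rest are retained but
#' flagged non-common.
#'
#' @param per_batch_peak_lists Named list; one data.frame per batch with
#'   columns `rt` (minutes) and `area`.
#' @param rt_tol Retention-time tolerance in minutes (default 0.1).
#' @return A [peak_table()] with per-cluster mean `rt` and the `common` flag;
#'   peaks are ordered by retention time.
#' @export
align_common_peaks <- function(per_batch_peak_lists, rt_tol = 0.1) {
  stopifnot(rt_tol > 0, length(per_batch_peak_lists) >= 1L)
  batches <- names(per_batch_peak_lists)
  if (is.null(batches)) {
    batches <- paste0("S", seq_along(per_batch_peak_lists))
  }
  all_rt <- unlist(lapply(per_batch_peak_lists, function(d) d$rt))
  all_area <- unlist(lapply(per_batch_peak_lists, function(d) d$area))
  all_batch <- rep(batches, vapply(per_batch_peak_lists, nrow, integer(1)))
  if (length(all_rt) == 1L) {
    cl <- 1L
  } else {
    hc <- stats::hclust(stats::dist(all_rt), method = "single")
    cl <- stats::cutree(hc, h = rt_tol)
  }
  clusters <- sort(unique(cl))
  n_cl <- length(clusters)
  areas <- matrix(0, nrow = length(batches), ncol = n_cl,
                  dimnames = list(batches, NULL))
  rt_mean <- numeric(n_cl)
  for (k in seq_len(n_cl)) {
    idx <- which(cl == clusters[k])
    rt_mean[k] <- mean(all_rt[idx])
    med <- stats::median(all_rt[idx])
    for (b in unique(all_batch[idx])) {
      sub <- idx[all_batch[idx] == b]
      if (length(sub) > 1L) {
        message("batch ", b, ": ", length(sub),
                " peaks in one rt cluster near ", round(med, 2),
                " min; keeping the nearest")
        sub <- sub[which.min(abs(all_rt[sub] - med))]
      }
      areas[b, k] <- all_area[sub]
    }
  }
  present_in_all <- colSums(areas > 0) == length(batches)
  ord <- order(rt_mean)
  areas <- areas[, ord, drop = FALSE]
  colnames(areas) <- paste0("P", seq_len(n_cl))
  peak_table(areas, rt = rt_mean[ord], common = present_in_all[ord])
}

#' Fingerprint similarity against a reference chromatogram
#'
#' The congruence (cosine) coefficient between each batch's area vector and
#' a reference vector: the mean fingerprint (default), the median
#' fingerprint, or a named batch.
#'
#' @param table A [peak_table()] or area matrix.
#' @param reference `"mean"`, `"median"`, or a batch id.
#' @return A list of class `"similarity_report"` with `similarity` (named
#'   per-batch scores in `[-1, 1]`) and `reference`.
#' @export
fingerprint_similarity <- function(table, reference = "mean") {
  x <- .as_area_matrix(table)
  if (identical(reference, "mean") || identical(reference, "median")) {
    if (nrow(x) < 2L) stop("mean/median reference needs >= 2 batches",
                           call. = FALSE)
    ref <- apply(x, 2, reference)
  } else {
    if (!reference %in% rownames(x)) {
      stop("unknown reference batch '", reference, "'", call. = FALSE)
    }
    ref <- x[reference, ]
  }
  if (sqrt(sum(ref^2)) == 0) stop("reference fingerprint is all zero",
                                  call. = FALSE)
  sims <- apply(x, 1, function(v) {
    nv <- sqrt(sum(v^2))
    if (nv == 0) stop("all-zero batch fingerprint", call. = FALSE)
    sum(v * ref) / (nv * sqrt(sum(ref^2)))
  })
  structure(list(similarity = sims, reference = reference),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat("<similarity_report> reference = ", x$reference, "; range ",
      sprintf("%.3f", min(x$similarity)), " - ",
      sprintf("%.3f", max(x$similarity)), "\n", sep = "")
  invisible(x)
}

#' Unit-variance autoscaling
#'
#' Centres every peak to mean zero and scales to unit variance -- the
#' pre-treatment applied before HCA, PCA and OPLS-DA. Constant peaks carry
#' no multivariate information and are dropped with a warning.
#'
#' @param table A [peak_table()] or numeric matrix (batches x peaks).
#' @return The scaled matrix with `"center"` and `"scale"` attributes;
#'   [unscale()] inverts it.
#' @export
autoscale <- function(table) {
  x <- .as_area_matrix(table)
  if (nrow(x) < 2L) stop("autoscaling needs >= 2 batches", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  constant <- sds == 0
  if (any(constant)) {
    warning("dropping constant peak(s): ",
            paste(colnames(x)[constant], collapse = ", "))
    x <- x[, !constant, drop = FALSE]
    sds <- sds[!constant]
  }
  ctr <- colMeans(x)
  scaled <- sweep(sweep(x, 2, ctr), 2, sds, "/")
  attr(scaled, "center") <- ctr
  attr(scaled, "scale") <- sds
  scaled
}

#' @rdname autoscale
#' @param scaled A matrix produced by [autoscale()].
#' @export
unscale <- function(scaled) {
  out <- sweep(sweep(scaled, 2, attr(scaled, "scale"), "*"), 2,
               attr(scaled, "center"), "+")
  attr(out, "center") <- NULL
  attr(out, "scale") <- NULL
  out
}

#' Hierarchical cluster analysis of batches
#'
#' Agglomerative clustering of the autoscaled area matrix, Ward linkage on
#' Euclidean distance by default. Heatmap row ordering should follow
#' `$hclust$order`.
#'
#' @param table A [peak_table()] or matrix; autoscaled internally unless
#'   `scale = FALSE`.
#' @param linkage `"ward"`, `"average"` or `"complete"`.
#' @param distance `"euclidean"` or `"correlation"` (1 - Pearson r).
#' @param k Number of clusters to cut at (optional).
#' @param scale Autoscale first? Default `TRUE`.
#' @return List with `hclust`, `order` (leaf order) and `clusters` (named
#'   integer vector, only when `k` given).
#' @export
hca <- function(table, linkage = c("ward", "average", "complete"),
                distance = c("euclidean", "correlation"), k = NULL,
                scale = TRUE) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  x <- .as_area_matrix(table)
  if (scale) x <- autoscale(x)
  d <- if (distance == "euclidean") {
    stats::dist(x)
  } else {
    stats::as.dist(1 - stats::cor(t(x)))
  }
  method <- c(ward = "ward.D2", average = "average",
              complete = "complete")[[linkage]]
  hc <- stats::hclust(d, method = method)
  out <- list(hclust = hc, order = hc$order, clusters = NULL)
  if (!is.null(k)) {
    if (k > nrow(x)) stop("k exceeds the number of batches", call. = FALSE)
    out$clusters <- stats::cutree(hc, k = k)
  }
  out
}

#' Principal component analysis of a scaled matrix
#'
#' Eigen-decomposition of the covariance of an (already autoscaled) matrix
#' via singular values. Sign convention: within each component the loading
#' of largest magnitude is made positive, so results are reproducible across
#' platforms. Explained fractions are relative to the total variance of the
#' input, so they sum to 1 when all rank components are requested.
#'
#' @param scaled Autoscaled matrix (see [autoscale()]); a `peak_table` is
#'   autoscaled automatically.
#' @param n_components Number of components (default
#'   `min(nrow - 1, ncol)`).
#' @return List of class `"pca_result"`: `scores` (batches x components),
#'   `loadings` (peaks x components), `explained_variance_fraction`.
#' @export
pca <- function(scaled, n_components = NULL) {
  if (inherits(scaled, "peak_table")) scaled <- autoscale(scaled)
  x <- as.matrix(scaled)
  rank_max <- min(nrow(x) - 1L, ncol(x))
  if (is.null(n_components)) n_components <- rank_max
  if (n_components > rank_max) {
    stop("n_components exceeds min(n - 1, p)", call. = FALSE)
  }
  total_var <- sum(scale(x, scale = FALSE)^2) / (nrow(x) - 1L)
  if (total_var == 0) stop("degenerate (constant) matrix", call. = FALSE)
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- n_components
  load <- pr$rotation[, seq_len(k), drop = FALSE]
  scores <- pr$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = load,
                 explained_variance_fraction = pr$sdev[seq_len(k)]^2 / total_var),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", ncol(x$scores), " components; explained: ",
      paste(sprintf("%.1f%%", 100 * x$explained_variance_fraction),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# one NIPALS pass: predictive component + optional orthogonal filtering
.opls_fit <- function(X, y, n_orthogonal) {
  W_o <- P_o <- NULL
  Xd <- X
  for (a in seq_len(n_orthogonal)) {
    w <- crossprod(Xd, y) / sum(y * y)
    w <- w / sqrt(sum(w^2))
    t_p <- Xd %*% w
    p <- crossprod(Xd, t_p) / sum(t_p^2)
    w_o <- p - as.numeric(crossprod(w, p)) * w
    n_wo <- sqrt(sum(w_o^2))
    if (n_wo < 1e-12) break
    w_o <- w_o / n_wo
    t_o <- Xd %*% w_o
    p_o <- crossprod(Xd, t_o) / sum(t_o^2)
    Xd <- Xd - t_o %*% t(p_o)
    W_o <- cbind(W_o, w_o)
    P_o <- cbind(P_o, p_o)
  }
  w <- crossprod(Xd, y) / sum(y * y)
  w <- w / sqrt(sum(w^2))
  t_p <- Xd %*% w
  p <- crossprod(Xd, t_p) / sum(t_p^2)
  q <- sum(y * t_p) / sum(t_p^2)
  list(w = w, t = t_p, p = p, q = q, W_o = W_o, P_o = P_o, X_deflated = Xd)
}

.opls_predict <- function(fit, Xnew) {
  if (!is.null(fit$W_o)) {
    for (a in seq_len(ncol(fit$W_o))) {
      t_o <- Xnew %*% fit$W_o[, a]
      Xnew <- Xnew - t_o %*% t(fit$P_o[, a])
    }
  }
  as.numeric((Xnew %*% fit$w) * fit$q)
}

#' Orthogonal partial-least-squares discriminant analysis
#'
#' Two-class OPLS-DA by NIPALS: `n_orthogonal` orthogonal-signal components
#' are filtered out, then a single predictive component is fitted. With
#' `n_orthogonal = 0` the model reduces exactly to one-component PLS-DA.
#' `R2X`/`R2Y` are fitted variance fractions; `Q2` is computed from
#' cross-validated prediction residuals over contiguous batch folds (7 by
#' default). VIP scores use the standard weighted-loadings formula over all
#' (orthogonal + predictive) components, weighted by the y-variance each
#' explains, so the squared scores average to 1 across peaks.
#'
#' @param scaled Autoscaled matrix (batches x peaks); a `peak_table` is
#'   autoscaled automatically.
#' @param groups A two-level factor (or coercible) of class labels.
#' @param n_orthogonal Number of orthogonal components (default 1).
#' @param cv_folds Cross-validation folds (default 7, capped at the number
#'   of batches).
#' @return List of class `"oplsda_result"` with `scores`, `loadings`,
#'   `weights`, `orthogonal_scores`, `orthogonal_loadings`, `R2X`, `R2Y`,
#'   `Q2`, `vip` (named per-peak scores) and `groups`.
#' @export
oplsda <- function(scaled, groups, n_orthogonal = 1L, cv_folds = 7L) {
  if (inherits(scaled, "peak_table")) scaled <- autoscale(scaled)
  X <- as.matrix(scaled)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("OPLS-DA needs exactly 2 classes",
                                  call. = FALSE)
  if (length(groups) != nrow(X)) stop("groups length must match batches",
                                      call. = FALSE)
  n <- nrow(X)
  cv_folds <- min(as.integer(cv_folds), n)
  if (cv_folds < 2L) stop("need at least 2 cross-validation folds",
                          call. = FALSE)
  y_raw <- as.numeric(groups == levels(groups)[2])
  y <- y_raw - mean(y_raw)
  ssy <- sum(y^2)
  if (ssy == 0) stop("single-class response", call. = FALSE)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ssx <- sum(Xc^2)

  fit <- .opls_fit(Xc, y, n_orthogonal)
  resid_X <- fit$X_deflated - fit$t %*% t(fit$p)
  R2X <- 1 - sum(resid_X^2) / ssx
  yhat <- as.numeric(fit$t * fit$q)
  R2Y <- 1 - sum((y - yhat)^2) / ssy

  # contiguous-block cross-validation in batch order
  fold_id <- sort(rep(seq_len(cv_folds), length.out = n))
  press <- 0
  for (f in seq_len(cv_folds)) {
    test <- fold_id == f
    if (all(test) || !any(test)) next
    ytr <- y_raw[!test] - mean(y_raw[!test])
    if (sum(ytr^2) == 0) {
      press <- press + sum((y[test])^2)  # uninformative fold predicts the mean
      next
    }
    ctr <- colMeans(X[!test, , drop = FALSE])
    Xtr <- sweep(X[!test, , drop = FALSE], 2, ctr)
    Xte <- sweep(X[test, , drop = FALSE], 2, ctr)
    f_tr <- .opls_fit(Xtr, ytr, n_orthogonal)
    pred <- .opls_predict(f_tr, Xte) + mean(y_raw[!test]) - mean(y_raw)
    press <- press + sum((y[test] - pred)^2)
  }
  Q2 <- 1 - press / ssy

  # VIP over all components, weighted by explained y-variance
  comps_w <- cbind(fit$W_o, fit$w)
  comps_t <- cbind(if (is.null(fit$W_o)) NULL else {
    sapply(seq_len(ncol(fit$W_o)), function(a) Xc %*% fit$W_o[, a])
  }, fit$t)
  ssy_comp <- apply(comps_t, 2, function(tt) {
    b <- sum(y * tt) / sum(tt^2)
    sum((b * tt)^2)
  })
  p_dim <- ncol(X)
  w_norm2 <- comps_w^2
  w_norm2 <- sweep(w_norm2, 2, colSums(w_norm2), "/")
  vip <- sqrt(p_dim * as.numeric(w_norm2 %*% ssy_comp) / sum(ssy_comp))
  names(vip) <- colnames(X)

  structure(list(scores = fit$t, loadings = fit$p, weights = fit$w,
                 orthogonal_scores = if (is.null(fit$W_o)) NULL else
                   Xc %*% fit$W_o,
                 orthogonal_loadings = fit$P_o,
                 R2X = R2X, R2Y = R2Y, Q2 = Q2, vip = vip, groups = groups),
            class = "oplsda_result")
}

#' @export
print.oplsda_result <- function(x, ...) {
  cat(sprintf("<oplsda_result> R2X %.3f, R2Y %.3f, Q2 %.3f; %d peaks with VIP > 1\n",
              x$R2X, x$R2Y, x$Q2, sum(x$vip > 1)))
  invisible(x)
}

#' Select discriminating peaks by VIP score
#'
#' @param result An [oplsda()] result.
#' @param threshold VIP cut-off (default 1.0).
#' @return Named numeric vector of VIP scores above the threshold, in
#'   descending order.
#' @export
vip_select <- function(result, threshold = 1.0) {
  stopifnot(threshold > 0)
  v <- result$vip[result$vip > threshold]
  sort(v, decreasing = TRUE)
}
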