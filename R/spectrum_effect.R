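# Spectrum-antioxidant correlation: activity summaries, Pearson correlation
# with dual-direction flagging, grey relational analysis, and DPPH
# peak-area-decrease scoring.

#' Construct an antioxidant activity table
#'
#' @param batch_ids Batch identifiers, aligned with the peak table.
#' @param dpph_ic50 DPPH radical-scavenging IC50 per batch, ug/mL (lower =
#'   more active).
#' @param abts_taoc ABTS total antioxidant capacity, mmol/g.
#' @param frap_taoc Ferric-reducing antioxidant power, mmol/g.
#' @return An object of class `"activity_table"`.
#' @export
activity_table <- function(batch_ids, dpph_ic50, abts_taoc, frap_taoc) {
  n <- length(batch_ids)
  stopifnot(length(dpph_ic50) == n, length(abts_taoc) == n,
            length(frap_taoc) == n)
  if (any(c(dpph_ic50, abts_taoc, frap_taoc) <= 0)) {
    stop("activity values must be positive", call. = FALSE)
  }
  structure(list(batch_ids = as.character(batch_ids),
                 dpph_ic50 = as.numeric(dpph_ic50),
                 abts_taoc = as.numeric(abts_taoc),
                 frap_taoc = as.numeric(frap_taoc)),
            class = "activity_table")
}

#' @export
print.activity_table <- function(x, ...) {
  cat("<activity_table> ", length(x$batch_ids), " batches; IC50 ",
      sprintf("%.3f-%.3f ug/mL", min(x$dpph_ic50), max(x$dpph_ic50)), "\n",
      sep = "")
  invisible(x)
}

#' Read / write an activity table as CSV
#'
#' Columns: `batch`, `dpph_ic50`, `abts_taoc`, `frap_taoc`.
#'
#' @param x An [activity_table()].
#' @param path CSV path.
#' @return `read_activity_table()` returns an `activity_table`;
#'   `write_activity_table()` the path, invisibly.
#' @export
write_activity_table <- function(x, path) {
  utils::write.csv(data.frame(batch = x$batch_ids, dpph_ic50 = x$dpph_ic50,
                              abts_taoc = x$abts_taoc, frap_taoc = x$frap_taoc),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_activity_table
#' @export
read_activity_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  activity_table(df$batch, df$dpph_ic50, df$abts_taoc, df$frap_taoc)
}

#' IC50 from a dose-response series by log-linear interpolation
#'
#' Interpolates log10(concentration) linearly between the two concentrations
#' bracketing 50 % inhibition. If the curve never reaches 50 % the IC50 is
#' undefined (`status = "undefined"`); a non-monotone curve is interpolated
#' at its first crossing, with a warning.
#'
#' @param concentrations Tested concentrations, ug/mL (ascending).
#' @param inhibition_percent Percent inhibition at each concentration.
#' @return List with `ic50` (ug/mL or `NA`) and `status` (`"ok"` or
#'   `"undefined"`).
#' @examples
#' ic50_from_doseresponse(c(2, 4), c(40, 60))  # ~2.83
#' @export
ic50_from_doseresponse <- function(concentrations, inhibition_percent) {
  stopifnot(length(concentrations) >= 2L,
            length(concentrations) == length(inhibition_percent),
            all(concentrations > 0))
  ord <- order(concentrations)
  conc <- concentrations[ord]
  inh <- inhibition_percent[ord]
  if (any(diff(inh) < 0)) {
    warning("non-monotone dose-response; interpolating at the first crossing")
  }
  exact <- which(inh == 50)
  if (length(exact)) return(list(ic50 = conc[exact[1]], status = "ok"))
  cross <- which(inh[-length(inh)] < 50 & inh[-1] > 50)
  if (!length(cross)) {
    if (inh[1] > 50) return(list(ic50 = conc[1], status = "ok"))
    return(list(ic50 = NA_real_, status = "undefined"))
  }
  i <- cross[1]
  lg <- log10(conc[i]) + (50 - inh[i]) / (inh[i + 1] - inh[i]) *
    (log10(conc[i + 1]) - log10(conc[i]))
  list(ic50 = 10^lg, status = "ok")
}

#' Pearson correlation of peak areas with antioxidant activities
#'
#' Computes the standard Pearson coefficient of every peak against the DPPH
#' IC50 and the ABTS / FRAP total antioxidant capacities, and flags the
#' antioxidant-consistent peaks: `r < -0.5` against IC50 (more of the peak,
#' lower IC50, stronger scavenging) and `r > 0.5` against both capacity
#' assays. `dual` marks peaks satisfying all three.
#'
#' @param peaks A [peak_table()] (or matrix) with batches aligned to
#'   `activities`.
#' @param activities An [activity_table()].
#' @param neg_threshold,pos_threshold Flag thresholds (defaults -0.5 / 0.5).
#' @return List of class `"correlation_report"`: `r` (peaks x assays matrix;
#'   `NA` for constant vectors), `flags` (logical data.frame with columns
#'   `ic50_neg`, `abts_pos`, `frap_pos`, `dual`).
#' @export
pearson_matrix <- function(peaks, activities, neg_threshold = -0.5,
                           pos_threshold = 0.5) {
  x <- .as_area_matrix(peaks)
  stopifnot(inherits(activities, "activity_table"))
  if (nrow(x) < 3L) stop("need >= 3 aligned batches", call. = FALSE)
  if (!identical(rownames(x), activities$batch_ids)) {
    stop("peak table and activity table batch ids do not align", call. = FALSE)
  }
  assays <- cbind(dpph_ic50 = activities$dpph_ic50,
                  abts_taoc = activities$abts_taoc,
                  frap_taoc = activities$frap_taoc)
  r <- suppressWarnings(stats::cor(x, assays))  # NA for zero-variance pairs
  flags <- data.frame(
    ic50_neg = !is.na(r[, "dpph_ic50"]) & r[, "dpph_ic50"] < neg_threshold,
    abts_pos = !is.na(r[, "abts_taoc"]) & r[, "abts_taoc"] > pos_threshold,
    frap_pos = !is.na(r[, "frap_taoc"]) & r[, "frap_taoc"] > pos_threshold,
    row.names = colnames(x))
  flags$dual <- flags$ic50_neg & flags$abts_pos & flags$frap_pos
  structure(list(r = r, flags = flags,
                 thresholds = c(neg = neg_threshold, pos = pos_threshold)),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("<correlation_report> ", nrow(x$r), " peaks; ",
      sum(x$flags$dual), " dual-flagged\n", sep = "")
  invisible(x)
}

.gra_normalise <- function(v, normalization) {
  if (normalization == "minmax") {
    rng <- range(v)
    if (diff(rng) == 0) return(rep(0.5, length(v)))
    (v - rng[1]) / diff(rng)
  } else {
    m <- mean(v)
    if (m == 0) stop("zero-mean sequence under mean normalization",
                     call. = FALSE)
    v / m
  }
}

#' Grey relational degrees between activity and peak sequences
#'
#' Deng's grey relational analysis: sequences are normalised, per-point
#' deviations from the reference are taken, grey relational coefficients
#' `(d_min + rho * d_max) / (d_i(k) + rho * d_max)` are computed with the
#' global minimum/maximum deviation over all comparisons, and each peak's
#' degree is the mean coefficient over batches. A degree of 1 means the
#' normalised sequences coincide.
#'
#' @param reference Per-batch reference sequence (e.g. `1 / IC50` so that
#'   larger = more active, matching the capacity assays' direction).
#' @param comparisons Matrix or `peak_table` of peak areas (batches x
#'   peaks).
#' @param rho Resolution coefficient in (0, 1], default 0.5.
#' @param normalization `"minmax"` (default) or `"mean"`.
#' @param cutoff Selection cut-off on the degree (default 0.7).
#' @return List of class `"gra_report"`: `degrees` (named, in (0, 1]),
#'   `selected` (degrees >= cutoff, descending), `rho`, `normalization`.
#' @export
grey_relational_degrees <- function(reference, comparisons, rho = 0.5,
                                    normalization = c("minmax", "mean"),
                                    cutoff = 0.7) {
  normalization <- match.arg(normalization)
  stopifnot(rho > 0, rho <= 1)
  x <- .as_area_matrix(comparisons)
  if (length(reference) != nrow(x)) {
    stop("reference length must match the number of batches", call. = FALSE)
  }
  ref <- .gra_normalise(as.numeric(reference), normalization)
  comp <- apply(x, 2, .gra_normalise, normalization = normalization)
  dev <- abs(comp - ref)
  d_min <- min(dev)
  d_max <- max(dev)
  coef <- if (d_max == 0) {
    dev * 0 + 1          # all sequences coincide with the reference
  } else {
    (d_min + rho * d_max) / (dev + rho * d_max)
  }
  degrees <- colMeans(coef)
  structure(list(degrees = degrees,
                 selected = sort(degrees[degrees >= cutoff], decreasing = TRUE),
                 rho = rho, normalization = normalization, cutoff = cutoff),
            class = "gra_report")
}

#' @export
print.gra_report <- function(x, ...) {
  cat(sprintf("<gra_report> rho %.2f (%s); degrees %.4f-%.4f; %d selected at %.2f\n",
              x$rho, x$normalization, min(x$degrees), max(x$degrees),
              length(x$selected), x$cutoff))
  invisible(x)
}

#' Peak-area decrease after DPPH treatment
#'
#' The percent decrease `(control - treated) / control * 100` per peak,
#' averaged over replicate injections; a negative mean (within-noise
#' increase) is flagged rather than clipped.
#'
#' @param control,treated Matrices (replicates x peaks) or single rows of
#'   areas with matching peak columns.
#' @return List of class `"dpph_report"`: `decrease_percent` (named, ranked
#'   descending), `flagged_increase` (peaks with negative mean decrease),
#'   `undefined` (peaks with zero mean control area).
#' @examples
#' dpph_peak_decrease(rbind(c(A = 100)), rbind(c(A = 56.84)))  # 43.16 %
#' @export
dpph_peak_decrease <- function(control, treated) {
  ctl <- rbind(control)
  trt <- rbind(treated)
  if (!identical(colnames(ctl), colnames(trt))) {
    stop("control and treated must share peak ids", call. = FALSE)
  }
  mc <- colMeans(ctl)
  mt <- colMeans(trt)
  undef <- mc == 0
  dec <- ifelse(undef, NA_real_, (mc - mt) / mc * 100)
  names(dec) <- colnames(ctl)
  structure(list(decrease_percent = sort(dec[!undef], decreasing = TRUE),
                 flagged_increase = names(dec)[!undef & !is.na(dec) & dec < 0],
                 undefined = names(dec)[undef]),
            class = "dpph_report")
}

#' @export
print.dpph_report <- function(x, ...) {
  cat("<dpph_report> ", length(x$decrease_percent), " peaks; top decrease ",
      sprintf("%.2f%%", x$decrease_percent[1]), "\n", sep = "")
  invisible(x)
}

#' Consensus ranking of antioxidant constituents
#'
#' Peaks are ranked by the number of lines of evidence selecting them:
#' dual-direction Pearson flags, grey relational degree at or above its
#' cut-off, and a DPPH peak-area decrease above a percentile of all decreases
#' (default the 70th). Ties are broken by the DPPH decrease, then by the GRA
#' degree.
#'
#' @param correlation A [pearson_matrix()] report.
#' @param gra A [grey_relational_degrees()] report.
#' @param dpph A [dpph_peak_decrease()] report.
#' @param dpph_percentile Percentile (0-100) above which a decrease counts
#'   as supporting evidence.
#' @return data.frame with `peak`, `n_methods`, `pearson`, `gra`, `dpph`,
#'   `dpph_decrease`, `gra_degree`, sorted by `n_methods` then the
#'   tie-breaks; peaks selected by no method are omitted.
#' @export
consensus_antioxidants <- function(correlation, gra, dpph,
                                   dpph_percentile = 70) {
  peaks <- rownames(correlation$flags)
  if (!setequal(peaks, names(gra$degrees)) ||
      !all(names(dpph$decrease_percent) %in% peaks)) {
    stop("reports must cover the same peak ids", call. = FALSE)
  }
  dpph_cut <- stats::quantile(dpph$decrease_percent, dpph_percentile / 100,
                              names = FALSE)
  sel_p <- peaks[correlation$flags$dual]
  sel_g <- names(gra$selected)
  sel_d <- names(dpph$decrease_percent)[dpph$decrease_percent > dpph_cut]
  out <- data.frame(
    peak = peaks,
    pearson = peaks %in% sel_p,
    gra = peaks %in% sel_g,
    dpph = peaks %in% sel_d,
    dpph_decrease = dpph$decrease_percent[match(peaks,
                                                names(dpph$decrease_percent))],
    gra_degree = gra$degrees[peaks],
    stringsAsFactors = FALSE)
  out$n_methods <- out$pearson + out$gra + out$dpph
  out <- out[out$n_methods > 0, , drop = FALSE]
  out <- out[order(-out$n_methods, -out$dpph_decrease, -out$gra_degree), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
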