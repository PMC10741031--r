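# Seeded generators emulating the study design: 18 batches in 3 origin
# groups with group-specific dominant constituents, antioxidant activities in
# the published ranges, MS/MS spectra synthesised from library fragment
# lists, and paired DPPH control/treated tables.

#' The 23 common-peak record ids of the fingerprint
#'
#' Record ids of the 23 common constituents used as the fingerprint peak set.
#' @return Integer vector of library record ids.
#' @export
common_peak_ids <- function() {
  c(3L, 12L, 15L, 30L, 33L, 34L, 36L, 39L, 47L, 56L, 60L, 68L, 72L, 74L,
    80L, 86L, 89L, 95L, 97L, 107L, 110L, 118L, 121L)
}

#' Synthetic study design
#'
#' Encodes the emulated study: 18 batches in three groups (5 whole-fruit
#' batches S1-S5, 7 whole-fruit batches S6-S12, 6 fruit-flesh batches
#' S13-S18) over the 23 common peaks. Eight marker peaks discriminate the
#' groups (the hydrolyzable-tannin markers are depressed in group III, and
#' the group-III batches are enriched in three degradation-prone
#' constituents); six peaks are planted antioxidants whose weighted area sum
#' drives the activity assays; chebulagic acid dominates group I and
#' chebulinic acid group II.
#'
#' @param n_per_group Batches per group (default `c(5, 7, 6)`).
#' @param noise_cv Multiplicative (log-normal) noise coefficient of
#'   variation on areas (default 0.15).
#' @param baseline_area Mean area of an unremarkable peak (default 100).
#' @param seed Integer seed; every generator derives its randomness from it.
#' @return A list of class `"synthetic_design"` with the group mean profile
#'   matrix (`group_means`, 3 x 23), `planted_antioxidants`,
#'   `planted_markers` (VIP truth), `activity_weights`, `susceptibility`
#'   (DPPH truth) and the identifiers.
#' @export
synthetic_design <- function(n_per_group = c(5L, 7L, 6L), noise_cv = 0.15,
                             baseline_area = 100, seed = 1L) {
  stopifnot(length(n_per_group) == 3L, all(n_per_group >= 1L),
            noise_cv >= 0, baseline_area > 0)
  peaks <- paste0("P", common_peak_ids())
  mult <- matrix(1, nrow = 3, ncol = length(peaks),
                 dimnames = list(c("I", "II", "III"), peaks))
  markers <- paste0("P", c(3L, 47L, 60L, 68L, 72L, 95L, 97L, 107L))
  antiox <- paste0("P", c(60L, 68L, 72L, 95L, 97L, 107L))
  degradation <- paste0("P", c(3L, 47L))        # enriched in group-III flesh
  mult[, antiox] <- rep(c(3, 3, 0.4), length(antiox))
  mult["I", "P95"] <- 6      # chebulagic acid dominates group I
  mult["II", "P107"] <- 6    # chebulinic acid dominates group II
  mult[, degradation] <- rep(c(0.8, 0.5, 2.2), length(degradation))
  # group-I whole fruits run low in a second set of constituents, giving the
  # origin groups a multi-peak identity (as in real fingerprints)
  mult[, paste0("P", c(15L, 74L, 80L, 86L))] <- rep(c(0.3, 1, 1), 4L)
  weights <- stats::setNames(rep(1, length(antiox)), antiox)
  susceptibility <- stats::setNames(rep(0.05, length(peaks)), peaks)
  susceptibility[antiox] <- c(0.32, 0.30, 0.3148, 0.2718, 0.25, 0.2201)
  susceptibility["P47"] <- 0.4316
  susceptibility["P110"] <- 0.0869
  susceptibility["P12"] <- 0.0831
  susceptibility["P3"] <- 0.0419
  groups <- rep(c("I", "II", "III"), times = n_per_group)
  structure(list(
    n_per_group = n_per_group,
    batch_ids = paste0("S", seq_len(sum(n_per_group))),
    groups = stats::setNames(groups, paste0("S", seq_len(sum(n_per_group)))),
    peak_ids = peaks,
    group_means = mult * baseline_area,
    planted_antioxidants = antiox,
    planted_markers = markers,
    activity_weights = weights,
    susceptibility = susceptibility,
    noise_cv = noise_cv,
    seed = as.integer(seed)),
    class = "synthetic_design")
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat("<synthetic_design> ", length(x$batch_ids), " batches (",
      paste(x$n_per_group, collapse = "/"), "), ", length(x$peak_ids),
      " peaks, noise_cv ", x$noise_cv, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# mean-one multiplicative log-normal noise
.lognorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Generate a batch-by-peak area table from a design
#'
#' Areas are the group mean profiles under multiplicative log-normal noise
#' at the design's coefficient of variation. The same design (including its
#' seed) always yields a bit-identical table.
#'
#' @param design A [synthetic_design()].
#' @return List with `table` (a [peak_table()]) and `truth` (group labels,
#'   planted sets, the design itself).
#' @export
generate_peak_tables <- function(design = synthetic_design()) {
  set.seed(design$seed)
  n <- length(design$batch_ids)
  p <- length(design$peak_ids)
  mu <- design$group_means[design$groups, , drop = FALSE]
  areas <- mu * matrix(.lognorm_noise(n * p, design$noise_cv), n, p)
  dimnames(areas) <- list(design$batch_ids, design$peak_ids)
  tab <- peak_table(areas)
  truth <- list(groups = design$groups,
                planted_antioxidants = design$planted_antioxidants,
                planted_markers = design$planted_markers,
                design = design)
  list(table = tab, truth = truth)
}

#' Generate antioxidant activities from a peak table
#'
#' The total antioxidant capacities are rescalings of the weighted area sum
#' of the planted antioxidant peaks; the DPPH IC50 is a rescaling of its
#' reciprocal, mapped into the published inter-batch ranges
#' (IC50 2.993-10.110 ug/mL, ABTS up to 14.47 mmol/g, FRAP up to
#' 1.566 mmol/g), with multiplicative noise on top. With the default design
#' the group-III batches therefore have the highest IC50 (weakest
#' scavenging).
#'
#' @param table A [peak_table()] from [generate_peak_tables()].
#' @param design The generating design (supplies weights and seed).
#' @param noise_cv Assay noise coefficient of variation (default 0.03).
#' @param ic50_range,abts_range,frap_range Target ranges for the noiseless
#'   values.
#' @return An [activity_table()].
#' @export
generate_activities <- function(table, design = synthetic_design(),
                                noise_cv = 0.03,
                                ic50_range = c(2.993, 10.110),
                                abts_range = c(7.5, 14.47),
                                frap_range = c(0.75, 1.566)) {
  set.seed(design$seed + 1L)
  w <- design$activity_weights
  x <- .as_area_matrix(table)
  wsum <- as.numeric(x[, names(w), drop = FALSE] %*% w)
  rescale <- function(v, range) {
    if (diff(range(v)) == 0) return(rep(mean(range), length(v)))
    range[1] + (v - min(v)) / diff(range(v)) * diff(range)
  }
  n <- nrow(x)
  ic50 <- rescale(1 / wsum, ic50_range) * .lognorm_noise(n, noise_cv)
  abts <- rescale(wsum, abts_range) * .lognorm_noise(n, noise_cv)
  frap <- rescale(wsum, frap_range) * .lognorm_noise(n, noise_cv)
  activity_table(rownames(x), ic50, abts, frap)
}

#' Synthesise MS/MS spectra from library fragment lists
#'
#' Each record yields one spectrum titled `LIB-<id>`: its printed fragments
#' (de-duplicated) as peaks with a geometrically decaying intensity profile
#' (the first-listed fragment most intense), Gaussian m/z jitter of
#' `fragment_noise_sd`, the observed precursor m/z (not jittered -- precursor
#' centroids are far better determined than fragment peaks), retention time
#' and, when available, the measured CCS. Decoy spectra draw uniformly
#' random peaks.
#'
#' @param records Library data.frame (default: full packaged library).
#' @param n_decoys Number of decoy spectra (default 0).
#' @param fragment_noise_sd Fragment m/z jitter SD in Da (default 0.002).
#' @param seed Integer seed.
#' @return List with `spectra` (list of [msms_spectrum()]) and `truth`
#'   (data.frame `spectrum_id`, `record_id`, `class`; decoys have record id
#'   `NA`).
#' @export
generate_spectra <- function(records = load_library(), n_decoys = 0L,
                             fragment_noise_sd = 0.002, seed = 1L) {
  set.seed(seed)
  spectra <- vector("list", nrow(records) + n_decoys)
  truth <- data.frame(spectrum_id = character(nrow(records) + n_decoys),
                      record_id = NA_integer_, class = NA_character_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(records))) {
    fr <- records$fragments[[i]]
    fr <- fr[!duplicated(round(fr, 6))]
    intens <- 1000 * 0.75^(seq_along(fr) - 1)
    mz <- fr + stats::rnorm(length(fr), 0, fragment_noise_sd)
    id <- sprintf("LIB-%03d", records$id[i])
    spectra[[i]] <- msms_spectrum(id, records$observed_mz[i], mz, intens,
                                  rt = records$rt_min[i],
                                  ccs = records$measured_ccs[i])
    truth$spectrum_id[i] <- id
    truth$record_id[i] <- records$id[i]
    truth$class[i] <- records$class[i]
  }
  for (d in seq_len(n_decoys)) {
    prec <- stats::runif(1, 200, 1100)
    k <- sample(6:12, 1)
    mz <- sort(stats::runif(k, 50, prec - 1))
    id <- sprintf("DECOY-%03d", d)
    spectra[[nrow(records) + d]] <-
      msms_spectrum(id, prec, mz, 1000 * 0.75^(seq_len(k) - 1))
    truth$spectrum_id[nrow(records) + d] <- id
  }
  list(spectra = spectra, truth = truth)
}

#' Generate a paired DPPH control/treated replicate set
#'
#' The treated mean area of each peak is the control mean scaled by
#' `1 - susceptibility`; replicate noise is multiplicative log-normal.
#'
#' @param areas Named numeric vector of control mean areas (one batch row of
#'   a [peak_table()]).
#' @param susceptibility Named vector in `[0, 1]` over the same peaks
#'   (default: the design's truth).
#' @param replicates Number of replicate injections (default 6).
#' @param noise_cv Replicate noise CV (default 0.05).
#' @param seed Integer seed.
#' @return List with matrices `control` and `treated`
#'   (replicates x peaks) and the `susceptibility` truth.
#' @export
generate_dpph_pair <- function(areas,
                               susceptibility = synthetic_design()$susceptibility,
                               replicates = 6L, noise_cv = 0.05, seed = 1L) {
  stopifnot(all(susceptibility >= 0), all(susceptibility <= 1))
  susceptibility <- susceptibility[names(areas)]
  set.seed(seed + 2L)
  p <- length(areas)
  noise <- function() matrix(.lognorm_noise(replicates * p, noise_cv),
                             replicates, p)
  ctl <- matrix(areas, replicates, p, byrow = TRUE) * noise()
  trt <- matrix(areas * (1 - susceptibility), replicates, p, byrow = TRUE) *
    noise()
  colnames(ctl) <- colnames(trt) <- names(areas)
  list(control = ctl, treated = trt, susceptibility = susceptibility)
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper producing aligned peak areas, activities and a DPPH
#' control/treated pair (for the most active batch) from one design.
#'
#' @param design A [synthetic_design()].
#' @return List with `peaks`, `activities`, `dpph`, `truth`.
#' @export
simulate_study <- function(design = synthetic_design()) {
  gen <- generate_peak_tables(design)
  act <- generate_activities(gen$table, design)
  best <- gen$truth$groups == "I"
  row <- gen$table$areas[which(best)[1], ]
  dpph <- generate_dpph_pair(row, design$susceptibility, seed = design$seed)
  list(peaks = gen$table, activities = act, dpph = dpph, truth = gen$truth)
}
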