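# MS/MS spectra and Mascot Generic Format interchange.

#' Construct an MS/MS spectrum
#'
#' @param spectrum_id Character id (unique within a run).
#' @param precursor_mz Precursor m/z (> 0).
#' @param mz,intensity Parallel numeric vectors of fragment peaks; peaks are
#'   stored sorted by m/z and must have strictly increasing m/z after sorting
#'   (no exact duplicates) and finite non-negative intensities.
#' @param rt Retention time in minutes, or `NA`.
#' @param ccs Optional measured collision cross-section in squared Angstrom,
#'   or `NA` when the spectrum was not ion-mobility resolved.
#' @return An object of class `"msms_spectrum"`.
#' @export
msms_spectrum <- function(spectrum_id, precursor_mz, mz, intensity,
                          rt = NA_real_, ccs = NA_real_) {
  stopifnot(length(mz) == length(intensity), length(mz) >= 1L,
            is.numeric(precursor_mz), precursor_mz > 0)
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  ord <- order(mz)
  mz <- as.numeric(mz[ord])
  intensity <- as.numeric(intensity[ord])
  if (any(diff(mz) <= 0)) stop("peak m/z must be strictly increasing", call. = FALSE)
  structure(list(spectrum_id = as.character(spectrum_id),
                 precursor_mz = as.numeric(precursor_mz),
                 rt = as.numeric(rt), ccs = as.numeric(ccs),
                 mz = mz, intensity = intensity),
            class = "msms_spectrum")
}

#' @export
print.msms_spectrum <- function(x, ...) {
  cat("<msms_spectrum> ", x$spectrum_id, ": precursor ",
      sprintf("%.4f", x$precursor_mz), ", ", length(x$mz), " peaks",
      if (!is.na(x$rt)) sprintf(", rt %.2f min", x$rt) else "", "\n", sep = "")
  invisible(x)
}

#' Read spectra from a Mascot Generic Format file
#'
#' One spectrum per `BEGIN IONS`/`END IONS` block. `PEPMASS` is required;
#' `TITLE` supplies the spectrum id (sequential ids are generated otherwise);
#' `RTINSECONDS` (converted to minutes) or `RTINMINUTES` sets the retention
#' time; an optional `CCS` header is kept for ion-mobility workflows.
#'
#' @param path Path to an MGF file.
#' @return A list of [msms_spectrum()] objects.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[i])
    if (identical(line, "BEGIN IONS")) {
      hdr <- list()
      mzs <- numeric(0)
      ints <- numeric(0)
      j <- i + 1L
      closed <- FALSE
      while (j <= n) {
        l <- trimws(lines[j])
        if (identical(l, "END IONS")) { closed <- TRUE; break }
        if (identical(l, "BEGIN IONS")) break
        if (nzchar(l) && !startsWith(l, "#")) {
          if (grepl("=", l, fixed = TRUE)) {
            key <- toupper(sub("=.*$", "", l))
            hdr[[key]] <- sub("^[^=]*=", "", l)
          } else {
            fields <- strsplit(l, "[ \t]+")[[1]]
            v <- suppressWarnings(as.numeric(fields))
            if (length(v) < 2L || any(is.na(v[1:2]))) {
              stop("malformed peak line ", j, " in ", path, ": '", l, "'",
                   call. = FALSE)
            }
            mzs <- c(mzs, v[1])
            ints <- c(ints, v[2])
          }
        }
        j <- j + 1L
      }
      if (!closed) stop("unterminated BEGIN IONS block starting at line ", i,
                        " in ", path, call. = FALSE)
      if (is.null(hdr$PEPMASS)) {
        stop("block at line ", i, " in ", path, " lacks PEPMASS", call. = FALSE)
      }
      pep <- suppressWarnings(as.numeric(strsplit(trimws(hdr$PEPMASS),
                                                  "[ \t]+")[[1]][1]))
      if (is.na(pep)) stop("unreadable PEPMASS at line ", i, " in ", path,
                           call. = FALSE)
      rt <- NA_real_
      if (!is.null(hdr$RTINSECONDS)) rt <- as.numeric(hdr$RTINSECONDS) / 60
      if (!is.null(hdr$RTINMINUTES)) rt <- as.numeric(hdr$RTINMINUTES)
      ccs <- if (!is.null(hdr$CCS)) as.numeric(hdr$CCS) else NA_real_
      id <- if (!is.null(hdr$TITLE)) trimws(hdr$TITLE) else
        sprintf("spectrum_%d", length(spectra) + 1L)
      if (!length(mzs)) stop("block at line ", i, " in ", path,
                             " has no peaks", call. = FALSE)
      spectra[[length(spectra) + 1L]] <-
        msms_spectrum(id, pep, mzs, ints, rt = rt, ccs = ccs)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  spectra
}

#' Write spectra to a Mascot Generic Format file
#'
#' @param spectra A list of [msms_spectrum()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s$spectrum_id), con)
    writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    if (!is.na(s$rt)) writeLines(sprintf("RTINMINUTES=%.4f", s$rt), con)
    if (!is.na(s$ccs)) writeLines(sprintf("CCS=%.4f", s$ccs), con)
    writeLines("CHARGE=1-", con)
    writeLines(sprintf("%.6f %.6f", s$mz, s$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}
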