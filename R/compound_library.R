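# The packaged in-house compound library (122 constituents of Chebulae
# Fructus) and mass- and fragment-based search over it.

.LIBRARY_CLASSES <- c("other", "phenolcarboxylic acid", "gallotannin",
                      "ellagitannin", "chebulic ellagitannin", "flavonoid",
                      "triterpenoid")

.library_cache <- new.env(parent = emptyenv())

#' Load the in-house compound library
#'
#' Reads the packaged library of 122 constituents (phenolcarboxylic acids,
#' gallotannins, ellagitannins, chebulic ellagitannins, flavonoids,
#' triterpenoids and three unclassed early-eluting records), or a user file in
#' the same JSON schema. The packaged library preserves the source table
#' verbatim, including absent collision cross-sections (stored as `NA`) and
#' duplicated network-node names; no cleaning is applied.
#'
#' @param source Path to a JSON library, or `NULL` (default) for the packaged
#'   library.
#' @return A data.frame with one row per record: `id`, `name`, `rt_min`,
#'   `ion_formula`, `species`, `observed_mz`, `mass_error_ppm`,
#'   `measured_ccs`, `predicted_ccs`, `fragments` (list column of m/z
#'   vectors), `class`, `standard`.
#' @examples
#' lib <- load_library()
#' table(lib$class)
#' @export
load_library <- function(source = NULL) {
  packaged <- is.null(source)
  if (packaged) {
    if (!is.null(.library_cache$default)) return(.library_cache$default)
    source <- system.file("extdata", "cf_library.json", package = "cftannin",
                          mustWork = TRUE)
  }
  if (!file.exists(source)) stop("library file not found: ", source, call. = FALSE)
  raw <- jsonlite::fromJSON(source, simplifyDataFrame = TRUE)
  rec <- raw$records
  if (is.null(rec)) stop("library JSON must have a top-level 'records' array",
                         call. = FALSE)
  lib <- data.frame(
    id = as.integer(rec$id),
    name = as.character(rec$name),
    rt_min = as.numeric(rec$rt_min),
    ion_formula = as.character(rec$ion_formula),
    species = as.character(rec$species),
    observed_mz = as.numeric(rec$observed_mz),
    mass_error_ppm = as.numeric(rec$mass_error_ppm),
    measured_ccs = as.numeric(rec$measured_ccs),
    predicted_ccs = as.numeric(rec$predicted_ccs),
    class = as.character(rec$class),
    standard = as.logical(rec$standard),
    stringsAsFactors = FALSE
  )
  lib$fragments <- lapply(rec$fragments, as.numeric)
  validate_library(lib)
  lib <- lib[order(lib$id), , drop = FALSE]
  rownames(lib) <- NULL
  if (packaged) .library_cache$default <- lib
  lib
}

#' Validate a compound-library data.frame
#'
#' Fatal, row-naming checks: unique ids, positive retention times, known class
#' labels and species, parseable ion formulas, non-empty fragment lists.
#'
#' @param lib A library data.frame as returned by [load_library()].
#' @return `lib`, invisibly, if valid.
#' @export
validate_library <- function(lib) {
  dup <- lib$id[duplicated(lib$id)]
  if (length(dup)) {
    stop("duplicate record id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_class <- which(!lib$class %in% .LIBRARY_CLASSES)
  if (length(bad_class)) {
    stop("unknown class label '", lib$class[bad_class[1]], "' at record id ",
         lib$id[bad_class[1]], call. = FALSE)
  }
  bad_rt <- which(!(lib$rt_min > 0))
  if (length(bad_rt)) {
    stop("non-positive retention time at record id ", lib$id[bad_rt[1]],
         call. = FALSE)
  }
  empty <- which(!vapply(lib$fragments, length, integer(1)))
  if (length(empty)) {
    stop("empty fragment list at record id ", lib$id[empty[1]], call. = FALSE)
  }
  for (i in seq_len(nrow(lib))) {
    tryCatch(parse_formula(lib$ion_formula[i]), error = function(e) {
      stop("record id ", lib$id[i], ": ", conditionMessage(e), call. = FALSE)
    })
    ion_species(lib$species[i])
  }
  invisible(lib)
}

#' Search the library by precursor m/z
#'
#' @param mz Query precursor m/z.
#' @param tol_ppm Tolerance in ppm (default 10).
#' @param library A library data.frame (default: packaged).
#' @return A data.frame of hits (library columns plus `ppm_deviation` and
#'   `rank`), sorted by absolute ppm deviation, ties broken by record id.
#'   Zero-row frame if nothing matches.
#' @examples
#' search_precursor(1083.0608)$name  # the two punicalagin isomers
#' @export
search_precursor <- function(mz, tol_ppm = 10, library = load_library()) {
  stopifnot(is.numeric(mz), length(mz) == 1L, tol_ppm > 0)
  dev <- (mz - library$observed_mz) / library$observed_mz * 1e6
  keep <- which(abs(dev) <= tol_ppm)
  hits <- library[keep, , drop = FALSE]
  hits$ppm_deviation <- dev[keep]
  ord <- order(abs(hits$ppm_deviation), hits$id)
  hits <- hits[ord, , drop = FALSE]
  hits$rank <- seq_len(nrow(hits))
  rownames(hits) <- NULL
  hits
}

# number of query fragments matched by a record's fragment list
.shared_fragments <- function(query, frags, tol) {
  sum(vapply(query, function(q) any(abs(frags - q) <= tol), logical(1)))
}

#' Search the library by MS/MS fragments
#'
#' Records sharing at least `min_shared` fragment m/z values with the query
#' (within `tol` Da) are returned, ranked by shared-fragment count; ties are
#' broken by absolute precursor deviation when `precursor_mz` is given, then
#' by record id.
#'
#' @param query_fragments Numeric vector of fragment m/z (non-empty).
#' @param tol Fragment tolerance in Da (default 0.01).
#' @param min_shared Minimum number of shared fragments (default 1).
#' @param library A library data.frame.
#' @param precursor_mz Optional query precursor for tie-breaking.
#' @return data.frame of hits with `shared_count`, `ppm_deviation` (NA when
#'   no precursor given) and `rank`.
#' @export
search_fragments <- function(query_fragments, tol = 0.01, min_shared = 1L,
                             library = load_library(), precursor_mz = NULL) {
  if (!length(query_fragments)) stop("empty fragment query", call. = FALSE)
  stopifnot(tol > 0, min_shared >= 1L)
  shared <- vapply(library$fragments, function(fr) {
    .shared_fragments(query_fragments, fr, tol)
  }, numeric(1))
  keep <- which(shared >= min_shared)
  hits <- library[keep, , drop = FALSE]
  hits$shared_count <- shared[keep]
  hits$ppm_deviation <- if (is.null(precursor_mz)) {
    NA_real_
  } else {
    (precursor_mz - hits$observed_mz) / hits$observed_mz * 1e6
  }
  tie <- if (is.null(precursor_mz)) rep(0, nrow(hits)) else abs(hits$ppm_deviation)
  ord <- order(-hits$shared_count, tie, hits$id)
  hits <- hits[ord, , drop = FALSE]
  hits$rank <- seq_len(nrow(hits))
  rownames(hits) <- NULL
  hits
}

#' Write / read a library as flat CSV
#'
#' CSV flattening keeps the ragged fragment lists as a semicolon-joined
#' column; `read_library_csv()` restores the JSON-equivalent data.frame.
#'
#' @param lib A library data.frame.
#' @param path Output (input) CSV path.
#' @return `path` invisibly; `read_library_csv()` returns the library.
#' @export
write_library_csv <- function(lib, path) {
  flat <- lib[setdiff(names(lib), "fragments")]
  flat$fragments <- vapply(lib$fragments, paste, character(1), collapse = ";")
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_library_csv
#' @export
read_library_csv <- function(path) {
  flat <- utils::read.csv(path, stringsAsFactors = FALSE)
  flat$fragments <- lapply(strsplit(as.character(flat$fragments), ";", fixed = TRUE),
                           as.numeric)
  validate_library(flat)
  flat
}
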