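# Elemental-formula parsing, monoisotopic mass and adduct m/z arithmetic for
# negative-mode ESI work on phenolcarboxylic acids and hydrolyzable tannins.

# Most-abundant-isotope atomic masses, IUPAC/CODATA recommended values
# (12C exact by definition; others to >= 8 decimal places).
.MONOISOTOPIC <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.00307400480,
  O = 15.99491461956,
  S = 31.97207100000
)

#' Parse an elemental formula in Hill notation
#'
#' Accepts element-count pairs such as `"C7H5O5"`; a missing count means one
#' atom. Only the elements relevant to plant polyphenols (C, H, N, O, S) are
#' recognised; anything else is an error naming the offending token.
#'
#' @param text A single formula string, e.g. `"C41H29O27"`.
#' @return A named integer vector of element counts with class
#'   `"elemental_formula"`. `format()` renders it back to a canonical
#'   Hill-order string (C first, then H, then remaining elements
#'   alphabetically), so parsing round-trips losslessly.
#' @examples
#' parse_formula("C7H5O5")
#' format(parse_formula("H2O"))
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("formula must be a single non-empty string", call. = FALSE)
  }
  tokens <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (!identical(paste0(tokens, collapse = ""), text)) {
    bad <- sub(paste0("^", paste0(gsub("([\\^$.|?*+()\\[\\]{}])", "\\\\\\1", tokens),
                                  collapse = "")), "", text)
    stop("cannot parse formula '", text, "': unexpected token near '",
         substr(bad, 1, 4), "'", call. = FALSE)
  }
  counts <- integer(0)
  for (tok in tokens) {
    elem <- sub("[0-9]*$", "", tok)
    n_str <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n_str)) as.integer(n_str) else 1L
    if (!elem %in% names(.MONOISOTOPIC)) {
      stop("unknown element symbol '", elem, "' in formula '", text, "'",
           call. = FALSE)
    }
    if (n <= 0L) {
      stop("zero count for element '", elem, "' in formula '", text, "'",
           call. = FALSE)
    }
    counts[elem] <- (if (elem %in% names(counts)) counts[[elem]] else 0L) + n
  }
  if (sum(counts) < 1L) stop("formula '", text, "' has no atoms", call. = FALSE)
  structure(counts, class = "elemental_formula")
}

#' @export
format.elemental_formula <- function(x, ...) {
  counts <- unclass(x)
  hill <- c(intersect(c("C", "H"), names(counts)),
            sort(setdiff(names(counts), c("C", "H"))))
  paste0(vapply(hill, function(e) {
    paste0(e, if (counts[[e]] > 1L) counts[[e]] else "")
  }, character(1)), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula> ", format(x), "\n", sep = "")
  invisible(x)
}

as_formula <- function(f) {
  if (inherits(f, "elemental_formula")) f else parse_formula(f)
}

#' Monoisotopic mass of a formula
#'
#' Sum of most-abundant-isotope atomic masses, in Da. No electron-mass
#' correction is applied anywhere in this package: the theoretical m/z of an
#' anion is the plain monoisotopic mass of its (already deprotonated) ion
#' formula, which is the convention that reproduces the mass errors reported
#' for the reference constituents (e.g. gallic acid `[M-H]-` at 169.0137).
#'
#' @param f An `elemental_formula` or a formula string.
#' @return Mass in Da (full double precision; display rounding is the
#'   caller's business).
#' @examples
#' monoisotopic_mass("C7H5O5") # deprotonated gallic acid, 169.0137
#' @export
monoisotopic_mass <- function(f) {
  counts <- unclass(as_formula(f))
  sum(.MONOISOTOPIC[names(counts)] * counts)
}

.PROTON <- 1.00782503207   # H atom; see monoisotopic_mass() for the convention
.FORMIC <- 12.0 + 2 * 1.00782503207 + 2 * 15.99491461956  # HCOOH

# label -> (n neutral molecules, charge magnitude, mass delta applied to n*M)
.SPECIES <- list(
  "[M-H]-"        = list(n = 1L, z = 1L, delta = -.PROTON),
  "[2M-H]-"       = list(n = 2L, z = 1L, delta = -.PROTON),
  "[M-2H]2-"      = list(n = 1L, z = 2L, delta = -2 * .PROTON),
  "[M+HCOOH-H]-"  = list(n = 1L, z = 1L, delta = .FORMIC - .PROTON)
)

#' Negative-mode ion species
#'
#' Constructor for the four quasi-molecular/adduct species observed for these
#' constituents: the deprotonated molecule `[M-H]-`, its proton-bound dimer
#' `[2M-H]-`, the doubly deprotonated `[M-2H]2-`, and the formate adduct
#' `[M+HCOOH-H]-`.
#'
#' @param label One of `"[M-H]-"`, `"[2M-H]-"`, `"[M-2H]2-"`,
#'   `"[M+HCOOH-H]-"`.
#' @return An object of class `"ion_species"` with fields `label`,
#'   `multimer_count` (n), `charge_magnitude` (z) and `delta_mass` (Da applied
#'   to n neutral molecules).
#' @export
ion_species <- function(label) {
  if (inherits(label, "ion_species")) return(label)
  if (!is.character(label) || length(label) != 1L || !label %in% names(.SPECIES)) {
    stop("unknown ion species '", paste(label, collapse = ","),
         "'; expected one of: ", paste(names(.SPECIES), collapse = ", "),
         call. = FALSE)
  }
  s <- .SPECIES[[label]]
  structure(list(label = label, multimer_count = s$n,
                 charge_magnitude = s$z, delta_mass = s$delta),
            class = "ion_species")
}

#' @export
print.ion_species <- function(x, ...) {
  cat("<ion_species> ", x$label, " (n=", x$multimer_count,
      ", z=", x$charge_magnitude, ")\n", sep = "")
  invisible(x)
}

#' Theoretical m/z of a tabulated ion formula
#'
#' The compound table stores the formula of the ion as observed (already
#' deprotonated or adducted), so the theoretical m/z is simply its
#' monoisotopic mass divided by the charge magnitude.
#'
#' @param ion_formula Formula of the ion (string or `elemental_formula`).
#' @param species An [ion_species()] or its label; only the charge is used.
#'   Default `"[M-H]-"`.
#' @return m/z in Th.
#' @examples
#' ion_mz("C7H5O5")                 # 169.0137
#' ion_mz("C41H28O27", "[M-2H]2-")  # doubly charged chebulagic species
#' @export
ion_mz <- function(ion_formula, species = "[M-H]-") {
  sp <- ion_species(species)
  if (sp$charge_magnitude < 1L) stop("charge must be >= 1", call. = FALSE)
  monoisotopic_mass(ion_formula) / sp$charge_magnitude
}

#' Convert an observed m/z between ion species of the same molecule
#'
#' Recovers the neutral monoisotopic mass from the observed species (undo the
#' charge, subtract the species mass delta, undo the multimer count) and
#' reapplies the target species. Useful for recognising that, e.g., a node at
#' m/z 1303.18 is the `[2M-H]-` of a compound whose `[M-H]-` sits at 651.08.
#'
#' @param observed_mz Observed m/z under `from_species`.
#' @param from_species,to_species [ion_species()] objects or labels.
#' @return Expected m/z under `to_species`.
#' @examples
#' expected_species_mz(651.0839, "[M-H]-", "[2M-H]-")   # 1303.1756
#' expected_species_mz(953.0911, "[M-H]-", "[M-2H]2-")  # 476.0416
#' @export
expected_species_mz <- function(observed_mz, from_species, to_species) {
  from <- ion_species(from_species)
  to <- ion_species(to_species)
  stopifnot(is.numeric(observed_mz), observed_mz > 0)
  neutral <- (observed_mz * from$charge_magnitude - from$delta_mass) /
    from$multimer_count
  (neutral * to$multimer_count + to$delta_mass) / to$charge_magnitude
}

#' Signed mass error in parts per million
#'
#' @param observed,theoretical m/z values; `theoretical` must be positive.
#' @return `(observed - theoretical) / theoretical * 1e6`. Report at 1 d.p.
#'   for display, as in the compound table.
#' @examples
#' round(ppm_error(169.0145, ion_mz("C7H5O5")), 1) # 4.7
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive", call. = FALSE)
  (observed - theoretical) / theoretical * 1e6
}

#' Default catalogue of biosynthetic mass differences
#'
#' The homolog modifications repeatedly invoked for this constituent class:
#' methylation, dehydration, decarboxylation, ketene (C2H2O) loss,
#' galloylation as a residue (+152.0110) or as gallic acid (+170.0215), and
#' hexosylation (+162.0528 residue). All deltas are exact elemental values;
#' multiplicity is capped at 5 by default.
#'
#' @param path Optional path to a JSON catalogue
#'   (`[{name, delta_mass, max_multiplicity}, ...]`) replacing the default.
#' @return A data.frame with columns `name`, `delta_mass`, `max_multiplicity`.
#' @export
mass_delta_catalog <- function(path = NULL) {
  if (!is.null(path)) {
    cat <- jsonlite::fromJSON(path)
    stopifnot(all(c("name", "delta_mass", "max_multiplicity") %in% names(cat)))
    return(data.frame(name = as.character(cat$name),
                      delta_mass = as.numeric(cat$delta_mass),
                      max_multiplicity = as.integer(cat$max_multiplicity),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    name = c("methylation", "dehydration", "decarboxylation", "ketene loss",
             "galloylation", "gallate addition", "hexosylation"),
    delta_mass = c(14.0156500, -18.0105646, -43.9898292, -42.0105646,
                   152.0110393, 170.0215039, 162.0528234),
    max_multiplicity = 5L,
    stringsAsFactors = FALSE
  )
}

#' Explain a mass difference as multiples of catalogued modifications
#'
#' Every (modification, multiplicity k) whose `k * delta_mass` lies within
#' `tol` of `delta` is returned, sorted by absolute residual. An empty frame
#' means the difference is left unannotated rather than guessed.
#'
#' @param delta Observed mass difference in Da (signed).
#' @param catalog A catalogue from [mass_delta_catalog()].
#' @param tol Matching tolerance in Da (default 0.01, the fragment tolerance
#'   used throughout).
#' @return data.frame with columns `name`, `multiplicity`, `expected_delta`,
#'   `residual`.
#' @examples
#' annotate_mass_difference(14.016)  # methylation x1
#' annotate_mass_difference(56.062)  # methylation x4
#' @export
annotate_mass_difference <- function(delta, catalog = mass_delta_catalog(),
                                     tol = 0.01) {
  stopifnot(tol > 0)
  out <- list()
  for (i in seq_len(nrow(catalog))) {
    ks <- seq_len(catalog$max_multiplicity[i])
    expd <- ks * catalog$delta_mass[i]
    hit <- abs(expd - delta) <= tol
    if (any(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        name = catalog$name[i], multiplicity = ks[hit],
        expected_delta = expd[hit], residual = expd[hit] - delta,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(name = character(0), multiplicity = integer(0),
                      expected_delta = numeric(0), residual = numeric(0)))
  }
  res <- do.call(rbind, out)
  res[order(abs(res$residual)), , drop = FALSE]
}
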