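# Diagnostic-fragment classification of phenolcarboxylic/tannic classes,
# homolog inference, CCS comparison and evidence integration.

.TANNIC_CLASSES <- c("phenolcarboxylic acid", "gallotannin", "ellagitannin",
                     "chebulic ellagitannin")

.rule <- function(rule_id, priority, implied_class, marker_ions = numeric(0),
                  min_markers = 0L, companion_ions = numeric(0),
                  min_companions = 0L, neutral_losses = numeric(0),
                  precursor_min = -Inf, precursor_max = Inf) {
  stopifnot(all(marker_ions > 0), implied_class %in% c(.TANNIC_CLASSES,
                                                       "unclassified"))
  structure(list(rule_id = rule_id, priority = priority,
                 implied_class = implied_class, marker_ions = marker_ions,
                 min_markers = as.integer(min_markers),
                 companion_ions = companion_ions,
                 min_companions = as.integer(min_companions),
                 neutral_losses = neutral_losses,
                 precursor_min = precursor_min, precursor_max = precursor_max),
            class = "diagnostic_rule")
}

#' Default diagnostic fragmentation rules
#'
#' The rule set encodes the cleavage behaviour of the reference constituents:
#'
#' * chebuloyl ions at m/z 337.0201 with the methyl/dimethyl ester homologs
#'   351.0357/365.0514 and the dehydrated 319.0090, or the
#'   dehydration/decarboxylation cascade ions 293.0303/275.0200 accompanied
#'   by the 205.0506 companion, or (for chebulic-acid polyol esters) two or
#'   more of the chebulic-acid ester ions 205.0506/193.0141/163.0398/
#'   133.0656/249.0401 at precursors of at least 450, imply a chebulic
#'   ellagitannin;
#' * hexahydroxydiphenoyl (HHDP) chemistry -- the ellagic anion 300.9990, the
#'   flavogallonic 450.9940 or the HHDP-glucose 481.0663 -- implies an
#'   ellagitannin;
#' * galloyl ions (169.0137 gallate, 125.0243 pyrogallol) together with
#'   galloylglucose core ions 313.0565/271.0459/211.0243 or with neutral
#'   losses of a galloyl residue (152.0110), gallic acid (170.0215), ketene
#'   (42.0106) or a hexosyl residue (162.0528) from the precursor imply a
#'   gallotannin;
#' * galloyl ions with the shikimate ion 93.0344 imply a galloylshikimic
#'   phenolcarboxylic acid; the ellagic-core ion 145.0294, the pyrogallol
#'   radical pair 124.0166/78.0113, galloyl ions at small precursors
#'   (< 550) and chebulic-acid ions at very small precursors (< 450) imply
#'   free phenolcarboxylic acids.
#'
#' Priorities nest the classes (chebuloyl before HHDP before galloyl), since
#' chebulic ellagitannins also show HHDP and galloyl ions.
#'
#' @return A list of `diagnostic_rule` objects, ordered by priority.
#' @export
default_diagnostic_rules <- function() {
  galloyl <- c(169.0137, 125.0243)
  chebulic_companions <- c(205.0506, 193.0141, 163.0398, 133.0656, 249.0401)
  list(
    .rule("chebuloyl_direct", 1L, "chebulic ellagitannin",
          marker_ions = c(337.0201, 351.0357, 365.0514, 319.0090),
          min_markers = 1L),
    .rule("chebuloyl_cascade", 2L, "chebulic ellagitannin",
          marker_ions = c(293.0303, 275.0200), min_markers = 1L,
          companion_ions = 205.0506, min_companions = 1L),
    .rule("chebulic_ester", 3L, "chebulic ellagitannin",
          marker_ions = chebulic_companions, min_markers = 2L,
          precursor_min = 450),
    .rule("hhdp", 4L, "ellagitannin",
          marker_ions = c(300.9990, 450.9940, 481.0663), min_markers = 1L),
    .rule("galloylshikimic", 5L, "phenolcarboxylic acid",
          marker_ions = galloyl, min_markers = 1L,
          companion_ions = 93.0344, min_companions = 1L),
    .rule("gallotannin_core", 6L, "gallotannin",
          marker_ions = galloyl, min_markers = 1L,
          companion_ions = c(313.0565, 271.0459, 211.0243),
          min_companions = 1L),
    .rule("gallotannin_loss", 7L, "gallotannin",
          marker_ions = galloyl, min_markers = 1L,
          neutral_losses = c(152.0110, 170.0215, 42.0106, 162.0528)),
    .rule("ellagic_core_phenolic", 8L, "phenolcarboxylic acid",
          marker_ions = 145.0294, min_markers = 1L),
    .rule("pyrogallol_phenolic", 9L, "phenolcarboxylic acid",
          marker_ions = c(124.0166, 78.0113), min_markers = 2L),
    .rule("galloyl_small", 10L, "phenolcarboxylic acid",
          marker_ions = galloyl, min_markers = 1L, precursor_max = 550),
    .rule("chebulic_small", 11L, "phenolcarboxylic acid",
          marker_ions = chebulic_companions, min_markers = 1L,
          precursor_max = 450)
  )
}

#' Read / write diagnostic rules as JSON
#'
#' @param rules A list of rules (as from [default_diagnostic_rules()]).
#' @param path JSON path.
#' @return `read_rules()` returns the rule list; `write_rules()` the path,
#'   invisibly.
#' @export
write_rules <- function(rules, path) {
  jsonlite::write_json(lapply(rules, unclass), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  rules <- lapply(raw, function(r) {
    .rule(r$rule_id, as.integer(r$priority), r$implied_class,
          marker_ions = as.numeric(unlist(r$marker_ions)),
          min_markers = r$min_markers,
          companion_ions = as.numeric(unlist(r$companion_ions)),
          min_companions = r$min_companions,
          neutral_losses = as.numeric(unlist(r$neutral_losses)),
          precursor_min = if (is.null(r$precursor_min)) -Inf else
            ifelse(is.character(r$precursor_min), -Inf, r$precursor_min),
          precursor_max = if (is.null(r$precursor_max)) Inf else
            ifelse(is.character(r$precursor_max), Inf, r$precursor_max))
  })
  rules[order(vapply(rules, `[[`, integer(1), "priority"))]
}

.count_matches <- function(fragments, ions, tol) {
  if (!length(ions)) return(0L)
  sum(vapply(ions, function(m) any(abs(fragments - m) <= tol), logical(1)))
}

.rule_fires <- function(rule, fragments, precursor, tol) {
  if (is.na(precursor)) {
    if (is.finite(rule$precursor_min) || is.finite(rule$precursor_max) ||
        length(rule$neutral_losses)) {
      return(FALSE)
    }
  } else {
    if (precursor < rule$precursor_min || precursor > rule$precursor_max) {
      return(FALSE)
    }
  }
  if (.count_matches(fragments, rule$marker_ions, tol) < rule$min_markers) {
    return(FALSE)
  }
  if (rule$min_markers == 0L && length(rule$marker_ions) &&
      .count_matches(fragments, rule$marker_ions, tol) < 1L) {
    return(FALSE)
  }
  if (.count_matches(fragments, rule$companion_ions, tol) < rule$min_companions) {
    return(FALSE)
  }
  if (length(rule$neutral_losses)) {
    # a genuine neutral loss: the fragment must sit well below the precursor
    ok <- any(vapply(rule$neutral_losses, function(L) {
      any(abs(precursor - fragments - L) <= tol & precursor - fragments > 5)
    }, logical(1)))
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Classify a spectrum by diagnostic fragments
#'
#' Rules are evaluated in priority order; the class of the highest-priority
#' firing rule is returned (higher-priority rules pre-empt lower ones, so
#' e.g. a chebulic ellagitannin showing both the chebuloyl 337.0201 and the
#' HHDP 300.9990 ions is classified chebulic, not plain, ellagitannin).
#'
#' @param spec An [msms_spectrum()], or a numeric vector of fragment m/z (in
#'   which case `precursor_mz` should be given for the precursor-dependent
#'   rules).
#' @param rules Rule list, default [default_diagnostic_rules()].
#' @param tol Fragment tolerance in Da (default 0.01).
#' @param precursor_mz Precursor m/z when `spec` is a bare fragment vector.
#' @return A list with `class` (`"unclassified"` when no rule fires) and
#'   `fired`, the character ids of all firing rules in priority order.
#' @examples
#' lib <- load_library()
#' r95 <- lib[lib$id == 95, ]   # chebulagic acid
#' classify_spectrum(r95$fragments[[1]], precursor_mz = r95$observed_mz)$class
#' @export
classify_spectrum <- function(spec, rules = default_diagnostic_rules(),
                              tol = 0.01, precursor_mz = NA_real_) {
  if (!length(rules)) stop("empty rule set", call. = FALSE)
  stopifnot(tol > 0)
  if (inherits(spec, "msms_spectrum")) {
    fragments <- spec$mz
    precursor_mz <- spec$precursor_mz
  } else {
    fragments <- as.numeric(spec)
  }
  rules <- rules[order(vapply(rules, `[[`, integer(1), "priority"))]
  fired <- character(0)
  cls <- "unclassified"
  for (rule in rules) {
    if (.rule_fires(rule, fragments, precursor_mz, tol)) {
      fired <- c(fired, rule$rule_id)
      if (identical(cls, "unclassified")) cls <- rule$implied_class
    }
  }
  list(class = cls, fired = fired)
}

#' Infer homolog relationships from a mass difference
#'
#' Annotates `node_mz - parent_mz` against the modification catalogue, e.g.
#' recognising the mono- to tetra-methylated series of chebulic acid at
#' +14.016 to +56.062 Da.
#'
#' @param parent_mz,node_mz m/z of the putative parent and derivative (same
#'   ion species assumed).
#' @param catalog Modification catalogue, default [mass_delta_catalog()].
#' @param tol Tolerance in Da (default 0.01).
#' @return The [annotate_mass_difference()] data.frame (possibly empty).
#' @export
infer_homolog <- function(parent_mz, node_mz, catalog = mass_delta_catalog(),
                          tol = 0.01) {
  stopifnot(parent_mz > 0, node_mz > 0)
  annotate_mass_difference(node_mz - parent_mz, catalog, tol)
}

#' Compare measured and predicted collision cross-sections
#'
#' The relative deviation is `|measured - predicted| / predicted * 100`.
#' Within `tol_percent` the pair is a `match`; beyond it the candidate is
#' `flagged` -- which demotes it in ranking but never deletes it, since CCS
#' prediction is only reliable for the smaller glycosides. A missing value on
#' either side gives `not_evaluated`.
#'
#' @param measured,predicted CCS in squared Angstrom (positive; `NA` allowed).
#' @param tol_percent Match tolerance in percent (default 3).
#' @return A list with `measured`, `predicted`, `relative_deviation`
#'   (percent) and `status`.
#' @examples
#' compare_ccs(172.066, 170.416)  # match, 0.97 %
#' compare_ccs(301.139, 274.834)  # flagged, 9.6 %
#' @export
compare_ccs <- function(measured, predicted, tol_percent = 3) {
  stopifnot(tol_percent > 0)
  if (is.na(measured) || is.na(predicted)) {
    return(list(measured = measured, predicted = predicted,
                relative_deviation = NA_real_, status = "not_evaluated"))
  }
  if (measured <= 0 || predicted <= 0) {
    stop("CCS values must be positive", call. = FALSE)
  }
  dev <- abs(measured - predicted) / predicted * 100
  list(measured = measured, predicted = predicted, relative_deviation = dev,
       status = if (dev <= tol_percent) "match" else "flagged")
}

#' Merge the evidence streams for one feature
#'
#' Deterministic precedence: a standard-confirmed library hit beats a library
#' hit consistent with the diagnostic class, which beats the diagnostic class
#' itself (optionally supported by a homolog link), which beats a bare
#' library hit, which beats a network-propagated class, which beats a
#' homolog-only lineage. Conflicting class evidence keeps the
#' higher-precedence class and raises `conflict = TRUE`. Candidates are
#' de-duplicated by record id; they are expected to arrive already ranked
#' (CCS-flagged candidates are demoted, never removed, by [annotate_run()]).
#'
#' @param feature List with `spectrum_id`, `precursor_mz`, `rt` (any may be
#'   `NA`).
#' @param library_hits data.frame of candidate library hits (may be empty or
#'   `NULL`), as from [search_precursor()]/[search_fragments()].
#' @param network_class Class propagated from the molecular-network
#'   component, or `NA`.
#' @param rule_class Class from [classify_spectrum()] (`"unclassified"` when
#'   no rule fired).
#' @param homologs Homolog hypotheses: data.frame with columns of
#'   [infer_homolog()] output plus `parent_id`, `parent_name`,
#'   `parent_class`; may be empty or `NULL`.
#' @param ccs A [compare_ccs()] result or `NULL`.
#' @return An object of class `"annotation_result"`.
#' @export
integrate_evidence <- function(feature, library_hits = NULL,
                               network_class = NA_character_,
                               rule_class = "unclassified",
                               homologs = NULL, ccs = NULL) {
  hits <- library_hits
  if (is.null(hits)) hits <- data.frame()
  homs <- homologs
  if (is.null(homs)) homs <- data.frame()
  has_hits <- nrow(hits) > 0
  has_rule <- !identical(rule_class, "unclassified")
  has_net <- !is.na(network_class)
  has_hom <- nrow(homs) > 0
  if (!has_hits && !has_rule && !has_net && !has_hom) {
    stop("no evidence at all for feature '", feature$spectrum_id, "'",
         call. = FALSE)
  }

  ccs_status <- if (is.null(ccs)) "not_evaluated" else ccs$status
  if (has_hits) {
    hits <- hits[!duplicated(hits$id), , drop = FALSE]
    hits$rank <- seq_len(nrow(hits))
  }

  evidence <- character(0)
  conflict <- FALSE
  assigned <- "unclassified"
  std <- has_hits && any(hits$standard)
  if (std) {
    top <- hits[which(hits$standard)[1], ]
    assigned <- top$class
    evidence <- c("standard", "library")
    if (has_rule) {
      evidence <- c(evidence, "diagnostic")
      if (!identical(rule_class, assigned)) conflict <- TRUE
    }
  } else if (has_hits && has_rule && any(hits$class == rule_class)) {
    assigned <- rule_class
    evidence <- c("library", "diagnostic")
  } else if (has_rule) {
    assigned <- rule_class
    evidence <- "diagnostic"
    if (has_hom) evidence <- c(evidence, "homolog")
    if (has_hits) {
      evidence <- c(evidence, "library")
      conflict <- TRUE        # library class disagrees with the rule class
    }
  } else if (has_hits) {
    assigned <- hits$class[1]
    evidence <- "library"
  } else if (has_net) {
    assigned <- network_class
    evidence <- "network"
  } else {
    assigned <- homs$parent_class[1]
    evidence <- "homolog"
  }
  if (has_net && !("network" %in% evidence)) {
    if (identical(network_class, assigned)) {
      evidence <- c(evidence, "network")
    } else if (!identical(assigned, "unclassified")) {
      conflict <- TRUE
    }
  }
  if (has_hom && !("homolog" %in% evidence)) evidence <- c(evidence, "homolog")
  if (identical(ccs_status, "match")) evidence <- c(evidence, "ccs")

  structure(list(feature = feature, assigned_class = assigned,
                 candidates = hits, homolog_links = homs,
                 ccs_status = ccs_status, evidence_flags = unique(evidence),
                 conflict = conflict),
            class = "annotation_result")
}

#' @export
print.annotation_result <- function(x, ...) {
  cat("<annotation_result> ", x$feature$spectrum_id, " -> ", x$assigned_class,
      " [", paste(x$evidence_flags, collapse = ","), "]",
      if (x$conflict) " (conflict)" else "", "\n", sep = "")
  invisible(x)
}

#' Run the full annotation pipeline over a set of spectra
#'
#' Composes the identification strategy: molecular networking with component
#' class propagation, in-house library search (precursor then fragment
#' ranking), diagnostic-fragment classification, homolog inference against
#' library precursors for otherwise unmatched features, CCS comparison where
#' both a measured and a predicted value exist, and evidence integration.
#'
#' @param spectra List of [msms_spectrum()] objects.
#' @param library Compound library data.frame.
#' @param rules Diagnostic rules.
#' @param params [network_params()].
#' @param precursor_tol_ppm Library precursor tolerance in ppm (default 10).
#' @param fragment_tol Fragment tolerance in Da (default 0.01).
#' @return A list of class `"annotation_run"`: `results` (one data.frame row
#'   per spectrum), `summary` (class counts), `details` (the
#'   `annotation_result` objects) and `network`.
#' @export
annotate_run <- function(spectra, library = load_library(),
                         rules = default_diagnostic_rules(),
                         params = network_params(),
                         precursor_tol_ppm = 10, fragment_tol = 0.01) {
  if (!length(spectra)) {
    empty <- data.frame(spectrum_id = character(0), precursor_mz = numeric(0),
                        rt = numeric(0), assigned_class = character(0),
                        top_id = integer(0), top_name = character(0),
                        evidence = character(0), ccs_status = character(0),
                        conflict = logical(0), stringsAsFactors = FALSE)
    return(structure(list(results = empty, summary = table(character(0)),
                          details = list(), network = NULL),
                     class = "annotation_run"))
  }
  net <- build_network(spectra, params)
  net <- annotate_nodes(net, library, precursor_tol_ppm, fragment_tol)
  net <- enhance_component_classes(net)
  nd <- net$nodes
  max_delta <- max(mass_delta_catalog()$delta_mass * 5) + 1

  details <- vector("list", nrow(nd))
  rows <- vector("list", nrow(nd))
  for (i in seq_len(nrow(nd))) {
    id <- nd$spectrum_id[i]
    spec <- net$spectra[[id]]
    hits <- net$candidates[[i]]
    cls <- classify_spectrum(spec, rules, fragment_tol)
    netcls <- nd$propagated_class[i]
    if (is.na(netcls) && !is.na(nd$component[i])) {
      cc <- net$component_classes
      lab <- cc$class[cc$component == nd$component[i]]
      if (length(lab) && lab != "unclassified") netcls <- lab
    }
    homs <- NULL
    if (is.null(hits) || !nrow(hits)) {
      delta <- spec$precursor_mz - library$observed_mz
      near <- which(abs(delta) <= max_delta & abs(delta) > 0.02)
      hl <- list()
      for (k in near) {
        ann <- infer_homolog(library$observed_mz[k], spec$precursor_mz,
                             tol = fragment_tol)
        if (nrow(ann)) {
          ann$parent_id <- library$id[k]
          ann$parent_name <- library$name[k]
          ann$parent_class <- library$class[k]
          hl[[length(hl) + 1L]] <- ann
        }
      }
      if (length(hl)) {
        homs <- do.call(rbind, hl)
        homs <- homs[order(abs(homs$residual)), , drop = FALSE]
      }
    }
    ccs <- NULL
    if (!is.na(spec$ccs) && !is.null(hits) && nrow(hits)) {
      # per-candidate CCS comparison, subordinate to fragment and precursor
      # evidence: a flagged candidate is demoted below an otherwise equal
      # unflagged one, never removed
      status <- vapply(hits$predicted_ccs, function(pc) {
        compare_ccs(spec$ccs, pc)$status
      }, character(1))
      hits <- hits[order(-hits$shared_count, round(abs(hits$ppm_deviation), 3),
                         status == "flagged", hits$id), , drop = FALSE]
      hits$rank <- seq_len(nrow(hits))
      if (!is.na(hits$predicted_ccs[1])) {
        ccs <- compare_ccs(spec$ccs, hits$predicted_ccs[1])
      }
    }
    feature <- list(spectrum_id = id, precursor_mz = spec$precursor_mz,
                    rt = spec$rt)
    res <- tryCatch(
      integrate_evidence(feature, hits, netcls, cls$class, homs, ccs),
      error = function(e) {
        structure(list(feature = feature, assigned_class = "unclassified",
                       candidates = data.frame(), homolog_links = data.frame(),
                       ccs_status = "not_evaluated",
                       evidence_flags = character(0), conflict = FALSE),
                  class = "annotation_result")
      })
    details[[i]] <- res
    rows[[i]] <- data.frame(
      spectrum_id = id, precursor_mz = spec$precursor_mz, rt = spec$rt,
      assigned_class = res$assigned_class,
      top_id = if (nrow(res$candidates)) res$candidates$id[1] else NA_integer_,
      top_name = if (nrow(res$candidates)) res$candidates$name[1] else NA_character_,
      evidence = paste(res$evidence_flags, collapse = ","),
      ccs_status = res$ccs_status, conflict = res$conflict,
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(results = results,
                 summary = table(factor(results$assigned_class,
                                        levels = c(.TANNIC_CLASSES,
                                                   "flavonoid", "triterpenoid",
                                                   "other", "unclassified"))),
                 details = details, network = net),
            class = "annotation_run")
}

#' @export
print.annotation_run <- function(x, ...) {
  cat("<annotation_run> ", nrow(x$results), " spectra\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Write annotation results as TSV
#'
#' @param run An [annotate_run()] result (or its `results` data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(run, path) {
  res <- if (inherits(run, "annotation_run")) run$results else run
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
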