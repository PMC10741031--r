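# Classic molecular networking: modified-cosine spectral similarity, the
# thresholded/top-k network, connected components, and majority-vote
# component class labelling.

#' Networking parameters
#'
#' Defaults follow the classic-molecular-networking conventions: 0.01 Da
#' precursor and fragment tolerances, minimum cosine 0.7, at least 6 matched
#' peaks per edge, each node keeping its 10 strongest edges (an edge survives
#' only if it is in the top-k of both endpoints), and components capped at
#' 100 nodes.
#'
#' @param fragment_tol,precursor_tol Tolerances in Da.
#' @param min_cosine Minimum modified-cosine score for an edge, in `[0, 1]`.
#' @param min_matched_peaks Minimum matched peak count for an edge.
#' @param top_k Per-node edge cap (mutual rule).
#' @param max_component_size Maximum component size, or `Inf` for no cap.
#' @return A list of class `"network_params"`.
#' @export
network_params <- function(fragment_tol = 0.01, precursor_tol = 0.01,
                           min_cosine = 0.7, min_matched_peaks = 6L,
                           top_k = 10L, max_component_size = 100L) {
  stopifnot(fragment_tol > 0, precursor_tol > 0,
            min_cosine >= 0, min_cosine <= 1,
            min_matched_peaks >= 1L, top_k >= 1L)
  structure(list(fragment_tol = fragment_tol, precursor_tol = precursor_tol,
                 min_cosine = min_cosine,
                 min_matched_peaks = as.integer(min_matched_peaks),
                 top_k = as.integer(top_k),
                 max_component_size = max_component_size),
            class = "network_params")
}

# square-root transform and L2-normalise intensities so self-similarity is 1
.norm_intensities <- function(intensity) {
  w <- sqrt(intensity)
  n <- sqrt(sum(w^2))
  if (n == 0) w else w / n
}

# candidate peak pairs: direct match or match shifted by the precursor delta
.candidate_pairs <- function(a_mz, b_mz, shift, tol) {
  pairs <- NULL
  for (i in seq_along(a_mz)) {
    direct <- abs(a_mz[i] - b_mz) <= tol
    shifted <- abs(a_mz[i] - (b_mz + shift)) <= tol
    j <- which(direct | shifted)
    if (length(j)) pairs <- rbind(pairs, cbind(i = i, j = j))
  }
  pairs
}

# exact maximum-score one-to-one pairing by branch-and-bound enumeration;
# only used for small candidate sets (the greedy path is the production one)
.exact_pairing_score <- function(pairs, score) {
  best <- 0
  best_n <- 0L
  recurse <- function(idx, used_i, used_j, acc, cnt) {
    if (acc + sum(score[idx]) <= best && cnt + length(idx) <= best_n) return()
    if (acc > best || (acc == best && cnt > best_n)) {
      best <<- acc
      best_n <<- cnt
    }
    if (!length(idx)) return()
    k <- idx[1]
    rest <- idx[-1]
    if (!(pairs[k, 1] %in% used_i) && !(pairs[k, 2] %in% used_j)) {
      recurse(rest, c(used_i, pairs[k, 1]), c(used_j, pairs[k, 2]),
              acc + score[k], cnt + 1L)
    }
    recurse(rest, used_i, used_j, acc, cnt)
  }
  recurse(seq_len(nrow(pairs)), integer(0), integer(0), 0, 0L)
  list(score = best, matches = best_n)
}

#' Modified-cosine similarity between two spectra
#'
#' Peaks are pairable when their m/z agree within `fragment_tol`, either
#' directly or after shifting one spectrum by the precursor mass difference.
#' Intensities are square-root transformed and L2-normalised, so the score of
#' a spectrum with itself is 1. A one-to-one pairing maximising the sum of
#' intensity products is selected greedily in descending product order; for
#' small candidate sets (`<= exact_limit` candidate pairs) the exact optimum
#' is found by enumeration instead, which is also the oracle used in the test
#' suite.
#'
#' @param a,b [msms_spectrum()] objects.
#' @param fragment_tol Fragment tolerance in Da.
#' @param exact_limit Candidate-pair count up to which exact enumeration is
#'   used (default 8).
#' @return A list with `score` in `[0, 1]` and `matches`, the matched peak
#'   count.
#' @export
modified_cosine <- function(a, b, fragment_tol = 0.01, exact_limit = 8L) {
  stopifnot(inherits(a, "msms_spectrum"), inherits(b, "msms_spectrum"))
  wa <- .norm_intensities(a$intensity)
  wb <- .norm_intensities(b$intensity)
  shift <- a$precursor_mz - b$precursor_mz
  pairs <- .candidate_pairs(a$mz, b$mz, shift, fragment_tol)
  if (is.null(pairs)) return(list(score = 0, matches = 0L))
  score <- wa[pairs[, 1]] * wb[pairs[, 2]]
  if (nrow(pairs) <= exact_limit) {
    res <- .exact_pairing_score(pairs, score)
    return(list(score = min(res$score, 1), matches = as.integer(res$matches)))
  }
  ord <- order(-score, pairs[, 1], pairs[, 2])
  used_i <- logical(length(a$mz))
  used_j <- logical(length(b$mz))
  total <- 0
  matches <- 0L
  for (k in ord) {
    i <- pairs[k, 1]
    j <- pairs[k, 2]
    if (!used_i[i] && !used_j[j]) {
      used_i[i] <- TRUE
      used_j[j] <- TRUE
      total <- total + score[k]
      matches <- matches + 1L
    }
  }
  list(score = min(total, 1), matches = matches)
}

#' Build a molecular network from spectra
#'
#' All spectrum pairs are scored with [modified_cosine()]; edges are kept
#' when the score reaches `min_cosine` and the matched peak count reaches
#' `min_matched_peaks`; each node then retains only its `top_k` strongest
#' edges, an edge surviving only if it is in the top-k of both endpoints.
#' Connected components are numbered over non-orphan nodes (degree-0 nodes
#' are flagged `orphan` and excluded from component numbering). Components
#' larger than `max_component_size` are pruned by repeatedly dropping their
#' weakest edge.
#'
#' @param spectra List of [msms_spectrum()] objects.
#' @param params A [network_params()].
#' @return An object of class `"molecular_network"`: list with `nodes`
#'   (data.frame: `spectrum_id`, `precursor_mz`, `rt`, `component`, `orphan`),
#'   `edges` (data.frame: `from`, `to`, `cosine`, `matched_peaks`) and
#'   `params`. Output is invariant to the input order of the spectra (nodes
#'   are sorted by `spectrum_id`).
#' @export
build_network <- function(spectra, params = network_params()) {
  stopifnot(length(spectra) >= 1L)
  ids <- vapply(spectra, `[[`, character(1), "spectrum_id")
  if (anyDuplicated(ids)) stop("duplicate spectrum ids", call. = FALSE)
  ord <- order(ids)
  spectra <- spectra[ord]
  ids <- ids[ord]
  n <- length(spectra)
  edges <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        mc <- modified_cosine(spectra[[i]], spectra[[j]], params$fragment_tol)
        if (mc$score >= params$min_cosine &&
            mc$matches >= params$min_matched_peaks) {
          edges[[length(edges) + 1L]] <-
            data.frame(from = ids[i], to = ids[j], cosine = mc$score,
                       matched_peaks = mc$matches, stringsAsFactors = FALSE)
        }
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0), cosine = numeric(0),
               matched_peaks = integer(0), stringsAsFactors = FALSE)

  # mutual top-k rule
  if (nrow(edges)) {
    keep <- rep(TRUE, nrow(edges))
    for (id in ids) {
      inc <- which(edges$from == id | edges$to == id)
      if (length(inc) > params$top_k) {
        ranked <- inc[order(-edges$cosine[inc], edges$from[inc], edges$to[inc])]
        keep[ranked[-seq_len(params$top_k)]] <- FALSE
      }
    }
    edges <- edges[keep, , drop = FALSE]
  }

  # component capping: drop weakest edges of oversized components
  if (nrow(edges) && is.finite(params$max_component_size)) {
    repeat {
      g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                         vertices = data.frame(name = ids))
      comp <- igraph::components(g)
      sizes <- comp$csize[comp$membership]
      over <- names(sizes)[sizes > params$max_component_size]
      if (!length(over)) break
      in_over <- edges$from %in% over | edges$to %in% over
      victim <- which(in_over)[which.min(edges$cosine[in_over])]
      edges <- edges[-victim, , drop = FALSE]
    }
  }

  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  deg <- igraph::degree(g)
  comp <- igraph::components(g)
  orphan <- deg == 0
  membership <- comp$membership
  # renumber components over non-orphan nodes only, by smallest spectrum_id
  live <- sort(unique(membership[!orphan]))
  comp_no <- rep(NA_integer_, n)
  if (length(live)) {
    first_id <- vapply(live, function(cid) min(ids[membership == cid & !orphan]),
                       character(1))
    relabel <- order(first_id)
    for (k in seq_along(live)) {
      comp_no[membership == live[relabel[k]] & !orphan] <- k
    }
  }
  nodes <- data.frame(
    spectrum_id = ids,
    precursor_mz = vapply(spectra, `[[`, numeric(1), "precursor_mz"),
    rt = vapply(spectra, `[[`, numeric(1), "rt"),
    component = comp_no,
    orphan = orphan,
    stringsAsFactors = FALSE
  )
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, params = params,
                 spectra = stats::setNames(spectra, ids)),
            class = "molecular_network")
}

#' @export
print.molecular_network <- function(x, ...) {
  cat("<molecular_network> ", nrow(x$nodes), " nodes (",
      sum(x$nodes$orphan), " orphaned), ", nrow(x$edges), " edges, ",
      length(stats::na.omit(unique(x$nodes$component))), " components\n",
      sep = "")
  invisible(x)
}

#' Annotate network nodes against the compound library
#'
#' Each node is searched by precursor m/z and its spectrum's fragments; the
#' best hit (most shared fragments, then smallest precursor deviation, then
#' record id) is attached. Nodes matching nothing stay unannotated.
#'
#' @param network A [build_network()] result.
#' @param library A compound library data.frame.
#' @param precursor_tol_ppm Precursor tolerance in ppm (default 10).
#' @param fragment_tol Fragment tolerance in Da (default 0.01).
#' @return The network with node columns `annotation_id`, `annotation_name`,
#'   `annotation_class` filled in, plus a `candidates` list (all precursor
#'   hits per node, ranked by fragment overlap) stored on the object.
#' @export
annotate_nodes <- function(network, library = load_library(),
                           precursor_tol_ppm = 10, fragment_tol = 0.01) {
  stopifnot(inherits(network, "molecular_network"))
  nd <- network$nodes
  nd$annotation_id <- NA_integer_
  nd$annotation_name <- NA_character_
  nd$annotation_class <- NA_character_
  candidates <- vector("list", nrow(nd))
  names(candidates) <- nd$spectrum_id
  for (i in seq_len(nrow(nd))) {
    hits <- search_precursor(nd$precursor_mz[i], precursor_tol_ppm, library)
    if (!nrow(hits)) next
    spec <- network$spectra[[nd$spectrum_id[i]]]
    hits$shared_count <- vapply(hits$fragments, function(fr) {
      .shared_fragments(spec$mz, fr, fragment_tol)
    }, numeric(1))
    hits <- hits[order(-hits$shared_count, abs(hits$ppm_deviation), hits$id), ,
                 drop = FALSE]
    hits$rank <- seq_len(nrow(hits))
    candidates[[i]] <- hits
    nd$annotation_id[i] <- hits$id[1]
    nd$annotation_name[i] <- hits$name[1]
    nd$annotation_class[i] <- hits$class[1]
  }
  network$nodes <- nd
  network$candidates <- candidates
  network
}

#' Majority-vote class labels for network components
#'
#' A component is labelled with a compound class when at least half of its
#' annotated nodes share that class (and at least one node is annotated);
#' otherwise it is `"unclassified"`. Unannotated nodes inside a labelled
#' component inherit the label as a propagated class (`propagated_class`
#' column), which is reported separately from asserted annotations.
#'
#' @param network An annotated network (see [annotate_nodes()]).
#' @return The network, with a `component_classes` data.frame
#'   (`component`, `class`, `n_nodes`, `n_annotated`) and a node column
#'   `propagated_class`.
#' @export
enhance_component_classes <- function(network) {
  stopifnot(inherits(network, "molecular_network"))
  if (is.null(network$nodes$annotation_class)) {
    stop("run annotate_nodes() first", call. = FALSE)
  }
  nd <- network$nodes
  comps <- as.integer(sort(stats::na.omit(unique(nd$component))))
  out <- data.frame(component = comps,
                    class = rep(NA_character_, length(comps)),
                    n_nodes = rep(NA_integer_, length(comps)),
                    n_annotated = rep(NA_integer_, length(comps)),
                    stringsAsFactors = FALSE)
  nd$propagated_class <- NA_character_
  for (k in seq_along(comps)) {
    sel <- which(nd$component %in% comps[k])
    cls <- nd$annotation_class[sel]
    ann <- cls[!is.na(cls)]
    label <- "unclassified"
    if (length(ann)) {
      tab <- sort(table(ann), decreasing = TRUE)
      if (tab[1] / length(ann) >= 0.5) label <- names(tab)[1]
    }
    out$class[k] <- label
    out$n_nodes[k] <- length(sel)
    out$n_annotated[k] <- length(ann)
    if (label != "unclassified") {
      inherit <- sel[is.na(nd$annotation_class[sel])]
      nd$propagated_class[inherit] <- label
    }
  }
  network$nodes <- nd
  network$component_classes <- out
  network
}

#' Export a molecular network to GraphML
#'
#' Node attributes: precursor m/z, retention time, annotation (id, name,
#' class), propagated class and component; edge attributes: cosine score and
#' matched peak count.
#'
#' @param network A [build_network()] result (annotated or not).
#' @param path Output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path) {
  stopifnot(inherits(network, "molecular_network"))
  nd <- network$nodes
  nd$component[is.na(nd$component)] <- -1L
  for (col in c("annotation_name", "annotation_class", "propagated_class")) {
    if (!is.null(nd[[col]])) nd[[col]][is.na(nd[[col]])] <- ""
  }
  nd$rt[is.na(nd$rt)] <- -1
  vert <- cbind(data.frame(name = nd$spectrum_id, stringsAsFactors = FALSE),
                nd[setdiff(names(nd), "spectrum_id")])
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = vert)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
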