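#' Load a scored protein-protein interaction graph
#'
#' Builds an undirected, unweighted [InteractionGraph-class] from a
#' STRING-style edge table (columns: two protein symbols and a combined
#' confidence score, 0-1000), keeping edges with score at or above the
#' cutoff. Duplicate edges are collapsed keeping the maximum score;
#' self-loops are dropped. After score filtering, edges are treated as
#' unweighted and shortest paths are hop-count geodesics.
#'
#' @param edges a data.frame (first two columns: protein symbols; a
#'   \code{combined_score} column or third column: scores) or the path to a
#'   tab-separated file in STRING export dialect
#'   (\code{protein1<TAB>protein2<TAB>combined_score}).
#' @param cutoff minimum combined score to retain an edge (the published
#'   analysis used 667).
#' @param seeds character vector of seed protein symbols; defaults to all
#'   retained nodes.
#' @return an [InteractionGraph-class] object.
#' @export
loadInteractions <- function(edges, cutoff = 667, seeds = NULL) {
  if (is.character(edges) && length(edges) == 1L) {
    df <- tryCatch(
      read.delim(edges, header = TRUE, stringsAsFactors = FALSE),
      error = function(e) stop("cannot read edge table: ",
                               conditionMessage(e)))
  } else df <- as.data.frame(edges)
  if (ncol(df) < 3L) stop("edge table needs 3 columns (two proteins, score)")
  scoreCol <- if ("combined_score" %in% names(df)) "combined_score"
              else names(df)[3L]
  a <- as.character(df[[1L]]); b <- as.character(df[[2L]])
  score <- suppressWarnings(as.numeric(df[[scoreCol]]))
  bad <- which(is.na(score) | is.na(a) | is.na(b) | a == "" | b == "")
  if (length(bad))
    stop("malformed edge row(s) at line(s): ",
         paste(head(bad + 1L, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "")
  keep <- score >= cutoff & a != b
  if (!any(keep)) stop("empty graph: no edges pass the score cutoff ", cutoff)
  a <- a[keep]; b <- b[keep]; score <- score[keep]
  ## collapse duplicates keeping the maximum score
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  best <- tapply(score, key, max)
  pairs <- do.call(rbind, strsplit(names(best), "\r", fixed = TRUE))
  g <- igraph::graph_from_data_frame(
    data.frame(from = pairs[, 1L], to = pairs[, 2L],
               combined_score = as.numeric(best)),
    directed = FALSE)
  if (is.null(seeds)) seeds <- igraph::V(g)$name
  missing <- setdiff(seeds, igraph::V(g)$name)
  if (length(missing))
    stop("seed protein(s) not in the filtered graph: ",
         paste(missing, collapse = ", "))
  new("InteractionGraph", graph = g, seeds = sort(unique(seeds)),
      cutoff = cutoff)
}

#' @describeIn InteractionGraph-class compact display
#' @param object an \code{InteractionGraph} object.
#' @export
setMethod("show", "InteractionGraph", function(object) {
  cat("InteractionGraph:", igraph::vcount(object@graph), "proteins,",
      igraph::ecount(object@graph), "interactions (score >=",
      object@cutoff, "),", length(object@seeds), "seeds\n")
  invisible(NULL)
})

## canonical direction-free identity of an unweighted path
.pathKey <- function(nodes) {
  if (nodes[1L] > nodes[length(nodes)]) nodes <- rev(nodes)
  paste(nodes, collapse = "->")
}

## all hop-count geodesics between two vertices; character() set when the
## pair is disconnected
.geodesics <- function(g, from, to) {
  if (!from %in% igraph::V(g)$name || !to %in% igraph::V(g)$name)
    return(character())
  res <- suppressWarnings(
    igraph::all_shortest_paths(g, from = from, to = to, weights = NA))
  paths <- res$vpaths
  if (!length(paths)) return(character())
  unique(vapply(paths, function(p) .pathKey(names(p)), ""))
}

#' All shortest paths between every seed pair
#'
#' Enumerates the complete set of equal-length (hop-count) shortest paths
#' for every unordered pair of seed proteins. Disconnected pairs are
#' recorded as empty sets, not errors.
#'
#' @param ig an [InteractionGraph-class] object.
#' @return named list; entry \code{"A|B"} holds the character vector of
#'   geodesics (each path encoded as \code{"A->...->B"}).
#' @export
seededPaths <- function(ig) {
  stopifnot(is(ig, "InteractionGraph"))
  seeds <- ig@seeds
  if (length(seeds) < 2L) stop("at least two seeds are required")
  out <- list()
  for (i in seq_len(length(seeds) - 1L)) {
    for (j in seq((i + 1L), length(seeds))) {
      out[[paste(seeds[i], seeds[j], sep = "|")]] <-
        .geodesics(ig@graph, seeds[i], seeds[j])
    }
  }
  out
}

#' Differential shortest-path analysis after node deletion
#'
#' Recomputes the geodesic sets between the anchor protein and every other
#' seed after deleting one node in silico, and quantifies the turnover of
#' each pair's geodesic set by the alteration fraction: the number of
#' geodesics present in only one of the before/after sets divided by the
#' size of their union. A fraction of 1 means no shortest path survived
#' unchanged (only deleted or newly created paths) -- these pairs are the
#' "most impacted" ones used for downstream ranking.
#'
#' @param ig an [InteractionGraph-class] object.
#' @param node protein to delete (must be in the graph; must not be the
#'   anchor).
#' @param anchor anchor protein (e.g. ARF1) whose pairs are analyzed.
#' @return data.frame with one row per (anchor, partner) pair: columns
#'   \code{anchor}, \code{partner}, \code{n_before}, \code{n_after},
#'   \code{alteration_fraction}, plus attribute \code{"changed"} holding the
#'   per-pair sets of non-surviving geodesics.
#' @export
deleteNodeDiff <- function(ig, node, anchor) {
  stopifnot(is(ig, "InteractionGraph"))
  vs <- igraph::V(ig@graph)$name
  if (!node %in% vs) stop("node not found in graph: ", node)
  if (!anchor %in% vs) stop("anchor not found in graph: ", anchor)
  if (identical(node, anchor))
    stop("deleting the anchor itself is not allowed")
  g2 <- igraph::delete_vertices(ig@graph, node)
  partners <- setdiff(ig@seeds, c(anchor, node))
  if (!length(partners)) stop("no partner seeds besides the anchor")
  rows <- vector("list", length(partners))
  changed <- vector("list", length(partners))
  for (i in seq_along(partners)) {
    before <- .geodesics(ig@graph, anchor, partners[i])
    after <- .geodesics(g2, anchor, partners[i])
    uni <- union(before, after)
    diffSet <- union(setdiff(before, after), setdiff(after, before))
    frac <- if (length(uni)) length(diffSet) / length(uni) else 0
    rows[[i]] <- data.frame(anchor = anchor, partner = partners[i],
                            n_before = length(before),
                            n_after = length(after),
                            alteration_fraction = frac)
    changed[[i]] <- diffSet
  }
  out <- do.call(rbind, rows)
  names(changed) <- partners
  attr(out, "changed") <- changed
  out
}

#' Rank end proteins by impact after node deletion
#'
#' Ranks the partner proteins of fully altered pairs (alteration fraction
#' exactly 1) by how many of their geodesics were deleted or newly created,
#' breaking ties alphabetically. An empty ranking is returned when no pair
#' has fraction 1.
#'
#' @param deltas the data.frame produced by [deleteNodeDiff()].
#' @return data.frame with columns \code{partner}, \code{impact_count}.
#' @export
rankEndProteins <- function(deltas) {
  stopifnot(is.data.frame(deltas), nrow(deltas) >= 1L)
  changed <- attr(deltas, "changed")
  hit <- deltas[deltas$alteration_fraction == 1 &
                  (deltas$n_before + deltas$n_after) > 0, , drop = FALSE]
  if (!nrow(hit))
    return(data.frame(partner = character(), impact_count = integer()))
  counts <- vapply(hit$partner, function(pt)
    if (!is.null(changed[[pt]])) length(changed[[pt]])
    else hit$n_before[hit$partner == pt] + hit$n_after[hit$partner == pt],
    integer(1L))
  out <- data.frame(partner = hit$partner, impact_count = as.integer(counts))
  out[order(-out$impact_count, out$partner), , drop = FALSE]
}

#' Write path-delta and ranking tables
#'
#' @param deltas data.frame from [deleteNodeDiff()].
#' @param path destination TSV
#'   (\code{anchor,partner,n_before,n_after,alteration_fraction}).
#' @return invisibly, the path.
#' @export
writePathDeltas <- function(deltas, path) {
  write.table(deltas, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
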