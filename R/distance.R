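#' Network connectivity degree of a metabolite
#'
#' The total number of sources and sinks of the metabolite: each base
#' reaction contributes one count per role (producer and/or consumer).
#' Irreversible reactions fill a single role; reversible reactions act as
#' both producer and consumer and contribute one count per role (not per
#' direction). A degree of 2 indicates strict linearity (one producer, one
#' consumer); high degrees mark hub metabolites such as pyruvate or ATP.
#'
#' @param net a `metabolic_network`.
#' @param met metabolite id (or vector of ids; default all).
#' @return named integer vector of degrees.
#' @export
metabolite_degree <- function(net, met = rownames(net$S)) {
  unknown <- setdiff(met, rownames(net$S))
  if (length(unknown)) stop("unknown metabolite: ", unknown[1])
  rev <- is_reversible(net)
  backward <- net$lb < 0 & net$ub <= 0   # runs reverse-only
  deg <- setNames(integer(length(met)), met)
  for (m in met) {
    s <- net$S[m, ]
    touched <- which(s != 0)
    d <- 0L
    for (j in touched) {
      if (rev[j]) d <- d + 2L          # both roles
      else d <- d + 1L                 # one role, whichever way it runs
    }
    deg[m] <- d
  }
  deg
}

#' Distance weight of a metabolite from its connectivity degree
#'
#' `w(m) = max(1, 1 + log2(deg(m) / 2))`: a degree-2 (strictly linear)
#' metabolite has weight 1, recovering the naive "number of reactions plus
#' one" distance, and hub metabolites inflate the distance sub-linearly
#' (degree 8 gives weight 3, degree 64 gives weight 6).
#'
#' @param degree integer vector of metabolite degrees.
#' @return numeric weights, all `>= 1`.
#' @export
metabolite_weight <- function(degree) {
  w <- 1 + log2(degree / 2)
  w[!is.finite(w)] <- 1
  pmax(w, 1)
}

#' Length of a reaction-adjacency edge from its bridging metabolites
#'
#' Two adjacent reactions may be connected through several metabolites; the
#' cheapest bridge defines the adjacency, so the edge length is the minimum
#' metabolite weight. A single linear carrier suffices for flux coupling
#' even when a hub co-product is also shared.
#'
#' @param degrees degrees of the bridging metabolites (at least one).
#' @return edge length `>= 1`.
#' @export
edge_length <- function(degrees) {
  if (!length(degrees)) stop("at least one bridging metabolite is required")
  min(metabolite_weight(degrees))
}

#' Build the directed reaction-adjacency graph
#'
#' Nodes are directed reactions; an edge `u -> v` exists when some
#' metabolite produced by `u` is consumed by `v` (mass flows from `u` into
#' `v`). The two directions of the same base reaction are never connected
#' to each other. Each edge carries a naive length of 1 and a weighted
#' length equal to the minimum [metabolite_weight()] over its bridging
#' metabolites.
#'
#' @param dnet a `directed_network`.
#' @return an `igraph` with vertex names = directed reaction ids and edge
#'   attributes `len_naive`, `len_weighted` and `bridges`
#'   (comma-separated bridging metabolite ids).
#' @export
reaction_graph <- function(dnet) {
  S <- dnet$S
  deg <- metabolite_degree(dnet$network)
  wmet <- metabolite_weight(deg)
  from <- character(0); to <- character(0); wts <- numeric(0); br <- character(0)
  edge_idx <- new.env(parent = emptyenv())
  for (m in rownames(S)) {
    prod <- colnames(S)[S[m, ] > 0]
    cons <- colnames(S)[S[m, ] < 0]
    if (!length(prod) || !length(cons)) next
    for (u in prod) for (v in cons) {
      if (u == v || dnet$base_id[[u]] == dnet$base_id[[v]]) next
      key <- paste0(u, "\r", v)
      i <- edge_idx[[key]]
      if (is.null(i)) {
        from <- c(from, u); to <- c(to, v)
        wts <- c(wts, wmet[[m]]); br <- c(br, m)
        edge_idx[[key]] <- length(from)
      } else if (wmet[[m]] < wts[i]) {
        wts[i] <- wmet[[m]]
        br[i] <- paste(br[i], m, sep = ",")
      } else {
        br[i] <- paste(br[i], m, sep = ",")
      }
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = colnames(S), stringsAsFactors = FALSE)
  )
  igraph::E(g)$len_naive <- rep(1, length(from))
  igraph::E(g)$len_weighted <- wts
  igraph::E(g)$bridges <- br
  g
}

#' Shortest metabolic distances from a reaction of interest
#'
#' Dijkstra over the reaction-adjacency graph. The naive metric counts
#' reaction steps (all edge lengths 1, i.e. the number of reactions between
#' the pair plus one); the weighted metric uses metabolite-degree edge
#' lengths, so paths through hub metabolites are longer. `mode = "out"`
#' follows mass flow downstream of the ROI, `"in"` upstream (suppliers),
#' and `"both"` takes the elementwise minimum of the two so that the whole
#' pathway passing through the ROI is within reach.
#'
#' @param graph a [reaction_graph()] (any igraph with `len_naive` and
#'   `len_weighted` edge attributes works).
#' @param roi directed reaction id (vertex name).
#' @param metric `"naive"` or `"weighted"`.
#' @param mode `"both"` (default), `"out"` or `"in"`.
#' @return named numeric vector of distances over all vertices;
#'   unreachable reactions are `Inf`, `d(roi, roi) = 0`.
#' @export
shortest_distances <- function(graph, roi,
                               metric = c("weighted", "naive"),
                               mode = c("both", "out", "in")) {
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  if (!roi %in% igraph::V(graph)$name) stop("ROI not in graph: ", roi)
  w <- if (metric == "naive") igraph::E(graph)$len_naive
       else igraph::E(graph)$len_weighted
  one <- function(md) {
    d <- igraph::distances(graph, v = roi, mode = md, weights = w)[1, ]
    d[igraph::V(graph)$name]
  }
  if (mode == "both") pmin(one("out"), one("in")) else one(mode)
}

#' Distance map for a set of ROI directions
#'
#' @param dnet a `directed_network`.
#' @param rois directed reaction ids (default all).
#' @param graph optionally a precomputed [reaction_graph()].
#' @param mode passed to [shortest_distances()].
#' @return a `distance_map`: list with matrices `naive` and `weighted`
#'   (ROI x directed reaction).
#' @export
distance_map <- function(dnet, rois = colnames(dnet$S), graph = NULL,
                         mode = "both") {
  if (is.null(graph)) graph <- reaction_graph(dnet)
  nv <- igraph::V(graph)$name
  naive <- weighted <- matrix(Inf, length(rois), length(nv),
                              dimnames = list(rois, nv))
  for (r in rois) {
    naive[r, ] <- shortest_distances(graph, r, "naive", mode)
    weighted[r, ] <- shortest_distances(graph, r, "weighted", mode)
  }
  structure(list(naive = naive, weighted = weighted), class = "distance_map")
}

#' Effective (interpretable) distance boundary
#'
#' The distance boundary of eFPA is measured on the weighted-distance
#' scale; this converts it to the maximum naive distance among reactions
#' that fall within the boundary, i.e. the actual length of the longest
#' integrated pathway.
#'
#' @param naive_d,weighted_d distance vectors for one ROI (same order).
#' @param b weighted distance boundary `>= 0`.
#' @return maximum naive distance within the boundary (0 if none).
#' @export
effective_boundary <- function(naive_d, weighted_d, b) {
  sel <- is.finite(weighted_d) & weighted_d <= b & is.finite(naive_d)
  if (!any(sel)) return(0)
  max(naive_d[sel])
}

#' Export distances for a set of ROIs as a long-format TSV
#'
#' @param dmap a [distance_map()].
#' @param dnet the `directed_network` the map was computed on.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_distances <- function(dmap, dnet, path) {
  rois <- rownames(dmap$naive)
  long <- do.call(rbind, lapply(rois, function(r) {
    data.frame(roi_id = dnet$base_id[[r]],
               direction = dnet$direction[[r]],
               reaction_id = colnames(dmap$naive),
               naive_d = dmap$naive[r, ],
               weighted_d = dmap$weighted[r, ],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
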