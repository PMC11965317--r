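# Independent oracles and fixture builders used across the suite.
# These are deliberately written without calling the package's own code
# paths they are meant to check.

# --- random GPR trees -------------------------------------------------------
# Generates a boolean tree directly (never via parse_gpr) together with a
# fully parenthesized string rendering; the tree is the ground truth.
random_gpr_tree <- function(genes, depth = 3) {
  if (depth == 0 || runif(1) < 0.4) {
    g <- sample(genes, 1)
    return(list(kind = "leaf", gene = g, string = g))
  }
  op <- sample(c("and", "or"), 1)
  k <- sample(2:3, 1)
  kids <- lapply(seq_len(k), function(i) random_gpr_tree(genes, depth - 1))
  list(kind = op, children = kids,
       string = paste0("(", paste(vapply(kids, `[[`, "", "string"),
                                  collapse = paste0(" ", op, " ")), ")"))
}

# Reference min/sum evaluation on the generator-side tree.
eval_gpr_ref <- function(tree, levels, measured = names(levels)) {
  if (tree$kind == "leaf") {
    if (tree$gene %in% measured) return(levels[[tree$gene]])
    return(NA_real_)
  }
  vals <- vapply(tree$children, eval_gpr_ref, numeric(1),
                 levels = levels, measured = measured)
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(NA_real_)
  if (tree$kind == "and") min(vals) else sum(vals)
}

# --- Bellman-Ford distances -------------------------------------------------
bf_distances <- function(graph, roi, metric = "weighted", mode = "out") {
  ed <- igraph::as_data_frame(graph, what = "edges")
  vs <- igraph::V(graph)$name
  w <- if (metric == "naive") ed$len_naive else ed$len_weighted
  if (mode == "in") {
    tmp <- ed$from; ed$from <- ed$to; ed$to <- tmp
  }
  d <- setNames(rep(Inf, length(vs)), vs)
  d[roi] <- 0
  for (iter in seq_len(length(vs))) {
    changed <- FALSE
    for (i in seq_len(nrow(ed))) {
      nd <- d[[ed$from[i]]] + w[i]
      if (nd < d[[ed$to[i]]]) {
        d[[ed$to[i]]] <- nd
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  d
}

bf_both <- function(graph, roi, metric = "weighted") {
  pmin(bf_distances(graph, roi, metric, "out"),
       bf_distances(graph, roi, metric, "in"))
}

# --- BH step-up -------------------------------------------------------------
bh_stepup <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[ord[i]] * m / i)
    q[ord[i]] <- running
  }
  q
}

# --- fixtures ---------------------------------------------------------------
# 3-reaction chain (uptake -> A, A -> B, B export), one gene per reaction.
chain3 <- function() {
  metabolic_network(
    data.frame(id = c("A", "B"), compartment = "c",
               stringsAsFactors = FALSE),
    list(list(id = "R1", stoich = c(A = 1), lb = 0, ub = 1000, gpr = "g1"),
         list(id = "R2", stoich = c(A = -1, B = 1), lb = 0, ub = 1000,
              gpr = "g2"),
         list(id = "R3", stoich = c(B = -1), lb = 0, ub = 1000, gpr = "g3")))
}

# reaction_expression object with a prescribed relative-expression matrix
rel_object <- function(m, status = NULL) {
  if (is.null(status)) {
    status <- setNames(ifelse(rowSums(!is.na(as.matrix(m))) > 0,
                              "complete", "missing"), rownames(m))
  }
  structure(list(rel = as.matrix(m), status = status,
                 zero = setNames(rep(FALSE, nrow(m)), rownames(m))),
            class = "reaction_expression")
}

# uniform relative expression over a network's enzymatic reactions
uniform_rel <- function(net, conds, value = 1) {
  has_gpr <- !vapply(net$gpr, is.null, logical(1))
  m <- matrix(NA_real_, ncol(net$S), length(conds),
              dimnames = list(colnames(net$S), conds))
  m[has_gpr, ] <- value
  rel_object(m)
}

# random directed graph with distance attributes, for distance oracles
random_distance_graph <- function(n = 15, p = 0.2) {
  g <- igraph::sample_gnp(n, p, directed = TRUE)
  igraph::V(g)$name <- paste0("v", seq_len(n))
  m <- igraph::ecount(g)
  igraph::E(g)$len_naive <- rep(1, m)
  igraph::E(g)$len_weighted <- 1 + rexp(m)
  g
}

# random toy fixture + simulated expression, for LP property tests
random_fixture <- function(seed) {
  set.seed(seed)
  template <- sample(c("linear", "branched", "hub"), 1)
  net <- switch(template,
    linear = make_toy_network("linear", length = sample(3:5, 1)),
    branched = make_toy_network("branched", pathway_length = sample(2:4, 1),
                                distal_length = sample(2:3, 1),
                                roi_has_gene = TRUE),
    hub = make_toy_network("hub", hub_degree = sample(c(4, 6, 8), 1)))
  sim <- simulate_expression(net, n_conditions = 4, rho = runif(1, 0, 0.9),
                             seed = seed + 500)
  list(net = net, sim = sim)
}
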