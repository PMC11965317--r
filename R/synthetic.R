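#' Construct a toy metabolic network fixture
#'
#' Small mass-balanced networks with uptake and export reactions so every
#' internal reaction can carry steady-state flux. Templates:
#' \describe{
#'   \item{`linear`}{a single chain of `length` internal reactions
#'     (genes `g1..gL`) between one uptake and one export.}
#'   \item{`branched`}{a linear route into the ROI consisting of a
#'     proximal coexpressed pathway (`pathway_length` reactions, genes
#'     `g1..gL`, flux-coupled to the pathway's latent activity) preceded by
#'     a distal segment (`distal_length` reactions, genes `u1..uK`,
#'     independently expressed), plus a side branch; the ROI itself has no
#'     GPR unless `roi_has_gene`. The scenario for gap-filling and
#'     boundary-titration studies: expression within the pathway informs
#'     the ROI flux, expression beyond it is noise.}
#'   \item{`hub`}{`ceil(degree/2)` producer arms and `floor(degree/2)`
#'     consumer arms meeting at one hub metabolite of the requested
#'     connectivity degree; cross-hub reaction pairs are separated by the
#'     weighted distance while within-arm pairs are not.}
#'   \item{`glycogen`}{two branches that drain a common precursor, each a
#'     2-step chain whose first reaction carries the *same* gene
#'     (`g_shared`) - the two branch entries are indistinguishable by
#'     reaction expression while their downstream genes (`g_b1`, `g_b2`)
#'     differ.}
#'   \item{`coproduct`}{a lumped reaction producing the ROI substrate
#'     together with a co-product that must be drained through a separate
#'     enzyme (`g_drain`); `hub_degree` extra producers inflate the
#'     co-product's connectivity. The obligatory drain penalizes
#'     whole-network resistance scores but lies outside the ROI's directed
#'     integration neighborhood.}
#' }
#'
#' @param template one of `"linear"`, `"branched"`, `"hub"`, `"glycogen"`,
#'   `"coproduct"`.
#' @param length chain length for `linear`.
#' @param pathway_length,distal_length segment lengths for `branched`.
#' @param hub_degree hub metabolite degree (`hub`), or number of extra
#'   co-product producers (`coproduct`).
#' @param roi_has_gene give the `branched` ROI its own coexpressed gene
#'   `g_roi` (default: data-less ROI).
#' @param isozymes number of interchangeable isozyme genes (`or`-joined)
#'   per enzymatic reaction of the `branched` template. The default 1
#'   gives one gene per reaction; central-metabolism reactions in animal
#'   models commonly carry 3-4 isozymes, which buffers single-cell
#'   dropout because a reaction loses all expression only when every
#'   isozyme drops out. Isozymes of pathway reactions are all pathway
#'   members; the ROI gene is always a single gene.
#' @param ub flux upper bound for all reactions.
#' @return a `metabolic_network` with attributes `roi` (base reaction id),
#'   `pathways` (named list of reaction-id sets), `pathway_genes`,
#'   `noise_genes`, and `chain` (reaction ids that carry the ground-truth
#'   flux).
#' @export
make_toy_network <- function(template = c("linear", "branched", "hub",
                                          "glycogen", "coproduct"),
                             length = 5, pathway_length = 4,
                             distal_length = 4, hub_degree = 8,
                             roi_has_gene = FALSE, isozymes = 1, ub = 1000) {
  template <- match.arg(template)
  mets <- character(0); rxns <- list()
  met <- function(id) mets <<- c(mets, id)
  rxn <- function(id, stoich, gpr = NULL) {
    rxns[[base::length(rxns) + 1]] <<- list(id = id, stoich = stoich, lb = 0,
                                            ub = ub, gpr = gpr)
  }
  att <- list(pathways = list(), pathway_genes = character(0),
              noise_genes = character(0), chain = character(0), roi = NULL)

  if (template == "linear") {
    if (length < 1) stop("linear template needs length >= 1")
    for (i in 0:length) met(paste0("m", i))
    rxn("UPT", c(m0 = 1))
    for (i in seq_len(length)) {
      rxn(paste0("R", i),
          setNames(c(-1, 1), paste0("m", c(i - 1, i))), paste0("g", i))
    }
    rxn("EXP", setNames(-1, paste0("m", length)))
    att$roi <- "R1"
    att$pathways <- list(main = paste0("R", seq_len(length)))
    att$pathway_genes <- paste0("g", seq_len(length))
    att$chain <- c("UPT", paste0("R", seq_len(length)), "EXP")
  } else if (template == "branched") {
    L <- pathway_length; K <- distal_length
    if (L < 1 || K < 1) stop("branched template needs positive segment lengths")
    iso <- function(stem) {   # "g1" or "g1 or g1.2 or g1.3" etc.
      if (isozymes <= 1) return(stem)
      paste(c(stem, paste0(stem, ".", 2:isozymes)), collapse = " or ")
    }
    iso_genes <- function(stem) {
      if (isozymes <= 1) return(stem)
      c(stem, paste0(stem, ".", 2:isozymes))
    }
    for (i in 0:K) met(paste0("u", i))       # distal metabolites; u0 == pathway start
    for (i in seq_len(L)) met(paste0("m", i))
    met("mR"); met("s1")
    rxn("UPT", setNames(1, paste0("u", K)))
    for (i in K:1) {                          # distal chain: uK -> ... -> u0
      rxn(paste0("U", i),
          setNames(c(-1, 1), paste0("u", c(i, i - 1))), iso(paste0("du", i)))
    }
    prev <- "u0"
    for (i in seq_len(L)) {                   # coexpressed pathway: u0 -> mL
      rxn(paste0("P", i), setNames(c(-1, 1), c(prev, paste0("m", i))),
          iso(paste0("g", i)))
      prev <- paste0("m", i)
    }
    rxn("ROI", setNames(c(-1, 1), c(prev, "mR")),
        if (roi_has_gene) "g_roi" else NULL)
    rxn("EXP", c(mR = -1))
    rxn("SIDE", c(u0 = -1, s1 = 1), "g_side") # optional side branch
    rxn("EXPS", c(s1 = -1))
    att$roi <- "ROI"
    att$pathways <- list(pathway = paste0("P", seq_len(L)),
                         distal = paste0("U", seq_len(K)))
    att$pathway_genes <- c(unlist(lapply(paste0("g", seq_len(L)), iso_genes)),
                           if (roi_has_gene) "g_roi")
    att$noise_genes <- c(unlist(lapply(paste0("du", seq_len(K)), iso_genes)),
                         "g_side")
    att$chain <- c("UPT", paste0("U", K:1), paste0("P", seq_len(L)),
                   "ROI", "EXP")
  } else if (template == "hub") {
    k <- hub_degree
    if (k < 2) stop("hub template needs degree >= 2")
    np <- ceiling(k / 2); nc <- k - np
    met("hub")
    for (i in seq_len(np)) {
      met(paste0("a", i))
      rxn(paste0("UPT", i), setNames(1, paste0("a", i)))
      rxn(paste0("P", i), setNames(c(-1, 1), c(paste0("a", i), "hub")),
          paste0("gp", i))
    }
    for (j in seq_len(nc)) {
      met(paste0("b", j))
      rxn(paste0("C", j), setNames(c(-1, 1), c("hub", paste0("b", j))),
          paste0("gc", j))
      rxn(paste0("EXP", j), setNames(-1, paste0("b", j)))
    }
    att$roi <- "P1"
    att$pathways <- list(producers = paste0("P", seq_len(np)),
                         consumers = paste0("C", seq_len(nc)))
    att$pathway_genes <- paste0("gp", seq_len(np))
    att$noise_genes <- paste0("gc", seq_len(nc))
    att$chain <- c("UPT1", "P1", "C1", "EXP1")
  } else if (template == "glycogen") {
    for (m in c("c", "g1m", "g2m", "o1", "o2")) met(m)
    rxn("UPT", c(c = 1))
    rxn("B1", c(c = -1, g1m = 1), "g_shared")
    rxn("B1b", c(g1m = -1, o1 = 1), "g_b1")
    rxn("EX1", c(o1 = -1))
    rxn("B2", c(c = -1, g2m = 1), "g_shared")
    rxn("B2b", c(g2m = -1, o2 = 1), "g_b2")
    rxn("EX2", c(o2 = -1))
    att$roi <- "B1"
    att$pathways <- list(branch1 = c("B1", "B1b"), branch2 = c("B2", "B2b"))
    att$pathway_genes <- c("g_shared", "g_b1")
    att$noise_genes <- "g_b2"
    att$chain <- c("UPT", "B1", "B1b", "EX1")
  } else { # coproduct
    for (m in c("s", "p", "q", "x", "y")) met(m)
    rxn("UPT", c(s = 1))
    rxn("LUMP", c(s = -1, p = 1, q = 1), "g_lump")
    rxn("ROI", c(p = -1, x = 1), "g_roi")
    rxn("EXPX", c(x = -1))
    rxn("DRAIN", c(q = -1, y = 1), "g_drain")
    rxn("EXPY", c(y = -1))
    for (i in seq_len(max(hub_degree - 2, 0))) {   # extra q producers: hub co-product
      met(paste0("z", i))
      rxn(paste0("ZUPT", i), setNames(1, paste0("z", i)))
      rxn(paste0("QP", i), setNames(c(-1, 1), c(paste0("z", i), "q")),
          paste0("gz", i))
    }
    att$roi <- "ROI"
    att$pathways <- list(main = c("LUMP", "ROI"), drain = "DRAIN")
    att$pathway_genes <- c("g_lump", "g_roi")
    att$noise_genes <- "g_drain"
    att$chain <- c("UPT", "LUMP", "ROI", "EXPX", "DRAIN", "EXPY")
  }

  net <- metabolic_network(
    data.frame(id = mets, compartment = "c", stringsAsFactors = FALSE),
    rxns)
  for (a in names(att)) attr(net, a) <- att[[a]]
  net
}

#' Simulate multi-condition expression with tunable pathway coexpression
#'
#' A log-normal (multiplicative-noise) expression model matching the
#' provenance of log2-scale proteomics: each condition draws a latent
#' pathway-activity factor; the log2 level of every pathway member gene is
#' `rho * factor + noise_sd * eps`, while non-member genes get independent
#' unit-variance noise. The ground-truth flux through the template's chain
#' is `2^(beta * factor + flux_noise_sd * eps)`, so flux and pathway
#' expression share the factor but neither determines the other exactly.
#'
#' @param net a [make_toy_network()] fixture (its `pathway_genes`,
#'   `noise_genes` and `chain` attributes drive the simulation).
#' @param n_conditions number of conditions (or cells).
#' @param rho coexpression loading of member genes on the factor, in
#'   \[-1, 1\].
#' @param beta flux-expression coupling.
#' @param noise_sd residual log2 sd of member genes; the default 0.6 is
#'   approximately `sqrt(1 - 0.8^2)`, so `rho = 0.8` yields pairwise
#'   member correlations near 0.64 on the log scale.
#' @param flux_noise_sd residual log2 sd of the ground-truth flux.
#' @param factor_mean per-condition shift of the latent factor (recycled);
#'   use a two-level vector to emulate two cell types with different
#'   pathway activity.
#' @param seed RNG seed; runs are reproducible per seed.
#' @return list with `levels` (gene x condition unscaled levels), `flux`
#'   (chain-reaction x condition ground-truth flux), `factor`
#'   (per-condition latent factor).
#' @export
simulate_expression <- function(net, n_conditions = 25, rho = 0.8, beta = 1,
                                noise_sd = 0.6, flux_noise_sd = 0.25,
                                factor_mean = 0, seed = 1) {
  stopifnot(abs(rho) <= 1, n_conditions >= 1)
  genes <- unique(unlist(lapply(net$gpr, gpr_genes)))
  member <- intersect(genes, attr(net, "pathway_genes"))
  other <- setdiff(genes, member)
  conds <- paste0("cond", seq_len(n_conditions))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  f <- rnorm(n_conditions) + rep_len(factor_mean, n_conditions)
  z <- matrix(NA_real_, length(genes), n_conditions,
              dimnames = list(genes, conds))
  for (g in member) z[g, ] <- rho * f + noise_sd * rnorm(n_conditions)
  for (g in other) z[g, ] <- rnorm(n_conditions)
  chain <- attr(net, "chain")
  fluxv <- 2^(beta * f + flux_noise_sd * rnorm(n_conditions))
  flux <- matrix(rep(fluxv, each = length(chain)), length(chain),
                 dimnames = list(chain, conds))
  list(levels = 2^z, flux = flux, factor = setNames(f, conds))
}

#' Apply single-cell dropout to an expression matrix
#'
#' Sets each measured entry to 0 independently with probability `rate`.
#' Dropouts are zeros, not missingness: the zero is data (an undetected
#' transcript), so downstream penalty mapping treats it as lowest observed
#' expression rather than excluding the gene.
#'
#' @param levels gene x condition (or cell) matrix.
#' @param rate dropout probability in \[0, 1).
#' @param seed RNG seed.
#' @return matrix of the same shape with zeroed entries.
#' @export
apply_dropout <- function(levels, rate, seed = 1) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(levels)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  drop <- matrix(runif(length(levels)) < rate, nrow(levels))
  levels[drop] <- 0
  levels
}
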