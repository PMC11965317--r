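#' Construct a metabolic network
#'
#' The canonical in-memory form of a genome-scale (or toy) metabolic model:
#' a stoichiometric matrix `S` (metabolites x reactions), flux bounds, and a
#' GPR rule per reaction. Exchange/boundary reactions are ordinary columns
#' with a single nonzero entry; no id-prefix conventions are assumed.
#'
#' @param metabolites data.frame with columns `id` and `compartment`.
#' @param reactions list of reaction records, each a list with elements
#'   `id`, `stoich` (named numeric, names are metabolite ids; negative =
#'   consumed, positive = produced), `lb`, `ub` (flux bounds, a.u.), and
#'   optionally `gpr` (a rule string, parsed with [parse_gpr()]).
#' @return a `metabolic_network`: list with `S` (dense named matrix),
#'   `lb`, `ub` (named numeric), `gpr` (named list of `gpr` trees or `NULL`),
#'   `compartment` (named character).
#' @export
metabolic_network <- function(metabolites, reactions) {
  met_ids <- as.character(metabolites$id)
  if (anyDuplicated(met_ids)) {
    stop("duplicate metabolite id: ", met_ids[duplicated(met_ids)][1])
  }
  rxn_ids <- vapply(reactions, function(r) as.character(r$id), character(1))
  if (anyDuplicated(rxn_ids)) {
    stop("duplicate reaction id: ", rxn_ids[duplicated(rxn_ids)][1])
  }
  S <- matrix(0, nrow = length(met_ids), ncol = length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  lb <- ub <- setNames(numeric(length(rxn_ids)), rxn_ids)
  gpr <- setNames(vector("list", length(rxn_ids)), rxn_ids)
  for (r in reactions) {
    st <- r$stoich
    if (is.null(names(st)) || any(!nzchar(names(st))) || anyNA(st) ||
        !is.numeric(st)) {
      stop("malformed stoichiometry in reaction '", r$id, "'")
    }
    unknown <- setdiff(names(st), met_ids)
    if (length(unknown)) {
      stop("reaction '", r$id, "' references undeclared metabolite: ",
           unknown[1])
    }
    if (r$lb > r$ub) stop("reaction '", r$id, "' has lb > ub")
    S[names(st), r$id] <- st
    lb[r$id] <- r$lb
    ub[r$id] <- r$ub
    if (!is.null(r$gpr)) {
      g <- if (inherits(r$gpr, "gpr")) r$gpr else {
        tryCatch(parse_gpr(r$gpr), error = function(e) {
          warning("unparseable GPR for reaction '", r$id, "' (",
                  conditionMessage(e), "); treated as no GPR", call. = FALSE)
          NULL
        })
      }
      gpr[[r$id]] <- g
    }
  }
  structure(
    list(S = S, lb = lb, ub = ub, gpr = gpr,
         compartment = setNames(as.character(metabolites$compartment), met_ids)),
    class = "metabolic_network"
  )
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("<metabolic_network> ", ncol(x$S), " reactions, ", nrow(x$S),
      " metabolites (", sum(is_reversible(x)), " reversible)\n", sep = "")
  invisible(x)
}

#' Reversibility of each reaction
#'
#' A reaction is reversible when it can carry flux in both directions
#' (`lb < 0` and `ub > 0`).
#' @param net a `metabolic_network`.
#' @return named logical vector.
#' @export
is_reversible <- function(net) net$lb < 0 & net$ub > 0

#' Load a metabolic model from SBML or the JSON interchange format
#'
#' SBML Level 3 with the FBC extension is supported (species, reactions,
#' flux bounds via FBC bound parameters, gene associations via
#' `geneProductAssociation`). The JSON format mirrors the
#' [metabolic_network()] fields directly and round-trips losslessly with
#' [write_model()].
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"sbml"` or `"json"`.
#' @return a `metabolic_network`.
#' @export
read_model <- function(path, format = c("auto", "sbml", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  if (format == "sbml") read_model_sbml(path) else read_model_json(path)
}

read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  mets <- data.frame(
    id = vapply(obj$metabolites, function(m) m$id, character(1)),
    compartment = vapply(obj$metabolites, function(m) {
      if (is.null(m$compartment)) "" else m$compartment
    }, character(1)),
    stringsAsFactors = FALSE
  )
  rxns <- lapply(obj$reactions, function(r) {
    list(id = r$id,
         stoich = unlist(r$stoichiometry),
         lb = r$lower_bound, ub = r$upper_bound,
         gpr = if (is.null(r$gpr) || !nzchar(r$gpr)) NULL else r$gpr)
  })
  metabolic_network(mets, rxns)
}

#' Write a metabolic model to the JSON interchange format
#'
#' @param net a `metabolic_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(net, path) {
  mets <- lapply(rownames(net$S), function(m) {
    list(id = m, compartment = unname(net$compartment[m]))
  })
  rxns <- lapply(colnames(net$S), function(r) {
    st <- net$S[, r]
    st <- st[st != 0]
    list(id = r, stoichiometry = as.list(st),
         lower_bound = unname(net$lb[r]), upper_bound = unname(net$ub[r]),
         gpr = gpr_to_string(net$gpr[[r]]))
  })
  jsonlite::write_json(list(metabolites = mets, reactions = rxns), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Minimal SBML L3 + FBC reader (xml2-based). Reads species, reactions with
# reactant/product stoichiometries, FBC flux bound parameters and FBC gene
# product associations. Gene products are reported by their fbc:label when
# present, else their fbc:id.
read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  params <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                   xml2::xml_attr(params, "id"))

  gps <- xml2::xml_find_all(doc, ".//*[local-name()='listOfGeneProducts']/*")
  gp_id <- xml2::xml_attr(gps, "id")
  gp_label <- xml2::xml_attr(gps, "label")
  gp_label[is.na(gp_label)] <- gp_id[is.na(gp_label)]
  gp_map <- setNames(gp_label, gp_id)

  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  boundary <- xml2::xml_attr(sp, "boundaryCondition")
  keep <- is.na(boundary) | boundary != "true"
  mets <- data.frame(
    id = xml2::xml_attr(sp, "id")[keep],
    compartment = xml2::xml_attr(sp, "compartment")[keep],
    stringsAsFactors = FALSE
  )

  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- lapply(rx, function(node) {
    id <- xml2::xml_attr(node, "id")
    st <- numeric(0)
    bump <- function(s, k) {
      cur <- if (s %in% names(st)) st[[s]] else 0
      st[s] <<- cur + k
    }
    for (ref in xml2::xml_find_all(node, "./listOfReactants/speciesReference")) {
      k <- as.numeric(xml2::xml_attr(ref, "stoichiometry"))
      bump(xml2::xml_attr(ref, "species"), -(if (is.na(k)) 1 else k))
    }
    for (ref in xml2::xml_find_all(node, "./listOfProducts/speciesReference")) {
      k <- as.numeric(xml2::xml_attr(ref, "stoichiometry"))
      bump(xml2::xml_attr(ref, "species"), if (is.na(k)) 1 else k)
    }
    st <- st[names(st) %in% mets$id]  # drop boundary species
    lb_id <- xml2::xml_attr(node, "lowerFluxBound")
    ub_id <- xml2::xml_attr(node, "upperFluxBound")
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb <- if (!is.na(lb_id) && lb_id %in% names(pval)) pval[[lb_id]] else
      if (rev) -1000 else 0
    ub <- if (!is.na(ub_id) && ub_id %in% names(pval)) pval[[ub_id]] else 1000
    gpa <- xml2::xml_find_first(
      node, "./*[local-name()='geneProductAssociation']/*")
    gpr <- if (inherits(gpa, "xml_missing")) NULL else {
      tryCatch(sbml_gpa_to_gpr(gpa, gp_map), error = function(e) {
        warning("unparseable GPR for reaction '", id, "'; treated as no GPR",
                call. = FALSE)
        NULL
      })
    }
    list(id = id, stoich = st, lb = lb, ub = ub, gpr = gpr)
  })
  metabolic_network(mets, rxns)
}

sbml_gpa_to_gpr <- function(node, gp_map) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    gene <- if (ref %in% names(gp_map)) gp_map[[ref]] else ref
    return(structure(list(gene = gene), class = "gpr"))
  }
  if (nm %in% c("and", "or")) {
    kids <- lapply(xml2::xml_children(node), sbml_gpa_to_gpr, gp_map = gp_map)
    return(gpr_node(nm, kids))
  }
  stop("unsupported gene association element: ", nm)
}

#' Summarize a model as a reaction table
#'
#' @param net a `metabolic_network`.
#' @return data.frame with reaction id, formula, bounds, reversibility flag
#'   and GPR string.
#' @export
model_summary <- function(net) {
  rev <- is_reversible(net)
  formula <- vapply(colnames(net$S), function(r) {
    st <- net$S[, r]
    lhs <- st[st < 0]; rhs <- st[st > 0]
    fmt <- function(v) {
      if (!length(v)) return("")
      paste(ifelse(abs(v) == 1, names(v), paste(abs(v), names(v))),
            collapse = " + ")
    }
    paste(fmt(lhs), if (rev[r]) "<=>" else "-->", fmt(rhs))
  }, character(1))
  data.frame(
    reaction = colnames(net$S), formula = formula,
    lb = unname(net$lb), ub = unname(net$ub), reversible = unname(rev),
    gpr = vapply(net$gpr, gpr_to_string, character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write the model summary as TSV
#' @param net a `metabolic_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_summary <- function(net, path) {
  write.table(model_summary(net), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Split reversible reactions into directed forward/reverse pairs
#'
#' Every reaction of the resulting network runs in a single direction with
#' bounds `[0, ub]`, which makes the penalty-weighted flux sum of eFPA linear
#' in nonnegative fluxes. A reversible reaction yields two directed copies
#' with mirrored stoichiometry; an irreversible one yields a single copy
#' (reactions with `lb < 0, ub <= 0` are flipped to run forward).
#'
#' @param net a `metabolic_network`.
#' @return a `directed_network`: list with `S`, `ub` (named), `base_id` and
#'   `direction` (`"f"`/`"r"`) per directed reaction, and the original
#'   network as `$network`.
#' @export
split_reversible <- function(net) {
  cols <- list(); ub <- c(); base <- c(); dirn <- c()
  add <- function(id, s, u, b, d) {
    cols[[id]] <<- s; ub[id] <<- u; base[id] <<- b; dirn[id] <<- d
  }
  for (r in colnames(net$S)) {
    s <- net$S[, r]; lo <- net$lb[[r]]; hi <- net$ub[[r]]
    if (lo < 0 && hi > 0) {            # reversible: two directed copies
      add(paste0(r, "_f"), s, hi, r, "f")
      add(paste0(r, "_r"), -s, -lo, r, "r")
    } else if (hi > 0 || (hi == 0 && lo >= 0)) {  # forward (incl. blocked)
      add(paste0(r, "_f"), s, max(hi, 0), r, "f")
    } else {                            # lb < 0, ub <= 0: reverse only
      add(paste0(r, "_r"), -s, -lo, r, "r")
    }
  }
  S <- do.call(cbind, cols)
  rownames(S) <- rownames(net$S)
  structure(list(S = S, ub = ub, base_id = base, direction = dirn,
                 network = net),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat("<directed_network> ", ncol(x$S), " directed reactions over ",
      length(unique(x$base_id)), " base reactions\n", sep = "")
  invisible(x)
}

#' Directed reaction id for a base reaction and direction
#' @param dnet a `directed_network`.
#' @param roi base reaction id.
#' @param direction `"f"` or `"r"`.
#' @return the directed reaction id.
#' @export
directed_id <- function(dnet, roi, direction = "f") {
  hit <- names(dnet$base_id)[dnet$base_id == roi & dnet$direction == direction]
  if (!length(hit)) {
    stop("no directed reaction for '", roi, "' direction '", direction, "'")
  }
  hit
}
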