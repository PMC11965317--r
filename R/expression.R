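#' Adjust measured fluxes by growth rate
#'
#' Chemostat flux measurements scale with the dilution (growth) rate;
#' dividing each condition's fluxes by its growth rate yields the per-unit
#' growth flux levels used in correlation analyses.
#'
#' @param flux reaction x condition numeric matrix (a.u.).
#' @param growth_rate named numeric, one positive rate (1/h) per condition.
#' @return matrix of the same shape, `flux[, j] / growth_rate[j]`.
#' @export
growth_adjust_flux <- function(flux, growth_rate) {
  flux <- as.matrix(flux)
  if (is.null(colnames(flux))) stop("flux must have condition column names")
  miss <- setdiff(colnames(flux), names(growth_rate))
  if (length(miss)) stop("no growth rate for condition: ", miss[1])
  g <- growth_rate[colnames(flux)]
  bad <- names(g)[!is.finite(g) | g <= 0]
  if (length(bad)) stop("non-positive growth rate for condition: ", bad[1])
  sweep(flux, 2, g, "/")
}

#' Undo a log2 transform
#'
#' Proteomics tables are commonly reported on the log2 scale; the penalty
#' machinery works on unscaled (linear) relative abundances.
#'
#' @param x numeric (finite).
#' @return `2^x`.
#' @export
unscale_log2 <- function(x) 2^x

#' Reaction-level expression from a GPR rule (one condition)
#'
#' Maps gene levels to a single reaction-level value: `and` nodes (enzyme
#' complexes) take the minimum of their children, `or` nodes (isozymes) the
#' sum. Unmeasured genes are excluded from `or` sums; an `and` node with
#' some unmeasured children uses the minimum of its measured children only.
#' Either case downgrades the status to `"partial"`. A node whose children
#' are all unmeasured - and an empty GPR - yields `"missing"`.
#'
#' @param gpr a `gpr` tree (or `NULL`).
#' @param levels named numeric, nonnegative gene levels for one condition.
#' @param measured named logical; genes absent from `levels` or flagged
#'   `FALSE` count as unmeasured. Defaults to "present in `levels`".
#' @return list with `value` (numeric or `NA`) and
#'   `status` (`"complete"`, `"partial"` or `"missing"`).
#' @export
reaction_raw_expression <- function(gpr, levels, measured = NULL) {
  genes <- gpr_genes(gpr)
  if (!length(genes)) return(list(value = NA_real_, status = "missing"))
  if (is.null(measured)) {
    measured <- setNames(genes %in% names(levels), genes)
  }
  is_meas <- function(g) isTRUE(measured[[g]]) && !is.na(levels[[g]])
  ev <- function(node) {
    if (!is.null(node$gene)) {
      if (is_meas(node$gene)) return(levels[[node$gene]])
      return(NA_real_)
    }
    vals <- vapply(node$children, ev, numeric(1))
    ok <- !is.na(vals)
    if (!any(ok)) return(NA_real_)
    if (node$op == "and") min(vals[ok]) else sum(vals[ok])
  }
  value <- ev(gpr)
  n_meas <- sum(vapply(genes, is_meas, logical(1)))
  status <- if (is.na(value) || n_meas == 0) "missing"
            else if (n_meas == length(genes)) "complete" else "partial"
  if (status == "missing") value <- NA_real_
  list(value = value, status = status)
}

#' Map a gene expression matrix to reaction-level raw expression
#'
#' Applies [reaction_raw_expression()] to every reaction of a model across
#' all conditions. Zeros in `levels` are data (e.g. single-cell dropout);
#' only genes missing from the matrix (or flagged unmeasured) are treated
#' as absent.
#'
#' @param net a `metabolic_network`.
#' @param levels gene x condition nonnegative matrix with row/col names.
#' @param measured optional gene x condition logical matrix (or a named
#'   logical vector applying to all conditions).
#' @return list with `raw` (reaction x condition matrix, `NA` where missing)
#'   and `status` (named character per reaction; `"partial"`/`"missing"` if
#'   any condition is).
#' @export
reaction_expression <- function(net, levels, measured = NULL) {
  levels <- as.matrix(levels)
  if (any(levels < 0, na.rm = TRUE)) stop("expression levels must be nonnegative")
  conds <- colnames(levels)
  rxns <- colnames(net$S)
  raw <- matrix(NA_real_, length(rxns), length(conds),
                dimnames = list(rxns, conds))
  status <- setNames(rep("missing", length(rxns)), rxns)
  for (r in rxns) {
    g <- net$gpr[[r]]
    if (is.null(g)) next
    st_r <- character(length(conds))
    for (j in seq_along(conds)) {
      lev <- setNames(levels[, j], rownames(levels))
      meas <- if (is.null(measured)) NULL
              else if (is.matrix(measured)) setNames(measured[, j], rownames(measured))
              else measured
      res <- reaction_raw_expression(g, lev, meas)
      raw[r, j] <- res$value
      st_r[j] <- res$status
    }
    status[r] <- if (all(st_r == "complete")) "complete"
                 else if (all(st_r == "missing")) "missing" else "partial"
  }
  list(raw = raw, status = status)
}

#' Normalize raw reaction expression to relative expression in [0, 1]
#'
#' Each reaction row is divided by its own maximum across conditions, so a
#' measured reaction attains 1 in the condition where it is most expressed.
#' All-zero rows (measured but never expressed) get 0 everywhere and are
#' flagged `zero`; rows without data stay `NA` with status `"missing"`.
#'
#' @param raw reaction x condition matrix (`NA` = missing).
#' @param status optional per-reaction status vector from
#'   [reaction_expression()]; carried through.
#' @return a `reaction_expression` object: list with `rel` (matrix in
#'   \[0,1\]), `status`, and `zero` (logical per reaction).
#' @export
normalize_relative <- function(raw, status = NULL) {
  raw <- as.matrix(raw)
  if (is.null(status)) {
    status <- setNames(ifelse(rowSums(!is.na(raw)) > 0, "complete", "missing"),
                       rownames(raw))
  }
  rel <- raw
  zero <- setNames(rep(FALSE, nrow(raw)), rownames(raw))
  for (r in rownames(raw)) {
    v <- raw[r, ]
    if (all(is.na(v))) next
    m <- max(v, na.rm = TRUE)
    if (m <= 0) {
      rel[r, !is.na(v)] <- 0
      zero[r] <- TRUE
    } else {
      rel[r, ] <- v / m
    }
  }
  structure(list(rel = rel, status = status, zero = zero),
            class = "reaction_expression")
}

#' @export
print.reaction_expression <- function(x, ...) {
  cat("<reaction_expression> ", nrow(x$rel), " reactions x ", ncol(x$rel),
      " conditions (", sum(x$status == "complete"), " complete, ",
      sum(x$status == "partial"), " partial, ",
      sum(x$status == "missing"), " missing)\n", sep = "")
  invisible(x)
}

#' Wrap an already-normalized matrix as a reaction expression object
#'
#' For relative expression computed elsewhere (values in \[0, 1\], `NA` for
#' reactions without data). Use [normalize_relative()] instead when starting
#' from raw reaction-level values.
#'
#' @param m reaction x condition matrix in \[0, 1\] with row names.
#' @param status optional per-reaction status (`"complete"`, `"partial"`,
#'   `"missing"`); inferred from missingness when absent.
#' @return a `reaction_expression`.
#' @export
as_reaction_expression <- function(m, status = NULL) {
  m <- as.matrix(m)
  if (any(m < -1e-9 | m > 1 + 1e-9, na.rm = TRUE)) {
    stop("relative expression must lie in [0, 1]")
  }
  if (is.null(status)) {
    status <- setNames(ifelse(rowSums(!is.na(m)) > 0, "complete", "missing"),
                       rownames(m))
  }
  structure(list(rel = m, status = status,
                 zero = setNames(rep(FALSE, nrow(m)), rownames(m))),
            class = "reaction_expression")
}

#' Expression penalties (weight precursors) from relative expression
#'
#' The penalty of a reaction in a condition is the reciprocal of its
#' relative expression, floored at `eps` so that zeros (e.g. dropout) give a
#' large but finite penalty of `1/eps`. Reactions without any expression
#' data get penalty 0: they are excluded from the weighted flux sum and can
#' carry flux freely, which is what makes gap-filling predictions possible.
#'
#' @param rel a `reaction_expression` (or a plain matrix in \[0,1\]).
#' @param eps positive floor on relative expression; default `1e-3` caps
#'   penalties at 1000.
#' @return a `penalty_matrix`: list with `penalty` (reaction x condition),
#'   `has_data` (logical per reaction) and `eps`.
#' @export
penalty_matrix <- function(rel, eps = 1e-3) {
  if (!is.numeric(eps) || length(eps) != 1 || eps <= 0) stop("eps must be > 0")
  if (inherits(rel, "reaction_expression")) {
    m <- rel$rel
    has_data <- rel$status != "missing"
  } else {
    m <- as.matrix(rel)
    has_data <- setNames(rowSums(!is.na(m)) > 0, rownames(m))
  }
  pen <- 1 / pmax(m, eps)
  pen[is.na(pen)] <- 0
  pen[!has_data, ] <- 0
  structure(list(penalty = pen, has_data = has_data, eps = eps),
            class = "penalty_matrix")
}

#' Read a gene expression TSV (genes in the first column)
#'
#' @param path TSV path; first column gene ids, remaining columns conditions.
#' @return numeric matrix with gene row names.
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a reaction x condition matrix as TSV
#'
#' @param m matrix (e.g. `$rel` of a `reaction_expression`, or
#'   `$penalty` of a `penalty_matrix`).
#' @param path output path.
#' @param id_col name of the first (id) column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "reaction") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
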