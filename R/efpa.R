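#' Distance decay specification
#'
#' The decay function multiplies expression penalties by a factor in
#' \[0, 1\] that shrinks with network distance from the ROI, confining the
#' integration of expression data to the ROI's neighborhood. Three families:
#' \describe{
#'   \item{`power`}{`(1 + d)^(-n)` - the original FPA decay; `n = 0`
#'     disables decay entirely (whole-network integration).}
#'   \item{`hard_boundary`}{1 for `d <= b`, 0 beyond: a sharp integration
#'     radius.}
#'   \item{`exponential`}{1 for `d <= b`, then `2^-(d - b)`: full weight
#'     inside the boundary with a soft exponential tail. With `b = 6` on
#'     the weighted metric this is the standard eFPA decay.}
#' }
#'
#' @param family `"exponential"`, `"hard_boundary"` or `"power"`.
#' @param order decay order `n >= 0` (power family).
#' @param boundary distance boundary `b >= 0` (boundary families).
#' @return a `decay_spec`.
#' @export
decay_spec <- function(family = c("exponential", "hard_boundary", "power"),
                       order = NULL, boundary = NULL) {
  family <- match.arg(family)
  if (family == "power") {
    if (is.null(order) || order < 0) stop("power decay needs order >= 0")
    boundary <- NA_real_
  } else {
    if (is.null(boundary) || boundary < 0) stop(family, " decay needs boundary >= 0")
    order <- NA_real_
  }
  structure(list(family = family, order = order, boundary = boundary),
            class = "decay_spec")
}

#' Evaluate a distance decay function
#'
#' @param d nonnegative distances (may contain `Inf` for unreachable
#'   reactions, which always decay to 0).
#' @param spec a [decay_spec()].
#' @return decay factors in \[0, 1\].
#' @export
decay <- function(d, spec) {
  out <- switch(spec$family,
    power = (1 + d)^(-spec$order),
    hard_boundary = as.numeric(d <= spec$boundary),
    exponential = ifelse(d <= spec$boundary, 1, 2^(-(d - spec$boundary)))
  )
  out[!is.finite(d)] <- 0
  # power decay with n = 0 integrates everything reachable, but an
  # unreachable reaction still carries no information about the ROI
  out
}

#' eFPA configuration
#'
#' @param allowance flux allowance `A > 0` (a.u.): the budget on the
#'   penalty-weighted flux sum. rFP is invariant to it, so the default of 1
#'   is arbitrary.
#' @param decay a [decay_spec()]; default exponential with boundary 6
#'   ("standard eFPA").
#' @param metric `"weighted"` (metabolite-degree weighted distance, the
#'   eFPA default) or `"naive"`.
#' @param eps penalty floor passed to [penalty_matrix()].
#' @param tol numerical tolerance for rFP definedness and status checks.
#' @return an `efpa_config`.
#' @export
efpa_config <- function(allowance = 1,
                        decay = decay_spec("exponential", boundary = 6),
                        metric = c("weighted", "naive"),
                        eps = 1e-3, tol = 1e-6) {
  if (allowance <= 0) stop("flux allowance must be > 0")
  structure(list(allowance = allowance, decay = decay,
                 metric = match.arg(metric), eps = eps, tol = tol),
            class = "efpa_config")
}

#' Weight coefficients for the eFPA budget row
#'
#' `w_j = decay(d_j) * penalty_j`, where the penalty of a directed reaction
#' is the penalty of its base reaction (both directions share one enzyme
#' complement) and `d_j` is its distance from the ROI (`d = 0` for the ROI
#' itself). Reactions without expression data have penalty 0 and therefore
#' weight 0 everywhere.
#'
#' @param penalty_col named numeric, penalty per base reaction (one
#'   condition's column of a [penalty_matrix()]).
#' @param dist_row named numeric, distance per directed reaction (one row
#'   of a [distance_map()] matrix).
#' @param spec a [decay_spec()].
#' @param base_id named character mapping directed reaction id to base id.
#' @return named numeric weight per directed reaction.
#' @export
efpa_weights <- function(penalty_col, dist_row, spec, base_id) {
  p <- penalty_col[base_id[names(dist_row)]]
  setNames(decay(dist_row, spec) * as.numeric(p), names(dist_row))
}

#' Flux potential of one ROI direction (single LP)
#'
#' Maximizes the ROI flux subject to steady state, directed bounds and the
#' weighted flux budget `sum_j w_j v_j <= A`. Reactions with small weights
#' (well expressed, or distant from the ROI) can carry flux almost freely;
#' poorly expressed reactions near the ROI eat into the allowance and limit
#' the attainable ROI flux.
#'
#' @param dnet a `directed_network`.
#' @param roi directed reaction id.
#' @param weights named numeric weight per directed reaction (see
#'   [efpa_weights()]).
#' @param allowance flux allowance `A > 0`.
#' @param tol numerical tolerance.
#' @return list with `fp` (the flux potential), `status` (`"optimal"`,
#'   `"clamped"` when only the flux bounds limit the ROI, `"infeasible"`,
#'   ...) and `solution` (the optimal flux vector).
#' @export
flux_potential <- function(dnet, roi, weights, allowance = 1, tol = 1e-6) {
  n <- ncol(dnet$S)
  if (!roi %in% colnames(dnet$S)) stop("unknown directed reaction: ", roi)
  w <- as.numeric(weights[colnames(dnet$S)])
  w[is.na(w)] <- 0
  obj <- as.numeric(colnames(dnet$S) == roi)
  res <- solve_flux_lp(obj, dnet$S, dnet$ub,
                       leq_mat = matrix(w, 1), leq_rhs = allowance)
  if (res$status %in% c("infeasible", "error")) {
    return(list(fp = 0, status = res$status, solution = res$solution))
  }
  status <- res$status
  if (res$value >= dnet$ub[[roi]] - tol) status <- "clamped"
  list(fp = max(res$value, 0), status = status, solution = res$solution)
}

#' Relative flux potential
#'
#' @param fp flux potential of the condition.
#' @param fp_super flux potential of the super condition (all relative
#'   expression at the observed maximum, i.e. penalties 1).
#' @param tol values of `fp_super` at or below `tol` make rFP undefined
#'   (`NA`).
#' @return `fp / fp_super`, or `NA` when undefined.
#' @export
relative_fp <- function(fp, fp_super, tol = 1e-6) {
  ifelse(fp_super > tol, fp / fp_super, NA_real_)
}

#' Run enhanced flux potential analysis
#'
#' For each ROI direction, distances are computed once; then one LP per
#' condition plus one super-condition LP (penalty 1 for every data-bearing
#' reaction) yield FP, FP_super and rFP = FP / FP_super.
#'
#' @param net a `metabolic_network`.
#' @param rel a `reaction_expression` (see [normalize_relative()]).
#' @param rois base reaction ids to analyze (default: all reactions).
#'   Reversible reactions are analyzed per direction.
#' @param config an [efpa_config()].
#' @param directions restrict to `"f"`, `"r"` or both (default).
#' @param bounds optional named numeric of upper-bound overrides on
#'   directed reaction ids (e.g. to block a nutrient uptake, set it to 0).
#' @param dist_mode distance orientation, see [shortest_distances()].
#' @param exclude_roi drop each ROI's own expression penalty (set to 0 in
#'   both the condition and the super-condition LP), so its rFP derives
#'   entirely from the network neighborhood. Useful when the ROI's own
#'   measurement is unreliable (e.g. single-cell dropout) and to test that
#'   predictions are not driven by the cognate enzyme alone.
#' @return an `fp_result` data.frame with columns `roi`, `direction`,
#'   `condition`, `fp`, `fp_super`, `rfp`, `status`. The super-condition
#'   LP status is appended to `status` when it is not optimal.
#' @export
run_efpa <- function(net, rel, rois = colnames(net$S),
                     config = efpa_config(), directions = c("f", "r"),
                     bounds = NULL, dist_mode = "both", exclude_roi = FALSE) {
  stopifnot(inherits(rel, "reaction_expression"))
  dnet <- split_reversible(net)
  if (!is.null(bounds)) {
    bad <- setdiff(names(bounds), colnames(dnet$S))
    if (length(bad)) stop("bound override for unknown directed reaction: ", bad[1])
    dnet$ub[names(bounds)] <- bounds
  }
  graph <- reaction_graph(dnet)
  pen <- penalty_matrix(rel, eps = config$eps)
  conds <- colnames(pen$penalty)
  super_pen <- setNames(as.numeric(pen$has_data), names(pen$has_data))

  droi <- names(dnet$base_id)[dnet$base_id %in% rois &
                                dnet$direction %in% directions]
  out <- vector("list", length(droi))
  for (k in seq_along(droi)) {
    r <- droi[k]
    d <- shortest_distances(graph, r, config$metric, dist_mode)
    sp <- super_pen
    if (exclude_roi) sp[dnet$base_id[[r]]] <- 0
    w_super <- efpa_weights(sp, d, config$decay, dnet$base_id)
    sup <- flux_potential(dnet, r, w_super, config$allowance, config$tol)
    rows <- lapply(conds, function(cn) {
      pc <- pen$penalty[, cn]
      if (exclude_roi) pc[dnet$base_id[[r]]] <- 0
      w <- efpa_weights(pc, d, config$decay, dnet$base_id)
      res <- flux_potential(dnet, r, w, config$allowance, config$tol)
      status <- res$status
      if (sup$status != "optimal") {
        status <- paste0(status, ";super_", sup$status)
      }
      data.frame(roi = dnet$base_id[[r]], direction = dnet$direction[[r]],
                 condition = cn, fp = res$fp, fp_super = sup$fp,
                 rfp = relative_fp(res$fp, sup$fp, config$tol),
                 status = status, stringsAsFactors = FALSE)
    })
    out[[k]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  class(res) <- c("fp_result", class(res))
  res
}

#' Reshape an eFPA result to a wide rFP matrix
#'
#' @param fpres an `fp_result` from [run_efpa()] (or a compatible
#'   data.frame).
#' @param value which column to spread (default `"rfp"`).
#' @return matrix with rows `roi_direction` and condition columns.
#' @export
rfp_matrix <- function(fpres, value = "rfp") {
  key <- paste(fpres$roi, fpres$direction, sep = "_")
  rows <- unique(key)
  conds <- unique(fpres$condition)
  m <- matrix(NA_real_, length(rows), length(conds),
              dimnames = list(rows, conds))
  m[cbind(match(key, rows), match(fpres$condition, conds))] <- fpres[[value]]
  m
}
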