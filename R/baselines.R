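#' Reaction expression score (cognate-enzyme baseline)
#'
#' The simplest flux proxy: the ROI's own relative expression, i.e. the
#' reciprocal of its expression penalty (off the penalty floor). No network
#' information is used, so reactions without expression data - and branches
#' sharing a GPR - cannot be scored or separated.
#'
#' @param rel a `reaction_expression`.
#' @param roi base reaction id.
#' @return named numeric per condition in \[0, 1\]; all-`NA` when the ROI
#'   has no expression data.
#' @export
reaction_expression_score <- function(rel, roi) {
  stopifnot(inherits(rel, "reaction_expression"))
  if (!roi %in% rownames(rel$rel)) stop("unknown reaction: ", roi)
  rel$rel[roi, ]
}

#' Compass configuration
#'
#' @param optimum_fraction fraction `f` of the unconstrained ROI optimum
#'   that the resistance LP must sustain; 0.95 is the published Compass
#'   default.
#' @param tol numerical tolerance.
#' @return a `compass_config`.
#' @export
compass_config <- function(optimum_fraction = 0.95, tol = 1e-6) {
  if (optimum_fraction <= 0 || optimum_fraction > 1) {
    stop("optimum_fraction must be in (0, 1]")
  }
  structure(list(optimum_fraction = optimum_fraction, tol = tol),
            class = "compass_config")
}

# Two-stage Compass resistance for one penalty column.
# Stage 1: v* = max v_roi under steady state and bounds.
# Stage 2: resistance = min sum_j w_j v_j s.t. v_roi >= f v*.
compass_resistance <- function(dnet, roi, stage2_weights, cfg) {
  obj <- as.numeric(colnames(dnet$S) == roi)
  s1 <- solve_flux_lp(obj, dnet$S, dnet$ub)
  if (s1$status %in% c("infeasible", "error") || s1$value <= cfg$tol) {
    return(list(resistance = NA_real_, vstar = max(s1$value, 0),
                status = "blocked"))
  }
  target <- cfg$optimum_fraction * s1$value
  w <- as.numeric(stage2_weights[colnames(dnet$S)])
  w[is.na(w)] <- 0
  s2 <- solve_flux_lp(w, dnet$S, dnet$ub,
                      geq_mat = matrix(obj, 1), geq_rhs = target,
                      maximize = FALSE)
  list(resistance = s2$value, vstar = s1$value, status = s2$status)
}

#' Compass- flux resistance score
#'
#' Compass without cell lumping: the minimal penalty-weighted total network
#' flux (the "resistance") needed to sustain a fraction `f` of the ROI's
#' unconstrained optimum. For comparability with eFPA and reaction
#' expression, the raw resistance is normalized against the super cell
#' (penalty 1 on every data-bearing reaction):
#' `score = resistance_super / resistance_cell`, clipped to \[0, 1\], so
#' higher always means more predicted flux capacity. No distance decay is
#' applied - every reaction in the network contributes at full weight.
#'
#' @param dnet a `directed_network`.
#' @param roi directed reaction id.
#' @param penalties a `penalty_matrix` (eFPA penalties, as in the fair
#'   benchmarking configuration).
#' @param cfg a [compass_config()].
#' @return data.frame per condition: `condition`, `resistance`,
#'   `resistance_super`, `score`, `status`.
#' @export
compass_minus <- function(dnet, roi, penalties, cfg = compass_config()) {
  compass_score(dnet, roi, penalties, cfg, decay_order = 0,
                dist_row = NULL)
}

#' Compass with the original FPA distance decay
#'
#' As [compass_minus()], but the stage-2 objective weights are
#' `decay(d; power n) * penalty` over naive metabolic distances, localizing
#' the resistance to the ROI's neighborhood.
#'
#' @inheritParams compass_minus
#' @param order power-decay order `n`; `n = 0` reduces to plain Compass-,
#'   2.5 is the best-performing FPA order.
#' @param dist_row naive distances from the ROI (one row of a
#'   [distance_map()]`$naive`); computed from `dnet` when `NULL`.
#' @param dist_mode distance orientation when computing `dist_row`.
#' @export
compass_with_decay <- function(dnet, roi, penalties, order = 2.5,
                               cfg = compass_config(), dist_row = NULL,
                               dist_mode = "both") {
  compass_score(dnet, roi, penalties, cfg, decay_order = order,
                dist_row = dist_row, dist_mode = dist_mode)
}

compass_score <- function(dnet, roi, penalties, cfg, decay_order,
                          dist_row = NULL, dist_mode = "both") {
  stopifnot(inherits(penalties, "penalty_matrix"))
  if (!roi %in% colnames(dnet$S)) stop("unknown directed reaction: ", roi)
  if (decay_order > 0) {
    if (is.null(dist_row)) {
      dist_row <- shortest_distances(reaction_graph(dnet), roi, "naive",
                                     dist_mode)
    }
    dec <- decay(dist_row, decay_spec("power", order = decay_order))
    dec <- dec[colnames(dnet$S)]
  } else {
    dec <- setNames(rep(1, ncol(dnet$S)), colnames(dnet$S))
  }
  base <- dnet$base_id[colnames(dnet$S)]
  super_pen <- as.numeric(penalties$has_data[base])
  sup <- compass_resistance(dnet, roi,
                            setNames(dec * super_pen, colnames(dnet$S)), cfg)
  conds <- colnames(penalties$penalty)
  rows <- lapply(conds, function(cn) {
    p <- penalties$penalty[base, cn]
    res <- compass_resistance(dnet, roi, setNames(dec * p, colnames(dnet$S)),
                              cfg)
    score <- if (identical(res$status, "blocked")) 0
      else if (!is.finite(res$resistance) || !is.finite(sup$resistance)) NA_real_
      else if (res$resistance <= cfg$tol) {
        if (sup$resistance <= cfg$tol) 1 else NA_real_
      } else min(1, max(0, sup$resistance / res$resistance))
    data.frame(condition = cn, resistance = res$resistance,
               resistance_super = sup$resistance, score = score,
               status = res$status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Original flux potential analysis (FPA)
#'
#' The same LP as eFPA but with the original power-law distance decay
#' `(1 + d)^(-n)` and, by default, the naive distance metric. The
#' `"weighted"` metric gives the "FPA with weighted distance" variant that
#' keeps the power decay but measures distance like eFPA.
#'
#' @inheritParams run_efpa
#' @param order power-decay order `n >= 0`; 0 disables decay
#'   (whole-network integration).
#' @param metric `"naive"` (original FPA) or `"weighted"`.
#' @return an `fp_result` data.frame, as [run_efpa()].
#' @export
original_fpa <- function(net, rel, rois = colnames(net$S), order = 2.5,
                         metric = c("naive", "weighted"),
                         allowance = 1, directions = c("f", "r"),
                         bounds = NULL, dist_mode = "both") {
  cfg <- efpa_config(allowance = allowance,
                     decay = decay_spec("power", order = order),
                     metric = match.arg(metric))
  run_efpa(net, rel, rois, cfg, directions = directions, bounds = bounds,
           dist_mode = dist_mode)
}
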