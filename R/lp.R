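# Internal LP layer.
#
# All programs solved in this package share one shape: nonnegative directed
# fluxes v, steady state S v = 0, upper bounds v <= ub, plus one budget row
# (<=, eFPA) or one optimum-fraction row (>=, Compass). boot::simplex is
# used as the solver; the steady-state equalities are passed as paired
# inequalities (S v <= 0 and -S v <= 0) so that the origin is a feasible
# starting basis, which avoids phase-I degeneracy failures on these highly
# degenerate networks.

solve_flux_lp <- function(objective, S, ub,
                          leq_mat = NULL, leq_rhs = NULL,
                          geq_mat = NULL, geq_rhs = NULL,
                          maximize = TRUE, n_iter = NULL) {
  n <- ncol(S)
  A1 <- rbind(S, -S, diag(n))
  b1 <- c(rep(0, 2 * nrow(S)), unname(ub))
  if (!is.null(leq_mat)) {
    A1 <- rbind(A1, leq_mat)
    b1 <- c(b1, leq_rhs)
  }
  if (is.null(n_iter)) n_iter <- max(200L, 20L * n)
  res <- tryCatch({
    if (is.null(geq_mat)) {
      boot::simplex(a = objective, A1 = A1, b1 = b1, maxi = maximize,
                    n.iter = n_iter)
    } else {
      boot::simplex(a = objective, A1 = A1, b1 = b1,
                    A2 = geq_mat, b2 = geq_rhs, maxi = maximize,
                    n.iter = n_iter)
    }
  }, error = function(e) NULL)
  if (is.null(res)) {
    return(list(value = NA_real_, solution = rep(NA_real_, n),
                status = "error"))
  }
  status <- switch(as.character(res$solved),
                   "1" = "optimal", "0" = "iteration_limit", "infeasible")
  list(value = unname(res$value),
       solution = setNames(as.numeric(res$soln), colnames(S)),
       status = status)
}
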