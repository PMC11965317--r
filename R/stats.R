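#' Row-wise Pearson correlation with BH-FDR
#'
#' Correlates each reaction's predicted profile with its measured profile
#' across conditions (paired columns), computes two-tailed t-based p-values,
#' and adjusts them with Benjamini-Hochberg over the family of reactions
#' actually tested. A reaction is called significant ("predicted") when
#' `q <= 0.05` and `PCC > 0`.
#'
#' @param x,y matrices with matching reaction row names and condition
#'   columns (`y` columns are matched to `x` by name when named).
#' @param alpha FDR threshold for the significance flag.
#' @param min_n minimum number of paired observations per reaction.
#' @return a data.frame per reaction: `reaction`, `pcc`, `p`, `q`, `n`,
#'   `tested`, `significant`. Reactions with fewer than `min_n` pairs or a
#'   constant profile are flagged `tested = FALSE` and excluded from the
#'   FDR family.
#' @export
pearson_fdr <- function(x, y, alpha = 0.05, min_n = 3) {
  x <- as.matrix(x); y <- as.matrix(y)
  common <- intersect(rownames(x), rownames(y))
  if (!length(common)) stop("x and y share no reaction rows")
  if (!is.null(colnames(x)) && !is.null(colnames(y))) {
    conds <- intersect(colnames(x), colnames(y))
    x <- x[, conds, drop = FALSE]; y <- y[, conds, drop = FALSE]
  }
  res <- data.frame(reaction = common, pcc = NA_real_, p = NA_real_,
                    q = NA_real_, n = 0L, tested = FALSE,
                    significant = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(common)) {
    xi <- x[common[i], ]; yi <- y[common[i], ]
    ok <- is.finite(xi) & is.finite(yi)
    res$n[i] <- sum(ok)
    if (sum(ok) < min_n) next
    if (sd(xi[ok]) == 0 || sd(yi[ok]) == 0) next   # constant: PCC undefined
    ct <- cor.test(xi[ok], yi[ok], method = "pearson",
                   alternative = "two.sided")
    res$pcc[i] <- unname(ct$estimate)
    res$p[i] <- ct$p.value
    res$tested[i] <- TRUE
  }
  res$q[res$tested] <- p.adjust(res$p[res$tested], method = "BH")
  res$significant <- res$tested & !is.na(res$q) &
    res$q <= alpha & res$pcc > 0
  res
}

#' Pathway coexpression strength and profile
#'
#' The strength of coexpression of a pathway is the median of the pairwise
#' Pearson correlations among its member reactions' relative expression
#' profiles; the pathway profile is the per-condition median of the member
#' profiles.
#'
#' @param rel a `reaction_expression` (or a plain reaction x condition
#'   matrix).
#' @param members reaction ids of the pathway (`>= 2` with data).
#' @return list with `strength` (median pairwise PCC), `profile`
#'   (per-condition median relative expression), `pairwise` (data.frame of
#'   member pairs and their PCCs) and `n_members` used.
#' @export
pathway_coexpression <- function(rel, members) {
  m <- if (inherits(rel, "reaction_expression")) rel$rel else as.matrix(rel)
  members <- intersect(members, rownames(m))
  sub <- m[members, , drop = FALSE]
  sub <- sub[rowSums(is.finite(sub)) >= 3, , drop = FALSE]
  if (nrow(sub) < 2) {
    return(list(strength = NA_real_, profile = NULL, pairwise = NULL,
                n_members = nrow(sub)))
  }
  pairs <- combn(rownames(sub), 2)
  pcc <- apply(pairs, 2, function(pr) {
    a <- sub[pr[1], ]; b <- sub[pr[2], ]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3 || sd(a[ok]) == 0 || sd(b[ok]) == 0) return(NA_real_)
    cor(a[ok], b[ok])
  })
  list(strength = median(pcc, na.rm = TRUE),
       profile = apply(sub, 2, median, na.rm = TRUE),
       pairwise = data.frame(a = pairs[1, ], b = pairs[2, ], pcc = pcc,
                             stringsAsFactors = FALSE),
       n_members = nrow(sub))
}

#' Pairwise cross-informing rate by bridging-metabolite degree
#'
#' For connected reaction pairs with a correlation result each, the
#' cross-informing rate of a group of pairs is the fraction whose profiles
#' significantly correlate (`q <= 0.05`, `PCC > 0`). Pairs are grouped into
#' equal-count bins of bridging-metabolite degree; each bin reports its
#' mean degree (x) and rate (y).
#'
#' @param pairs data.frame with columns `degree`, `pcc`, `q`.
#' @param n_bins number of equal-count degree bins (default 8).
#' @param alpha FDR threshold.
#' @return data.frame per non-empty bin: `bin`, `n`, `mean_degree`, `rate`.
#' @export
cross_informing_rate <- function(pairs, n_bins = 8, alpha = 0.05) {
  stopifnot(all(c("degree", "pcc", "q") %in% names(pairs)))
  pairs <- pairs[is.finite(pairs$degree), , drop = FALSE]
  if (!nrow(pairs)) return(data.frame())
  ord <- order(pairs$degree)
  pairs <- pairs[ord, , drop = FALSE]
  bin <- ceiling(seq_len(nrow(pairs)) / ceiling(nrow(pairs) / n_bins))
  informed <- !is.na(pairs$q) & pairs$q <= alpha &
    !is.na(pairs$pcc) & pairs$pcc > 0
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    data.frame(bin = b, n = sum(sel),
               mean_degree = mean(pairs$degree[sel]),
               rate = mean(informed[sel]))
  }))
  out
}

#' Shuffle reaction labels of a relative expression matrix
#'
#' Randomizes the association between expression profiles and reaction
#' identities: rows keep their values but are reassigned to a permutation
#' of the reaction labels (data-bearing rows only; missing rows stay
#' missing).
#'
#' @param rel a `reaction_expression`.
#' @return a `reaction_expression` with permuted row labels.
#' @export
permute_reaction_labels <- function(rel) {
  stopifnot(inherits(rel, "reaction_expression"))
  hasdata <- rownames(rel$rel)[rel$status != "missing"]
  perm <- sample(hasdata)
  out <- rel
  map <- setNames(perm, hasdata)
  rn <- rownames(rel$rel)
  rn2 <- ifelse(rn %in% hasdata, map[rn], rn)
  # reorder rows so that row names remain in original order
  m <- rel$rel; rownames(m) <- rn2
  out$rel <- m[rownames(rel$rel), , drop = FALSE]
  # completeness flags travel with the data, not the label
  st <- rel$status
  st[map[hasdata]] <- rel$status[hasdata]
  out$status <- st
  out
}

#' Permutation test over reaction-label shuffles
#'
#' Recomputes a user statistic (e.g. the number of predicted reactions)
#' on label-shuffled expression data and reports the empirical p-value
#' with the +1 pseudo-count, `p = (1 + #\{perm >= obs\}) / (1 + n_perm)`,
#' so p is never exactly 0.
#'
#' @param rel a `reaction_expression`.
#' @param statistic function taking a `reaction_expression`, returning one
#'   number (larger = stronger signal).
#' @param n_perm number of permutations.
#' @param seed RNG seed for reproducibility.
#' @return list with `observed`, `perm` (numeric of length `n_perm`),
#'   `p_value`.
#' @export
permutation_test <- function(rel, statistic, n_perm = 1000, seed = 1) {
  stopifnot(n_perm >= 1)
  observed <- statistic(rel)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    statistic(permute_reaction_labels(rel))
  }, numeric(1))
  list(observed = observed, perm = perm,
       p_value = (1 + sum(perm >= observed)) / (1 + n_perm))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Tissue enrichment scores (delta rFP)
#'
#' Centers each reaction's rFP across groups (tissues) by subtracting the
#' row median; a group is called enriched at `delta >= 0.2` and depleted at
#' `delta <= -0.2`. Undefined rFPs are excluded from the median and stay
#' `NA`.
#'
#' @param rfp reaction x group matrix of rFP values.
#' @param threshold enrichment threshold on `|delta|` (default 0.2).
#' @return list with `delta` (centered matrix), `enriched`, `depleted`
#'   (logical matrices).
#' @export
delta_rfp <- function(rfp, threshold = 0.2) {
  rfp <- as.matrix(rfp)
  med <- apply(rfp, 1, median, na.rm = TRUE)
  delta <- sweep(rfp, 1, med, "-")
  list(delta = delta,
       enriched = !is.na(delta) & delta >= threshold,
       depleted = !is.na(delta) & delta <= -threshold)
}

#' Cell-type enrichment of a reaction score
#'
#' For each cell type, compares the per-cell scores of one reaction against
#' all other cells with a median fold change and a Wilcoxon rank-sum test
#' (tie-corrected normal approximation - single-cell zeros create heavy
#' ties). To keep one metabolically dominant type (e.g. liver) from masking
#' every comparison, the top-ranking type (by median) is excluded from the
#' "others" pool; when the tested type is itself top-ranked, the second
#' highest is excluded instead. Enrichment requires `FC > 1.2` and
#' `p < 1e-10`.
#'
#' @param scores named numeric, one score per cell for a single reaction.
#' @param labels named character (or factor), cell type per cell.
#' @param fc_threshold,p_threshold enrichment thresholds.
#' @return data.frame per cell type: `type`, `n`, `median`, `rank`,
#'   `median_others`, `fc`, `p`, `enriched`.
#' @export
celltype_enrichment <- function(scores, labels, fc_threshold = 1.2,
                                p_threshold = 1e-10) {
  labels <- setNames(as.character(labels), names(labels))
  if (!is.null(names(scores)) && !is.null(names(labels))) {
    labels <- labels[names(scores)]
  }
  types <- unique(labels)
  if (length(types) < 2) stop("need at least 2 cell types")
  med <- vapply(types, function(t) median(scores[labels == t], na.rm = TRUE),
                numeric(1))
  rk <- rank(-med, ties.method = "first")   # 1 = highest median
  top <- types[which.min(rk)]
  second <- types[which(rk == 2)]
  out <- do.call(rbind, lapply(types, function(t) {
    excluded <- if (t == top) second else top
    others <- scores[!(labels %in% c(t, excluded))]
    mine <- scores[labels == t]
    mo <- median(others, na.rm = TRUE)
    fc <- if (is.na(mo) || mo <= 0) NA_real_ else med[[t]] / mo
    p <- tryCatch(
      stats::wilcox.test(mine, others, alternative = "two.sided",
                         exact = FALSE, correct = TRUE)$p.value,
      error = function(e) NA_real_)
    data.frame(type = t, n = length(mine), median = med[[t]],
               rank = rk[[t]], median_others = mo, fc = fc, p = p,
               enriched = !is.na(fc) && !is.na(p) &&
                 fc > fc_threshold && p < p_threshold,
               stringsAsFactors = FALSE)
  }))
  out[order(out$rank), ]
}
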