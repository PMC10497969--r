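#' Match predicted against ground-truth instances
#'
#' Computes the IoU matrix over all overlapping (prediction, ground truth)
#' instance pairs, selects the one-to-one assignment maximising the total
#' IoU (maximum-weight bipartite matching), and keeps pairs with
#' IoU >= `tau` as true positives. Unmatched predictions are false
#' positives, unmatched ground-truth instances false negatives. Background
#' (label 0) is ignored, and pairs with zero overlap are never matched,
#' regardless of `tau`.
#'
#' @param pred,gt [labeled_volume()]s (or integer arrays) on the same grid.
#' @param tau IoU acceptance threshold in `[0, 1)` (default 0.5).
#' @return a `match_result` with `tp`, `fp`, `fn`, `tau` and
#'   `matched_pairs` (data frame: `pred`, `gt`, `iou`).
#' @export
match_instances <- function(pred, gt, tau = 0.5) {
  p <- if (inherits(pred, "labeled_volume")) pred$labels else pred
  g <- if (inherits(gt, "labeled_volume")) gt$labels else gt
  if (!identical(dim(p), dim(g))) stop("shape mismatch between pred and gt")
  if (tau < 0 || tau >= 1) stop("tau must be in [0, 1)")
  pl <- sort(unique(p[p > 0]))
  gl <- sort(unique(g[g > 0]))
  pairs <- data.frame(pred = integer(), gt = integer(), iou = numeric())
  if (length(pl) && length(gl)) {
    sel <- p > 0 & g > 0
    if (any(sel)) {
      ov <- table(factor(p[sel], levels = pl), factor(g[sel], levels = gl))
      psz <- tabulate(p[p > 0], nbins = max(pl))[pl]
      gsz <- tabulate(g[g > 0], nbins = max(gl))[gl]
      nz <- which(ov > 0, arr.ind = TRUE)
      if (nrow(nz)) {
        inter <- ov[nz]
        uni <- psz[nz[, 1]] + gsz[nz[, 2]] - inter
        iou <- as.numeric(inter) / uni
        # maximum-weight one-to-one assignment over overlapping pairs
        np <- length(pl); ng <- length(gl)
        edges <- as.vector(t(cbind(nz[, 1], np + nz[, 2])))
        gr <- igraph::make_bipartite_graph(c(rep(FALSE, np), rep(TRUE, ng)),
                                           edges)
        igraph::E(gr)$weight <- iou
        mm <- igraph::max_bipartite_match(gr)$matching
        keep <- integer(0)
        for (e in seq_along(iou)) {
          i <- nz[e, 1]; j <- nz[e, 2]
          if (!is.na(mm[i]) && mm[i] == np + j && iou[e] >= tau)
            keep <- c(keep, e)
        }
        if (length(keep))
          pairs <- data.frame(pred = pl[nz[keep, 1]], gt = gl[nz[keep, 2]],
                              iou = iou[keep])
      }
    }
  }
  structure(list(tp = nrow(pairs), fp = length(pl) - nrow(pairs),
                 fn = length(gl) - nrow(pairs), tau = tau,
                 matched_pairs = pairs),
            class = "match_result")
}

#' Instance-matching accuracy
#'
#' `accuracy = TP / (TP + FN + FP)` at the match result's IoU threshold.
#' When both images are empty (no instances at all) the accuracy is defined
#' as 1.
#'
#' @param m a `match_result`.
#' @return accuracy in `[0, 1]`.
#' @export
accuracy <- function(m) {
  denom <- m$tp + m$fp + m$fn
  if (denom == 0) return(1.0)
  m$tp / denom
}

#' Precision, recall and F1 of a match result
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)` (0 when the
#' denominator vanishes).
#'
#' @param m a `match_result`.
#' @return named list with `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(m) {
  prec <- if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else 0
  rec <- if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(precision = prec, recall = rec, f1 = f1)
}
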