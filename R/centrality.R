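# Directed-network centrality: in/out expected influence (signed sums of
# incoming/outgoing cross-lagged edges; autoregressive self-loops excluded,
# reported separately).

#' Out-expected-influence of each node
#'
#' \code{OEI_i = sum_{j != i} weights[i, j]}: the signed sum of node i's
#' outgoing cross-lagged edges — how strongly a symptom at wave 1 predicts
#' the other symptoms at wave 2. Autoregressive (diagonal) terms are
#' excluded.
#'
#' @param net a \code{clpn} or square weight matrix.
#' @return Named numeric vector of length p.
#' @export
out_expected_influence <- function(net) {
  w <- .clpn_weights(net)
  rowSums(w) - diag(w)
}

#' In-expected-influence of each node
#'
#' \code{IEI_j = sum_{i != j} weights[i, j]}: the signed sum of node j's
#' incoming cross-lagged edges — how strongly a symptom at wave 2 is
#' predicted by the other symptoms at wave 1.
#'
#' @inheritParams out_expected_influence
#' @return Named numeric vector of length p.
#' @export
in_expected_influence <- function(net) {
  w <- .clpn_weights(net)
  colSums(w) - diag(w)
}

#' Centrality table for a directed cross-lagged network
#'
#' @inheritParams out_expected_influence
#' @return Data frame (class \code{clpn_centrality}) with item labels,
#'   OEI, IEI and the autoregressive coefficient of each node. The OEI and
#'   IEI columns sum to the same value (both sum all off-diagonal weights).
#' @export
centrality_table <- function(net) {
  w <- .clpn_weights(net)
  labs <- rownames(w)
  if (is.null(labs)) labs <- paste0("item", seq_len(nrow(w)))
  out <- data.frame(item = labs,
                    out_expected_influence = unname(out_expected_influence(w)),
                    in_expected_influence = unname(in_expected_influence(w)),
                    autoregressive = unname(diag(w)))
  class(out) <- c("clpn_centrality", class(out))
  out
}

#' Top-k nodes by each centrality index
#'
#' Ranks nodes by OEI and by IEI; ties are broken by item order, so the
#' listing is stable across runs.
#'
#' @param tab a \code{clpn_centrality} table (or a \code{clpn}, from which
#'   one is computed).
#' @param k how many nodes to report per index (k <= p).
#' @return List with data frames \code{oei} and \code{iei}, each with
#'   columns rank, item, value.
#' @export
rank_report <- function(tab, k = 5L) {
  if (inherits(tab, "clpn") || is.matrix(tab)) tab <- centrality_table(tab)
  p <- nrow(tab)
  if (k > p) stopf("k = %d exceeds the number of nodes (%d)", k, p)
  top <- function(x) {
    ord <- order(-x, seq_along(x))[seq_len(k)]
    data.frame(rank = seq_len(k), item = tab$item[ord], value = x[ord])
  }
  list(oei = top(tab$out_expected_influence),
       iei = top(tab$in_expected_influence))
}
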