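#' Plug-in mutual information between two discrete variables
#'
#' Estimates I(A; B) from the joint empirical distribution of two equal-length
#' discretized observation vectors. Continuous outputs should be discretized
#' first (see [discretize_quantile()]). The plug-in estimate is nonnegative
#' and symmetric in its arguments.
#'
#' @param a,b vectors (factor, character, or integer codes) of equal length.
#' @param unit `"bits"` (log base 2, default) or `"nats"` (natural log).
#' @return Mutual information in the requested unit.
#' @export
mutual_information <- function(a, b, unit = c("bits", "nats")) {
  unit <- match.arg(unit)
  if (length(a) != length(b)) stop("a and b must have equal length")
  joint <- table(a, b) / length(a)
  pa <- rowSums(joint)
  pb <- colSums(joint)
  expected <- outer(pa, pb)
  pos <- joint > 0
  mi <- sum(joint[pos] * log(joint[pos] / expected[pos]))
  mi <- max(mi, 0)
  if (unit == "bits") mi / log(2) else mi
}

#' Quantile-based discretization of a continuous variable
#'
#' Bins a continuous vector at its empirical quantiles (duplicate quantiles
#' collapsed), so any strictly monotone transform of the input yields the same
#' binning — making downstream mutual-information scores invariant under such
#' transforms.
#'
#' @param x numeric vector.
#' @param bins target number of bins (default 16).
#' @return Integer vector of bin codes.
#' @export
discretize_quantile <- function(x, bins = 16L) {
  brk <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                                names = FALSE, type = 7))
  if (length(brk) < 2L) return(rep.int(1L, length(x)))  # constant input
  as.integer(cut(x, breaks = brk, include.lowest = TRUE))
}

#' MRMR importance scores for system outputs
#'
#' Ranks outputs by minimum-redundancy maximum-relevance and assigns each a
#' recursive importance score. Relevance is the mutual information between an
#' output and the hypothesis label; redundancy is the mean mutual information
#' with the already-selected outputs; their ratio is the mutual information
#' quotient (MIQ). The top rank goes to the output with the highest relevance
#' and receives its relevance as its importance score; each later rank goes to
#' the remaining output with the highest MIQ and is scored as the previous
#' score multiplied by the ratio of its MIQ to the previous MIQ.
#'
#' For the top-ranked output the redundancy set is empty; its MIQ denominator
#' is taken as the mean mutual information against the remaining outputs (an
#' implementation convention giving finite scores, mirroring common MRMR
#' implementations).
#'
#' @param table a [cell_table()] (or data frame containing the output columns).
#' @param hypothesis_labels per-cell label (two levels: e.g. `"H0"`/`"H1"`).
#' @param outputs character vector (>= 2) of output column names.
#' @param bins quantile bins per continuous output (default 16).
#' @param unit `"bits"` (default) or `"nats"`.
#' @return An `importance_report`: a data frame with one row per output in
#'   rank order and columns `output`, `rank`, `relevance`, `redundancy`,
#'   `miq`, `score`, plus attribute `unit`.
#' @export
mrmr_importance <- function(table, hypothesis_labels, outputs,
                            bins = 16L, unit = c("bits", "nats")) {
  unit <- match.arg(unit)
  if (length(outputs) < 2L) stop("at least 2 outputs are required")
  df <- as.data.frame(table)
  missing_out <- setdiff(outputs, names(df))
  if (length(missing_out)) stop("unknown output(s): ", paste(missing_out, collapse = ", "))
  labels <- as.factor(hypothesis_labels)
  if (nlevels(labels) != 2L) stop("hypothesis_labels must have exactly 2 levels")
  if (length(labels) != nrow(df)) stop("hypothesis_labels length must match the table")

  disc <- lapply(df[outputs], discretize_quantile, bins = bins)
  relevance <- vapply(disc, mutual_information, numeric(1), b = labels, unit = unit)

  # pairwise MI among outputs (needed for redundancy terms)
  k <- length(outputs)
  pair_mi <- matrix(0, k, k, dimnames = list(outputs, outputs))
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      pair_mi[i, j] <- pair_mi[j, i] <-
        mutual_information(disc[[i]], disc[[j]], unit = unit)
    }
  }

  selected <- character(0)
  rows <- vector("list", k)
  remaining <- outputs
  for (r in seq_len(k)) {
    if (r == 1L) {
      best <- remaining[which.max(relevance[remaining])]
      if (sum(relevance[remaining] == relevance[best]) > 1L) {
        warning("relevance tie at rank 1; broken by input order")
      }
      red <- mean(pair_mi[best, setdiff(outputs, best)])  # finite-MIQ floor
      miq <- relevance[best] / red
      score <- relevance[best]
    } else {
      reds <- vapply(remaining, function(o) mean(pair_mi[o, selected]), numeric(1))
      # 0/0 (an output carrying no information at all) counts as MIQ 0
      miqs <- ifelse(reds == 0 & relevance[remaining] == 0, 0,
                     relevance[remaining] / reds)
      best <- remaining[which.max(miqs)]
      if (sum(miqs == max(miqs)) > 1L) {
        warning("MIQ tie at rank ", r, "; broken by input order")
      }
      red <- reds[best]
      miq <- miqs[best]
      prev <- rows[[r - 1L]]
      # score_k = score_{k-1} * MIQ_k / MIQ_{k-1}, computed as a ratio of
      # products so a shared zero redundancy cancels instead of giving Inf/Inf
      score <- if (is.finite(miq) && is.finite(prev$miq)) {
        prev$score * miq / prev$miq
      } else {
        prev$score * (relevance[best] * prev$redundancy) /
          (prev$relevance * red)
      }
      if (!is.finite(score)) score <- 0
    }
    rows[[r]] <- data.frame(output = best, rank = r,
                            relevance = unname(relevance[best]),
                            redundancy = unname(red), miq = unname(miq),
                            score = unname(score), stringsAsFactors = FALSE)
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  out <- do.call(rbind, rows)
  structure(out, unit = unit, class = c("importance_report", class(out)))
}

#' @export
print.importance_report <- function(x, ...) {
  cat(sprintf("<importance_report> MI unit: %s\n", attr(x, "unit")))
  NextMethod()
}
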