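#' Best-match accuracy between predicted and true group labels
#'
#' Builds the confusion matrix of predicted vs true groups and finds the
#' one-to-one assignment of predicted to true groups that maximizes the number
#' of agreeing items (exhaustive search over assignments, exact for the small
#' group counts used here), returning the matched accuracy. Used to compare
#' recovered temporal pattern groups against simulator ground truth without
#' depending on arbitrary group names.
#'
#' @param predicted,truth vectors of group labels over the same items.
#' @return list with `accuracy`, `assignment` (predicted -> truth) and the
#'   confusion `table`.
#' @export
match_group_accuracy <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  tab <- table(predicted = as.character(predicted), truth = as.character(truth))
  np <- nrow(tab)
  nt <- ncol(tab)
  if (np > 8L) stop("exhaustive matching supports at most 8 predicted groups")
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    unlist(lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
  }
  cols <- seq_len(nt)
  best <- -1
  best_assign <- NULL
  if (np <= nt) {
    for (p in perms(cols)) {
      sel <- p[seq_len(np)]
      sc <- sum(tab[cbind(seq_len(np), sel)])
      if (sc > best) {
        best <- sc
        best_assign <- stats::setNames(colnames(tab)[sel], rownames(tab))
      }
    }
  } else {
    for (p in perms(seq_len(np))) {
      sel <- p[seq_len(nt)]
      sc <- sum(tab[cbind(sel, seq_len(nt))])
      if (sc > best) {
        best <- sc
        assign <- stats::setNames(rep(NA_character_, np), rownames(tab))
        assign[sel] <- colnames(tab)
        best_assign <- assign
      }
    }
  }
  list(accuracy = best / length(predicted), assignment = best_assign,
       table = tab)
}
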