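#' Threshold classification of membership matrices
#'
#' Assigns each individual to the class with maximal membership iff that
#' membership strictly exceeds the threshold, else `UNASSIGNED`.
#'
#' @param q membership matrix (individuals x classes, rows sum to 1).
#' @param threshold assignment threshold (conventionally 0.5, 0.75 or
#'   0.9). A threshold at or below `1/ncol(q)` makes every individual
#'   assignable and triggers a warning.
#' @return character vector of class labels or `"UNASSIGNED"`.
#' @export
classify <- function(q, threshold = 0.5) {
  if (is.null(colnames(q))) stop("membership matrix needs class column names")
  if (threshold < 1 / ncol(q))
    warning("threshold < 1/", ncol(q), ": every individual is assignable")
  top <- max.col(q, ties.method = "first")
  val <- q[cbind(seq_len(nrow(q)), top)]
  out <- colnames(q)[top]
  out[val <= threshold] <- "UNASSIGNED"
  out
}

#' Error rates of hybrid classification against simulation truth
#'
#' Computes, for individuals with known simulated class: the assigned
#' fraction, the false-positive rate (truly pure individuals assigned to
#' any hybrid class), the false-negative rate (true hybrids assigned to
#' a parental class), and the detection rate (true hybrids assigned to
#' any hybrid class, regardless of the exact class), plus the confusion
#' matrix. For hybrids, detection + false-negative + unassigned = 1.
#'
#' @param classified character vector from [classify()].
#' @param truth character vector of true class labels, same length.
#' @param parental labels counted as pure classes (default P1/P2).
#' @return a `power_report` list: `rates` (named numeric vector),
#'   `confusion` (truth x assigned table), `n_pure`, `n_hybrid`.
#' @export
eval_rates <- function(classified, truth, parental = c("P1", "P2")) {
  if (length(classified) != length(truth))
    stop("classified and truth lengths differ")
  is_pure <- truth %in% parental
  is_hyb <- !is_pure
  asg <- classified != "UNASSIGNED"
  to_par <- classified %in% parental
  to_hyb <- asg & !to_par
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  rates <- c(
    assigned = mean(asg),
    false_positive = rate(sum(is_pure & to_hyb), sum(is_pure)),
    false_negative = rate(sum(is_hyb & to_par), sum(is_hyb)),
    detection = rate(sum(is_hyb & to_hyb), sum(is_hyb)),
    unassigned_hybrids = rate(sum(is_hyb & !asg), sum(is_hyb)),
    pure_correct = rate(sum(is_pure & to_par & classified == truth), sum(is_pure)))
  conf <- table(truth = truth,
                assigned = factor(classified,
                                  levels = c(sort(unique(c(truth, classified[asg]))),
                                             "UNASSIGNED")))
  structure(list(rates = rates, confusion = conf,
                 n_pure = sum(is_pure), n_hybrid = sum(is_hyb)),
            class = "power_report")
}

#' @export
print.power_report <- function(x, ...) {
  cat(sprintf("power report (%d pure, %d hybrid):\n", x$n_pure, x$n_hybrid))
  print(round(x$rates, 3))
  invisible(x)
}

#' Power summary over thresholds for one or more membership matrices
#'
#' @param qs a membership matrix or a list of them (e.g. replicate runs).
#' @param truth true class labels for the rows evaluated.
#' @param rows optional row indices/names restricting evaluation to the
#'   mixture individuals.
#' @param thresholds assignment thresholds.
#' @param parental pure class labels.
#' @return data.frame: replicate, threshold, and the [eval_rates()] rates.
#' @export
power_table <- function(qs, truth, rows = NULL,
                        thresholds = c(0.5, 0.75, 0.9),
                        parental = c("P1", "P2")) {
  if (is.matrix(qs)) qs <- list(qs)
  out <- list()
  for (r in seq_along(qs)) {
    q <- qs[[r]]
    if (!is.null(rows)) q <- q[rows, , drop = FALSE]
    for (th in thresholds) {
      cl <- suppressWarnings(classify(q, th))
      er <- eval_rates(cl, truth, parental)
      out[[length(out) + 1L]] <- data.frame(replicate = r, threshold = th,
                                            t(er$rates))
    }
  }
  do.call(rbind, out)
}
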