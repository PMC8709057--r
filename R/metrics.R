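# Confusion-matrix metric suite. P300 is always the positive class.

#' Classification metrics report from confusion counts
#'
#' Builds the accuracy / precision / recall / F1 report from the four
#' confusion-matrix counts:
#' \deqn{A = (TP + TN) / (TP + TN + FP + FN)}
#' \deqn{PPV = TP / (TP + FP)}
#' \deqn{TPR = TP / (TP + FN)}
#' \deqn{F1 = 2 \cdot PPV \cdot TPR / (PPV + TPR)}
#' A metric whose denominator is zero is reported as `NA` and its name
#' recorded in the `undefined` field -- never silently coerced to 0, which
#' would corrupt downstream impact differences.
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return object of class `metrics_report`.
#' @examples
#' metrics_report(tp = 50, tn = 100, fp = 10, fn = 20)
#' @export
metrics_report <- function(tp, tn, fp, fn) {
  for (nm in c("tp", "tn", "fp", "fn"))
    check_number(get(nm), nm, lower = 0, integer = TRUE)
  total <- tp + tn + fp + fn
  undefined <- character(0)
  div <- function(num, den, name) {
    if (den == 0) {
      undefined <<- c(undefined, name)
      return(NA_real_)
    }
    num / den
  }
  A <- div(tp + tn, total, "A")
  PPV <- div(tp, tp + fp, "PPV")
  TPR <- div(tp, tp + fn, "TPR")
  F1 <- if (is.na(PPV) || is.na(TPR)) {
    undefined <- c(undefined, "F1")
    NA_real_
  } else div(2 * PPV * TPR, PPV + TPR, "F1")
  structure(
    list(TP = tp, TN = tn, FP = fp, FN = fn, total = total,
         A = A, PPV = PPV, TPR = TPR, F1 = F1, undefined = undefined),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d  TP=%d TN=%d FP=%d FN=%d\n",
              x$total, x$TP, x$TN, x$FP, x$FN))
  cat(sprintf("  A=%.4f  PPV=%.4f  TPR=%.4f  F1=%.4f\n",
              x$A, x$PPV, x$TPR, x$F1))
  if (length(x$undefined))
    cat("  undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(TP = x$TP, TN = x$TN, FP = x$FP, FN = x$FN,
             A = x$A, PPV = x$PPV, TPR = x$TPR, F1 = x$F1)
}

# report from parallel label vectors ("P300" positive)
metrics_from_predictions <- function(predicted, truth) {
  pos <- predicted == "P300"
  tru <- truth == "P300"
  metrics_report(tp = sum(pos & tru), tn = sum(!pos & !tru),
                 fp = sum(pos & !tru), fn = sum(!pos & tru))
}

#' Cyberattack impact between two metric reports
#'
#' The attack-impact parameter is the plain difference
#' \eqn{\Delta = V_{real} - V_{fake}} for each metric, computed between an
#' evaluation on clean data and the same model's evaluation on attacked
#' data. Positive values mean the attack degraded the metric. Differences
#' involving an undefined metric are `NA`.
#'
#' @param real_report,fake_report two [metrics_report] objects produced by
#'   the same model under the same configuration.
#' @return object of class `impact_report`: named deltas for A, PPV, TPR, F1.
#' @export
cyberattack_impact <- function(real_report, fake_report) {
  stopifnot(inherits(real_report, "metrics_report"),
            inherits(fake_report, "metrics_report"))
  delta <- sapply(c("A", "PPV", "TPR", "F1"),
                  function(m) real_report[[m]] - fake_report[[m]])
  structure(list(delta = delta,
                 undefined = union(real_report$undefined,
                                   fake_report$undefined)),
            class = "impact_report")
}

#' @export
print.impact_report <- function(x, ...) {
  cat("<impact_report> delta (real - fake):\n")
  print(round(x$delta, 4))
  invisible(x)
}
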