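#' Carpenter-Coustan judgement of a 100-g OGTT panel
#'
#' GDM-positive when at least two of the four plasma glucose thresholds
#' are met (inclusive, "at least"): fasting >= 95, 1-h >= 180,
#' 2-h >= 155, 3-h >= 140 mg/dL. All inputs are mg/dL; no unit
#' conversion is performed. Vectorized over panels.
#'
#' @param fasting,h1,h2,h3 Plasma glucose at fasting, 1, 2 and 3 hours
#'   (mg/dL, all > 0).
#' @return Logical: `TRUE` for GDM-positive.
#' @export
carpenter_coustan <- function(fasting, h1, h2, h3) {
  vals <- cbind(fasting, h1, h2, h3)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all OGTT glucose values must be finite and > 0 mg/dL",
         call. = FALSE)
  met <- (vals[, 1] >= 95) + (vals[, 2] >= 180) +
    (vals[, 3] >= 155) + (vals[, 4] >= 140)
  as.vector(met >= 2)
}

#' Two-step GDM diagnosis (50-g GLT then 100-g OGTT)
#'
#' Step 1 measures 1-h plasma glucose after a 50-g glucose load; values
#' of 140 mg/dL or more (inclusive) trigger the diagnostic 100-g OGTT,
#' which is judged by [carpenter_coustan()]. Subjects below the trigger
#' are non-GDM without an OGTT. Vectorized; OGTT values may be `NA` for
#' subjects below the trigger, but a triggered subject with a missing
#' panel is an error.
#'
#' @param glt_1h 1-h plasma glucose after the 50-g load (mg/dL).
#' @param fasting,h1,h2,h3 OGTT panel (mg/dL), required where
#'   `glt_1h >= 140`.
#' @return Integer diagnosis: 1 = non-GDM, 2 = GDM.
#' @export
two_step_diagnose <- function(glt_1h, fasting = NA, h1 = NA, h2 = NA, h3 = NA) {
  if (any(!is.finite(glt_1h)) || any(glt_1h <= 0))
    stop("GLT values must be finite and > 0 mg/dL", call. = FALSE)
  n <- length(glt_1h)
  panel <- cbind(rep_len(fasting, n), rep_len(h1, n),
                 rep_len(h2, n), rep_len(h3, n))
  triggered <- glt_1h >= 140
  if (any(triggered & apply(panel, 1, function(r) any(is.na(r)))))
    stop("OGTT panel required for subjects with GLT >= 140 mg/dL",
         call. = FALSE)
  out <- rep(1L, n)
  if (any(triggered))
    out[triggered] <- ifelse(
      carpenter_coustan(panel[triggered, 1], panel[triggered, 2],
                        panel[triggered, 3], panel[triggered, 4]),
      2L, 1L)
  out
}
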