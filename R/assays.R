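# Closed-form phenotype and expression assay calculators: relative
# electrolyte conductivity (REC), malondialdehyde (MDA) content, and the
# 2^-ddCt relative-expression method. Vectorized so a TSV of replicate
# measurements can be processed in one call; replicate summaries are mean
# +/- sd computed on the transformed quantities.

#' Relative electrolyte conductivity (REC)
#'
#' `REC = R1 / R2 * 100` (percent), where R1 is the conductivity of the
#' leaf-tissue infusion before boiling and R2 after boiling. A
#' membrane-damage proxy for cold injury; R1 <= R2 in a valid measurement,
#' giving values in \[0, 100\].
#'
#' @param r1 Conductivity before boiling (instrument units, >= 0).
#' @param r2 Conductivity after boiling (same units, > 0).
#' @return REC in percent.
#' @examples
#' rec_percent(5, 20)  # 25
#' @export
rec_percent <- function(r1, r2) {
  if (any(r2 <= 0)) stop("R2 must be positive")
  if (any(r1 < 0)) stop("R1 must be non-negative")
  r1 / r2 * 100
}

#' Malondialdehyde (MDA) content
#'
#' `MDA = 25.58 * ((A532 - A600) + 0.0076) / W` in nmol per g fresh
#' weight, from the absorbance differential at 532 and 600 nm and the
#' sample fresh weight.
#'
#' @param a532,a600 Absorbances at 532 and 600 nm.
#' @param w Fresh weight in g (> 0).
#' @return MDA content in nmol/g fresh weight.
#' @examples
#' mda_content(0.5, 0.1, 0.3)
#' @export
mda_content <- function(a532, a600, w) {
  if (any(w <= 0)) stop("fresh weight must be positive")
  25.58 * ((a532 - a600) + 0.0076) / w
}

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_target,treat - Ct_ref,treat) - (Ct_target,ctrl -
#' Ct_ref,ctrl)`; the fold change of the target gene in the treatment
#' relative to control, normalized to the reference gene, is `2^-ddCt`.
#'
#' @param ct_target_treat,ct_ref_treat Target and reference Ct in the
#'   treatment condition.
#' @param ct_target_ctrl,ct_ref_ctrl Target and reference Ct in the
#'   control condition.
#' @return Fold change (1 = no change).
#' @examples
#' relative_expression(24, 20, 26, 20)  # ddCt = -2 -> 4
#' @export
relative_expression <- function(ct_target_treat, ct_ref_treat,
                                ct_target_ctrl, ct_ref_ctrl) {
  ddct <- (ct_target_treat - ct_ref_treat) -
    (ct_target_ctrl - ct_ref_ctrl)
  if (any(!is.finite(ddct))) stop("all Ct values must be finite")
  2^(-ddct)
}

#' Mean and sd over biological replicates
#'
#' @param x Numeric vector of per-replicate values (already transformed,
#'   e.g. REC percentages or fold changes).
#' @return Named vector `mean`, `sd`, `n`.
#' @export
replicate_summary <- function(x) {
  c(mean = mean(x), sd = stats::sd(x), n = length(x))
}
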