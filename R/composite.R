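# Composite summed drug index and tail-quadrant classification.

#' Z-standardise a vector
#'
#' Subtracts the mean and divides by the population (n-denominator)
#' standard deviation, so the output has mean 0 and SD 1 exactly. The n vs
#' n-1 choice is immaterial at library scale but is fixed for
#' reproducibility.
#'
#' @param values numeric vector (length >= 2).
#' @param component name used in error messages.
#' @return standardised vector.
#' @export
zstandardize <- function(values, component = "component") {
  if (length(values) < 2) stop("need >= 2 values to standardise ", component)
  if (anyNA(values)) stop("missing values in ", component)
  s <- sqrt(mean((values - mean(values))^2))
  if (s == 0) stop("zero standard deviation in ", component)
  (values - mean(values)) / s
}

#' Summed drug index from the five component scores
#'
#' Each component is z-standardised over the scored compound set; the Ro5
#' count enters raw and its z-score is negated (so positive values mean
#' fewer Lipinski exceedances). The summed index is the sum of the five
#' z-scores and has dataset mean 0 by construction.
#'
#' @param jaccard,tanimoto,rdl,admet,ro5 aligned numeric vectors: mean
#'   Jaccard drug similarity, mean combined Tanimoto index, RDL,
#'   ADMET-score, and raw rule-of-five violation counts.
#' @return data frame: `z_jaccard`, `z_tanimoto`, `z_rdl`, `z_admet`,
#'   `z_negro5`, `summed`.
#' @export
summed_index <- function(jaccard, tanimoto, rdl, admet, ro5) {
  n <- length(jaccard)
  if (any(c(length(tanimoto), length(rdl), length(admet), length(ro5)) != n))
    stop("component vectors differ in length")
  out <- data.frame(
    z_jaccard = zstandardize(jaccard, "jaccard"),
    z_tanimoto = zstandardize(tanimoto, "tanimoto"),
    z_rdl = zstandardize(rdl, "rdl"),
    z_admet = zstandardize(admet, "admet"),
    z_negro5 = -zstandardize(ro5, "ro5"))
  out$summed <- rowSums(out)
  out
}

#' Quadrant thresholds for tail classification
#'
#' The four corner regions of the (summed index, QED) plane. Defaults are
#' the printed cut values from the source analyses; they are tails of that
#' particular library, so percentile-based cuts may suit other libraries
#' better. Corners must be pairwise disjoint rectangles; overlap is an
#' error at construction.
#'
#' @param consistent_druglike high summed and high QED: `c(summed_gt, qed_gt)`.
#' @param druglike_low_qed high summed, QED rounding to 0: `summed_gt`.
#' @param least_druglike low summed, QED rounding to 0: `summed_lt`.
#' @param qed_only low summed, high QED: `c(summed_lt, qed_gt)`.
#' @return Object of class `quadrant_thresholds`.
#' @export
quadrant_thresholds <- function(consistent_druglike = c(summed_gt = 2.42, qed_gt = 0.55),
                                druglike_low_qed = c(summed_gt = 2.06),
                                least_druglike = c(summed_lt = -12.94),
                                qed_only = c(summed_lt = -2.6, qed_gt = 0.53)) {
  # each corner as a rectangle [s_lo, s_hi] x [q_lo, q_hi]; "QED = 0" means
  # QED rounds to 0.00 at 2 decimals, i.e. q in [0, 0.005)
  rect <- function(s_lo, s_hi, q_lo, q_hi) c(s_lo = s_lo, s_hi = s_hi,
                                             q_lo = q_lo, q_hi = q_hi)
  corners <- list(
    consistent_druglike = rect(consistent_druglike[["summed_gt"]], Inf,
                               consistent_druglike[["qed_gt"]], 1),
    druglike_low_qed = rect(druglike_low_qed[["summed_gt"]], Inf, 0, 0.005),
    least_druglike = rect(-Inf, least_druglike[["summed_lt"]], 0, 0.005),
    qed_only = rect(-Inf, qed_only[["summed_lt"]],
                    qed_only[["qed_gt"]], 1))
  nm <- names(corners)
  for (a in seq_along(corners)) for (b in seq_len(a - 1L)) {
    ra <- corners[[a]]; rb <- corners[[b]]
    overlap <- ra["s_lo"] < rb["s_hi"] && rb["s_lo"] < ra["s_hi"] &&
      ra["q_lo"] < rb["q_hi"] && rb["q_lo"] < ra["q_hi"]
    if (overlap) stop("overlapping corner definitions: ", nm[a], " and ", nm[b])
  }
  structure(corners, class = "quadrant_thresholds")
}

#' Classify compounds into (summed index, QED) tail quadrants
#'
#' QED is rounded to 2 decimals before the "QED = 0" corner tests (reported
#' QED values of 0 are rounded display values; internal scores stay
#' positive). Corners take precedence over the interior; each compound gets
#' exactly one label.
#'
#' @param summed summed drug index values.
#' @param qed QED values.
#' @param thresholds a [quadrant_thresholds()] object.
#' @return character vector of labels: `consistent_druglike`,
#'   `druglike_low_qed`, `least_druglike`, `qed_only`, or `interior`.
#' @export
classify_quadrants <- function(summed, qed, thresholds = quadrant_thresholds()) {
  stopifnot(inherits(thresholds, "quadrant_thresholds"))
  if (length(summed) != length(qed)) stop("summed and qed differ in length")
  q2 <- round(qed, 2)
  labels <- rep("interior", length(summed))
  for (nm in names(thresholds)) {
    r <- thresholds[[nm]]
    inside <- summed > r["s_lo"] & summed < r["s_hi"] &
      ((r["q_hi"] <= 0.005 & q2 == 0) |
         (r["q_hi"] > 0.005 & qed > r["q_lo"] & qed <= r["q_hi"]))
    labels[inside & labels == "interior"] <- nm
  }
  labels
}

#' Composite scores for a compound set
#'
#' Assembles the five z-standardised components, the summed index, the QED
#' (reported alongside, not summed), and the quadrant label.
#'
#' @param components data frame with columns `id`, `mean_jaccard`,
#'   `tanimoto_index`, `rdl`, `admet` (standardised or raw ADMET-score),
#'   `ro5`, `qed`.
#' @param thresholds a [quadrant_thresholds()].
#' @return data frame: `id`, the five z-components, `summed`, `qed`,
#'   `quadrant`.
#' @export
composite_scores <- function(components, thresholds = quadrant_thresholds()) {
  need <- c("id", "mean_jaccard", "tanimoto_index", "rdl", "admet", "ro5", "qed")
  missing <- setdiff(need, names(components))
  if (length(missing)) stop("components missing columns: ",
                            paste(missing, collapse = ", "))
  z <- summed_index(components$mean_jaccard, components$tanimoto_index,
                    components$rdl, components$admet, components$ro5)
  data.frame(id = components$id, z, qed = components$qed,
             quadrant = classify_quadrants(z$summed, components$qed, thresholds),
             stringsAsFactors = FALSE)
}

#' Merged, ranked report of all per-compound scores
#'
#' Joins the likeness profiles, similarity results and composite scores by
#' id (all ids must be present in every input) and orders by summed index,
#' descending, with ties broken lexicographically by id. The merge is
#' lossless: every input column appears.
#'
#' @param profiles likeness profile data frame (with `id`).
#' @param similarity similarity data frame (with `id`).
#' @param composite composite score data frame (with `id` and `summed`).
#' @return merged, ordered data frame.
#' @export
rank_report <- function(profiles, similarity, composite) {
  for (nm in c("profiles", "similarity", "composite")) {
    x <- get(nm)
    if (!("id" %in% names(x))) stop(nm, " has no id column")
  }
  ids <- composite$id
  for (nm in c("profiles", "similarity")) {
    x <- get(nm)
    missing <- setdiff(ids, x$id)
    if (length(missing))
      stop("ids absent from ", nm, ": ", paste(missing, collapse = ", "))
  }
  out <- merge(merge(composite, profiles, by = "id",
                     suffixes = c("", ".profile")),
               similarity, by = "id", suffixes = c("", ".similarity"))
  out <- out[order(-out$summed, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
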