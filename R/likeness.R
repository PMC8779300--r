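# Drug-likeness indices: QED, RDL, rule-of-five violations, ADMET-score.

#' The eight QED/RDL property names
#'
#' Molecular weight, log P, H-bond donors/acceptors, topological polar
#' surface area, rotatable bonds, aromatic rings, structural alerts.
#' @export
QED_PROPERTIES <- c("MW", "ALOGP", "HBD", "HBA", "PSA", "ROTB", "AROM", "ALERTS")

# Freedman-Diaconis style histogram breaks for a drug reference sample,
# optionally extended to cover a wider range (shared grids for RDL).
fd_breaks <- function(values, range_hint = NULL) {
  rng <- range(values)
  if (!is.null(range_hint)) rng <- range(c(rng, range_hint))
  if (diff(rng) == 0) return(c(rng[1] - 0.5, rng[1] + 0.5))
  iqr <- stats::IQR(values)
  h <- if (iqr > 0) 2 * iqr / length(values)^(1 / 3) else diff(rng) / 30
  n_bins <- max(1L, min(500L, ceiling(diff(rng) / h)))
  seq(rng[1], rng[2], length.out = n_bins + 1L)
}

#' Fit a desirability model for one molecular property
#'
#' Desirability is the smoothed, peak-normalised histogram of the property
#' over reference drugs: values common among drugs score near 1, values in
#' the tails score near the floor. The floor keeps the geometric mean of a
#' QED strictly positive.
#'
#' @param drug_values property values over the reference drug set.
#' @param property property name (one of `r toString(QED_PROPERTIES)` or any
#'   label).
#' @param bins optional explicit break points; default Freedman-Diaconis.
#' @param floor minimum desirability after flooring (default `1e-6`).
#' @param min_n minimum reference sample size (default 30).
#' @param smooth half-width of the moving-average smoother in bins
#'   (default 1, i.e. a 3-bin window; 0 disables smoothing).
#' @return Object of class `desirability_model` with fields `property`,
#'   `breaks`, `d` (one desirability per cell), `floor`.
#' @export
fit_desirability <- function(drug_values, property = "property", bins = NULL,
                             floor = 1e-6, min_n = 30, smooth = 1) {
  drug_values <- drug_values[is.finite(drug_values)]
  if (length(drug_values) < min_n)
    stop("need at least ", min_n, " drug values to fit desirability for ",
         property)
  breaks <- if (is.null(bins)) fd_breaks(drug_values) else sort(bins)
  counts <- cell_counts(drug_values, breaks)
  if (smooth > 0 && length(counts) > 1) counts <- moving_average(counts, smooth)
  d <- counts / max(counts)
  d <- pmax(d, floor)
  structure(list(property = property, breaks = breaks, d = d, floor = floor),
            class = "desirability_model")
}

# histogram cell counts with clamping of boundary values into end cells
cell_counts <- function(values, breaks) {
  idx <- cell_index(values, breaks)
  tabulate(idx, nbins = length(breaks) - 1L)
}

cell_index <- function(values, breaks) {
  idx <- findInterval(values, breaks, rightmost.closed = TRUE)
  pmin(pmax(idx, 1L), length(breaks) - 1L)
}

moving_average <- function(x, half_width) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- max(1L, i - half_width):min(n, i + half_width)
    mean(x[w])
  }, 0)
}

#' Evaluate a desirability model at property values
#'
#' Values outside the fitted grid take the floor (they are, by construction,
#' undesirable tail values).
#'
#' @param model a [fit_desirability()] model.
#' @param x property values.
#' @return desirability in `[floor, 1]` per value.
#' @export
eval_desirability <- function(model, x) {
  stopifnot(inherits(model, "desirability_model"))
  out <- rep(model$floor, length(x))
  inside <- x >= model$breaks[1] & x <= model$breaks[length(model$breaks)]
  out[inside] <- model$d[cell_index(x[inside], model$breaks)]
  out
}

geometric_mean <- function(x) exp(mean(log(x)))

#' Quantitative estimate of drug-likeness (QED)
#'
#' The unweighted geometric mean of the per-property desirability scores of
#' a molecule: `(prod d_i)^(1/k)` over the `k` fitted property models
#' (canonically the eight of [eight_properties()]).
#'
#' @param pv named numeric vector (or one-row data frame) of property
#'   values.
#' @param models named list of [fit_desirability()] models, one per property
#'   in `pv` that should enter the score.
#' @return QED in `(0, 1]`.
#' @export
qed <- function(pv, models) {
  pv <- unlist(pv[names(models)])
  missing <- names(models)[!vapply(models, inherits, TRUE,
                                   what = "desirability_model")]
  if (length(missing) || anyNA(pv))
    stop("missing desirability model or property value for: ",
         paste(unique(c(missing, names(models)[is.na(pv)])), collapse = ", "))
  d <- vapply(names(models),
              function(p) eval_desirability(models[[p]], pv[[p]]), 0)
  geometric_mean(d)
}

#' Fit QED desirability models for a property table
#'
#' @param drug_properties data frame of drug property values (columns =
#'   properties).
#' @param properties which columns to model (default the eight QED
#'   properties).
#' @param ... passed to [fit_desirability()].
#' @return named list of desirability models.
#' @export
fit_qed_models <- function(drug_properties, properties = QED_PROPERTIES, ...) {
  stats::setNames(lapply(properties, function(p) {
    fit_desirability(drug_properties[[p]], property = p, ...)
  }), properties)
}

#' Score a property table with QED
#' @param properties data frame with the modelled property columns.
#' @param models from [fit_qed_models()].
#' @return numeric vector of QED scores.
#' @export
qed_scores <- function(properties, models) {
  d <- vapply(names(models), function(p) {
    eval_desirability(models[[p]], properties[[p]])
  }, numeric(nrow(properties)))
  if (nrow(properties) == 1L) d <- matrix(d, nrow = 1L)
  exp(rowMeans(log(d)))
}

#' Fit a relative-drug-likelihood model for one property
#'
#' Histogram density estimates for the drug and reference (here: toxin)
#' samples on a shared grid, each normalised to total mass 1 with a
#' pseudocount so the relative likelihood `f_drug / (f_drug + f_ref)` is
#' bounded away from 0 and 1.
#'
#' @param drug_values,reference_values property samples.
#' @param property property name.
#' @param bins optional explicit shared break points.
#' @param eps pseudocount added to each cell mass (default `1e-9`).
#' @param min_n minimum size of each sample (default 30).
#' @return Object of class `rdl_model` with `breaks`, `f_drug`, `f_ref`.
#' @export
fit_rdl_model <- function(drug_values, reference_values,
                          property = "property", bins = NULL,
                          eps = 1e-9, min_n = 30) {
  drug_values <- drug_values[is.finite(drug_values)]
  reference_values <- reference_values[is.finite(reference_values)]
  if (length(drug_values) < min_n || length(reference_values) < min_n)
    stop("need at least ", min_n, " drug and reference values for ", property)
  breaks <- if (is.null(bins)) {
    fd_breaks(drug_values, range_hint = range(reference_values))
  } else sort(bins)
  mass <- function(v) {
    m <- cell_counts(v, breaks) / length(v) + eps
    m / sum(m)
  }
  structure(list(property = property, breaks = breaks,
                 f_drug = mass(drug_values), f_ref = mass(reference_values),
                 eps = eps),
            class = "rdl_model")
}

# Relative likelihood f_drug/(f_drug+f_ref) at x; outside-grid values are
# evaluated at the nearest boundary cell.
relative_likelihood <- function(model, x) {
  stopifnot(inherits(model, "rdl_model"))
  idx <- cell_index(x, model$breaks)
  model$f_drug[idx] / (model$f_drug[idx] + model$f_ref[idx])
}

#' Relative drug likelihood (RDL)
#'
#' Geometric mean over properties of the relative likelihood that the
#' molecule is a drug rather than a reference compound; values closer to 1
#' indicate greater drug similarity.
#'
#' @param pv named numeric vector (or one-row data frame) of property values.
#' @param models named list of [fit_rdl_model()] models.
#' @return RDL in `(0, 1)`.
#' @export
rdl <- function(pv, models) {
  pv <- unlist(pv[names(models)])
  if (anyNA(pv))
    stop("missing property value for: ",
         paste(names(models)[is.na(pv)], collapse = ", "))
  rl <- vapply(names(models),
               function(p) relative_likelihood(models[[p]], pv[[p]]), 0)
  geometric_mean(rl)
}

#' Fit RDL models for all properties of a property table
#' @param drug_properties,reference_properties data frames of property values.
#' @param properties columns to model.
#' @param ... passed to [fit_rdl_model()].
#' @return named list of `rdl_model`s.
#' @export
fit_rdl_models <- function(drug_properties, reference_properties,
                           properties = QED_PROPERTIES, ...) {
  stats::setNames(lapply(properties, function(p) {
    fit_rdl_model(drug_properties[[p]], reference_properties[[p]],
                  property = p, ...)
  }), properties)
}

#' Score a property table with RDL
#' @param properties data frame with the modelled property columns.
#' @param models from [fit_rdl_models()].
#' @return numeric vector of RDL scores.
#' @export
rdl_scores <- function(properties, models) {
  rl <- vapply(names(models), function(p) {
    relative_likelihood(models[[p]], properties[[p]])
  }, numeric(nrow(properties)))
  if (nrow(properties) == 1L) rl <- matrix(rl, nrow = 1L)
  exp(rowMeans(log(rl)))
}

#' Lipinski rule-of-five violation count
#'
#' Number of the four oral-drug thresholds a molecule fails: log P < 5,
#' molecular weight < 500 Da, H-bond donors < 5, H-bond acceptors < 10.
#' The thresholds are strict, so boundary values (e.g. MW exactly 500)
#' count as violations. 0 = most drug-like, 4 = least drug-like.
#'
#' @param mw molecular weight (Da).
#' @param logp octanol:water log-partition estimate.
#' @param hbd,hba donor / acceptor counts.
#' @return integer vector of violation counts in `[0, 4]`.
#' @export
ro5_violations <- function(mw, logp, hbd, hba) {
  n <- max(length(mw), length(logp), length(hbd), length(hba))
  mw <- rep_len(mw, n); logp <- rep_len(logp, n)
  hbd <- rep_len(hbd, n); hba <- rep_len(hba, n)
  if (anyNA(mw) || anyNA(logp) || anyNA(hbd) || anyNA(hba))
    stop("ro5_violations: missing property values (no partial scoring)")
  as.integer(!(logp < 5)) + as.integer(!(mw < 500)) +
    as.integer(!(hbd < 5)) + as.integer(!(hba < 10))
}

#' Derive ADMET endpoint weights from a drug reference set
#'
#' Per endpoint `i` the frequency weight `w1_i` is the fraction of reference
#' drugs predicted beneficial on that endpoint. The QSAR-performance weight
#' `w2` and endpoint-importance weight `w3` are taken as supplied (they are
#' properties of the upstream QSAR models, not of the data); when omitted
#' they default to 1 and a message notes it.
#'
#' @param drug_endpoints an [endpoint_table()] for the reference drugs.
#' @param w2,w3 optional named numeric vectors of positive weights per
#'   endpoint (or single values recycled).
#' @return Object of class `admet_weights`: data frame `endpoint`, `w1`,
#'   `w2`, `w3`.
#' @export
derive_admet_weights <- function(drug_endpoints, w2 = NULL, w3 = NULL) {
  stopifnot(inherits(drug_endpoints, "endpoint_table"))
  if (!length(drug_endpoints$ids)) stop("empty drug endpoint table")
  eps <- drug_endpoints$endpoints
  w1 <- colMeans(drug_endpoints$values)
  fill <- function(w, label) {
    if (is.null(w)) {
      message("admet weights: no ", label, " supplied; using 1 for all endpoints")
      return(stats::setNames(rep(1, length(eps)), eps))
    }
    if (is.null(names(w))) w <- stats::setNames(rep_len(w, length(eps)), eps)
    if (!all(eps %in% names(w))) stop("missing ", label, " for some endpoints")
    w <- w[eps]
    if (any(w <= 0)) stop(label, " weights must be positive")
    w
  }
  out <- data.frame(endpoint = eps, w1 = unname(w1),
                    w2 = unname(fill(w2, "w2")), w3 = unname(fill(w3, "w3")),
                    stringsAsFactors = FALSE)
  class(out) <- c("admet_weights", "data.frame")
  out
}

#' ADMET-score: weighted endpoint sum, drug-range standardised
#'
#' Raw score per molecule: `sum_i w1_i * w2_i * w3_i * v_i` over the binary
#' endpoint values `v_i`. Standardised score: `(raw - drug_min) /
#' (drug_max - drug_min)` using the raw-score range of the reference drugs,
#' so drugs span `[0, 1]` while other compound classes may fall outside and
#' are not clipped.
#'
#' @param endpoints an [endpoint_table()] for the compounds to score.
#' @param weights an [derive_admet_weights()] object.
#' @param drug_range length-2 numeric `c(min, max)` of drug raw scores; if
#'   `NULL` only raw scores are returned.
#' @return data frame `id`, `admet_raw`, and `admet_std` when `drug_range`
#'   is given.
#' @export
admet_score <- function(endpoints, weights, drug_range = NULL) {
  stopifnot(inherits(endpoints, "endpoint_table"),
            inherits(weights, "admet_weights"))
  if (!all(endpoints$endpoints %in% weights$endpoint))
    stop("weights missing for endpoints: ",
         paste(setdiff(endpoints$endpoints, weights$endpoint), collapse = ", "))
  w <- weights[match(endpoints$endpoints, weights$endpoint), ]
  raw <- as.vector(endpoints$values %*% (w$w1 * w$w2 * w$w3))
  out <- data.frame(id = endpoints$ids, admet_raw = raw,
                    stringsAsFactors = FALSE)
  if (!is.null(drug_range)) {
    if (length(drug_range) != 2 || !(drug_range[1] < drug_range[2]))
      stop("drug_range must be c(min, max) with min < max")
    out$admet_std <- (raw - drug_range[1]) / (drug_range[2] - drug_range[1])
  }
  out
}

#' Likeness profiles: QED, RDL, Ro5 and ADMET-score for a compound set
#'
#' Convenience wrapper fitting the QED and RDL reference models on the drug
#' rows of a property table, deriving ADMET weights and the drug raw-score
#' range from the drug endpoint rows, and scoring every compound.
#'
#' @param properties property data frame from [eight_properties()] or
#'   [generate_property_tables()] (must have `id`, `category` and the eight
#'   property columns).
#' @param endpoints an [endpoint_table()] covering the same ids.
#' @param reference_category category used as the RDL reference
#'   (default `"toxin"`).
#' @param w2,w3 passed to [derive_admet_weights()].
#' @return data frame: `id`, `category`, `qed`, `rdl`, `ro5`, `admet_raw`,
#'   `admet_std`.
#' @export
likeness_profiles <- function(properties, endpoints,
                              reference_category = "toxin",
                              w2 = NULL, w3 = NULL) {
  stopifnot(all(c("id", "category", QED_PROPERTIES) %in% names(properties)))
  drugs <- properties[properties$category == "drug", ]
  refs <- properties[properties$category == reference_category, ]
  qm <- fit_qed_models(drugs)
  rm_ <- fit_rdl_models(drugs, refs)
  prof <- data.frame(id = properties$id, category = properties$category,
                     qed = qed_scores(properties, qm),
                     rdl = rdl_scores(properties, rm_),
                     ro5 = ro5_violations(properties$MW, properties$ALOGP,
                                          properties$HBD, properties$HBA),
                     stringsAsFactors = FALSE)
  w <- derive_admet_weights(
    endpoint_subset(endpoints, properties$id[properties$category == "drug"]),
    w2 = w2, w3 = w3)
  drug_raw <- admet_score(
    endpoint_subset(endpoints, prof$id[prof$category == "drug"]), w)$admet_raw
  sc <- admet_score(endpoint_subset(endpoints, prof$id), w,
                    drug_range = range(drug_raw))
  merge_by_id(prof, sc)
}

endpoint_subset <- function(x, ids) {
  stopifnot(inherits(x, "endpoint_table"))
  missing <- setdiff(ids, x$ids)
  if (length(missing))
    stop("endpoint table missing ids: ", paste(missing, collapse = ", "))
  endpoint_table(x$values[match(ids, x$ids), , drop = FALSE])
}

merge_by_id <- function(a, b) {
  out <- merge(a, b, by = "id", sort = FALSE)
  out[match(a$id, out$id), , drop = FALSE]
}
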