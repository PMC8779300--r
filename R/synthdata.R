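# Synthetic drug / NP / toxin compound sets with the statistical structure
# the analysis assumes: shifted multivariate descriptor clouds, unimodal
# drug property histograms with heavier NP molecular-weight tails and
# elevated toxin alert rates, and category-specific ADMET endpoint
# beneficial-probabilities.

#' Simulation configuration
#'
#' Defaults are desk-scale versions of the reference study conditions
#' (drug/NP/toxin libraries in roughly the 2:5.6:2 ratio of the full
#' 2009/5600/2012 sets, scaled to 200/560/200 so a full pipeline run stays
#' in test-suite time). `delta` is the magnitude of the per-category mean
#' offset in descriptor space, along fixed orthogonal unit directions, so it
#' maps monotonically to the expected PERMANOVA r-squared.
#'
#' @param n_drug,n_np,n_toxin library sizes (each >= 2).
#' @param seed integer seed; all generators are bit-reproducible under it.
#' @param descriptor_dim number of continuous descriptors (default 51).
#' @param delta descriptor-space group shift magnitude (default 1).
#' @param property_params per-category distribution parameters for the
#'   eight QED properties; see [default_property_params()].
#' @param endpoint_params per-category beneficial-probabilities, each a
#'   single value or one per endpoint; see [default_endpoint_params()].
#' @param n_endpoints number of binary ADMET endpoints (default 18).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_drug = 200, n_np = 560, n_toxin = 200,
                       seed = 1L, descriptor_dim = 51, delta = 1,
                       property_params = default_property_params(),
                       endpoint_params = default_endpoint_params(),
                       n_endpoints = 18) {
  if (min(n_drug, n_np, n_toxin) < 2) stop("category counts must be >= 2")
  if (descriptor_dim < 2) stop("descriptor_dim must be >= 2")
  if (delta < 0) stop("delta must be >= 0")
  probs <- unlist(endpoint_params)
  if (any(probs < 0 | probs > 1))
    stop("endpoint beneficial-probabilities must lie in [0, 1]")
  structure(list(n_drug = n_drug, n_np = n_np, n_toxin = n_toxin,
                 seed = as.integer(seed), descriptor_dim = descriptor_dim,
                 delta = delta, property_params = property_params,
                 endpoint_params = endpoint_params,
                 n_endpoints = n_endpoints),
            class = "sim_config")
}

#' Default per-category property distribution parameters
#'
#' Drugs: unimodal, oral-drug-typical centres (log-normal MW with median
#' 350 Da). NPs: heavier molecular-weight tail and broader lipophilicity.
#' Toxins: elevated structural-alert rates. Counts are Poisson, MW is
#' log-normal, ALOGP normal, PSA gamma.
#'
#' @return nested list `category -> property -> parameters`.
#' @export
default_property_params <- function() {
  list(
    drug = list(MW = c(meanlog = log(350), sdlog = 0.35),
                ALOGP = c(mean = 2.5, sd = 1.3),
                HBD = c(lambda = 1.8), HBA = c(lambda = 4.5),
                PSA = c(shape = 3.2, scale = 25),
                ROTB = c(lambda = 5), AROM = c(lambda = 1.7),
                ALERTS = c(lambda = 0.35)),
    np = list(MW = c(meanlog = log(420), sdlog = 0.65),
              ALOGP = c(mean = 2.0, sd = 2.2),
              HBD = c(lambda = 3), HBA = c(lambda = 6),
              PSA = c(shape = 3, scale = 40),
              ROTB = c(lambda = 6), AROM = c(lambda = 1.0),
              ALERTS = c(lambda = 0.8)),
    toxin = list(MW = c(meanlog = log(300), sdlog = 0.55),
                 ALOGP = c(mean = 2.8, sd = 1.8),
                 HBD = c(lambda = 1.5), HBA = c(lambda = 3.5),
                 PSA = c(shape = 2.5, scale = 30),
                 ROTB = c(lambda = 4), AROM = c(lambda = 1.6),
                 ALERTS = c(lambda = 2.0)))
}

#' Default per-category ADMET endpoint beneficial-probabilities
#'
#' NPs above drugs (low predicted toxicity), toxins well below — the
#' direction the reference comparisons report.
#' @return list `category -> probability`.
#' @export
default_endpoint_params <- function() {
  list(drug = 0.75, np = 0.85, toxin = 0.45)
}

sim_ids <- function(cfg) {
  list(drug = sprintf("D%04d", seq_len(cfg$n_drug)),
       np = sprintf("L%05d", seq_len(cfg$n_np)),
       toxin = sprintf("T%04d", seq_len(cfg$n_toxin)))
}

sim_counts <- function(cfg) c(drug = cfg$n_drug, np = cfg$n_np,
                              toxin = cfg$n_toxin)

#' Generate a labelled synthetic descriptor table
#'
#' Each category is sampled from a multivariate Gaussian with identity
#' covariance and mean `delta * u_g`, where `u_1, u_2, u_3` are the first
#' three standard basis directions (fixed and orthogonal, so `delta` maps
#' monotonically to expected group separation).
#'
#' @param cfg a [sim_config()].
#' @return A [descriptor_table()] with all three categories.
#' @export
generate_descriptor_tables <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ids <- sim_ids(cfg)
  counts <- sim_counts(cfg)
  p <- cfg$descriptor_dim
  withr::with_seed(cfg$seed, {
    blocks <- lapply(seq_along(counts), function(g) {
      n <- counts[g]
      m <- matrix(rnorm(n * p), n, p)
      shift <- numeric(p)
      shift[min(g, p)] <- cfg$delta
      sweep(m, 2, shift, "+")
    })
    vals <- do.call(rbind, blocks)
    rownames(vals) <- unlist(ids)
    colnames(vals) <- sprintf("desc_%02d", seq_len(p))
    descriptor_table(vals, rep(names(counts), counts))
  })
}

rpois_named <- function(n, par) rpois(n, par[["lambda"]])

#' Generate synthetic eight-property tables for all categories
#'
#' @param cfg a [sim_config()].
#' @return data frame: `id`, `category`, `MW`, `ALOGP`, `HBD`, `HBA`,
#'   `PSA`, `ROTB`, `AROM`, `ALERTS`.
#' @export
generate_property_tables <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ids <- sim_ids(cfg)
  counts <- sim_counts(cfg)
  pp <- cfg$property_params
  bad <- vapply(pp, function(p) any(!is.finite(unlist(p))) ||
                  any(unlist(p)[grepl("lambda|sd|sdlog|shape|scale",
                                      names(unlist(p)))] < 0), TRUE)
  if (any(bad)) stop("invalid property distribution parameters for: ",
                     paste(names(pp)[bad], collapse = ", "))
  withr::with_seed(cfg$seed + 1L, {
    blocks <- lapply(names(counts), function(g) {
      n <- counts[[g]]
      p <- pp[[g]]
      data.frame(
        id = ids[[g]], category = g,
        MW = rlnorm(n, p$MW[["meanlog"]], p$MW[["sdlog"]]),
        ALOGP = rnorm(n, p$ALOGP[["mean"]], p$ALOGP[["sd"]]),
        HBD = rpois_named(n, p$HBD), HBA = rpois_named(n, p$HBA),
        PSA = rgamma(n, shape = p$PSA[["shape"]], scale = p$PSA[["scale"]]),
        ROTB = rpois_named(n, p$ROTB), AROM = rpois_named(n, p$AROM),
        ALERTS = rpois_named(n, p$ALERTS),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, blocks)
  })
}

#' Generate synthetic binary ADMET endpoint tables
#'
#' Independent Bernoulli draws per endpoint with the category's
#' beneficial-probability.
#'
#' @param cfg a [sim_config()].
#' @return named list of [endpoint_table()]s (`drug`, `np`, `toxin`).
#' @export
generate_endpoint_tables <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ids <- sim_ids(cfg)
  counts <- sim_counts(cfg)
  ep_names <- sprintf("endpoint_%02d", seq_len(cfg$n_endpoints))
  withr::with_seed(cfg$seed + 2L, {
    out <- lapply(names(counts), function(g) {
      n <- counts[[g]]
      prob <- rep_len(cfg$endpoint_params[[g]], cfg$n_endpoints)
      vals <- vapply(prob, function(pr) rbinom(n, 1L, pr), integer(n))
      if (n == 1L) vals <- matrix(vals, nrow = 1L)
      dimnames(vals) <- list(ids[[g]], ep_names)
      endpoint_table(vals)
    })
    stats::setNames(out, names(counts))
  })
}

#' Combine the per-category endpoint tables into one
#' @param tables list of [endpoint_table()]s.
#' @return a single [endpoint_table()].
#' @export
bind_endpoint_tables <- function(tables) {
  endpoint_table(do.call(rbind, lapply(tables, `[[`, "values")))
}

#' Curated fixture structures
#'
#' Returns the first `n` molecules of the shipped fixture list of
#' well-known, valid small-molecule SMILES (including nitro-containing
#' compounds for the structural-alert path).
#'
#' @param n number of molecules (at most the fixture list size).
#' @param category category label to assign (default `"np"`).
#' @return A [molecule_set()].
#' @export
fixture_structures <- function(n = NULL, category = "np") {
  path <- system.file("extdata", "fixture_structures.smi",
                      package = "npdrugspace")
  ms <- read_molecules(path, format = "smiles", category = category)
  if (is.null(n)) return(ms)
  if (n > nrow(ms))
    stop("only ", nrow(ms), " fixture structures available (asked for ", n, ")")
  out <- ms[seq_len(n), , drop = FALSE]
  class(out) <- c("molecule_set", "data.frame")
  out
}

#' Generate a full synthetic library
#'
#' Bundles the three generators: descriptor table, property table, and
#' endpoint tables, all reproducible from the configuration seed.
#'
#' @param cfg a [sim_config()].
#' @return list: `config`, `descriptors` ([descriptor_table()]),
#'   `properties` (data frame), `endpoints` (list of [endpoint_table()]s).
#' @export
simulate_library <- function(cfg = sim_config()) {
  list(config = cfg,
       descriptors = generate_descriptor_tables(cfg),
       properties = generate_property_tables(cfg),
       endpoints = generate_endpoint_tables(cfg))
}
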