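# End-to-end scoring: from molecule sets, property, descriptor and endpoint
# tables to the ranked composite report.

#' Attach fixture structures to a synthetic library
#'
#' Synthetic compound sets are statistical objects without structures; the
#' structural-similarity components (fingerprint and MCS Tanimoto) need
#' molecular graphs. This assigns each synthetic compound a structure drawn
#' (with replacement, seeded) from the curated fixture list, so structures
#' recur across compounds — acceptable for exercising the similarity
#' pipeline, not a model of library diversity (no novel structures are
#' generated).
#'
#' @param cfg a [sim_config()].
#' @return A [molecule_set()] covering all three categories, ids matching
#'   the other generators.
#' @export
assign_fixture_structures <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  fixtures <- fixture_structures()
  ids <- sim_ids(cfg)
  counts <- sim_counts(cfg)
  withr::with_seed(cfg$seed + 3L, {
    smi <- sample(fixtures$smiles, sum(counts), replace = TRUE)
  })
  molecule_set(unlist(ids), smi, rep(names(counts), counts))
}

# Memoised MCS Tanimoto over the unique structure pairs of two molecule
# sets; returns a lookup matrix [unique query smiles x unique drug smiles].
mcs_matrix <- function(query_smiles, drug_smiles, time_cap = 5) {
  uq <- unique(query_smiles)
  ud <- unique(drug_smiles)
  m <- matrix(NA_real_, length(uq), length(ud), dimnames = list(uq, ud))
  for (a in seq_along(uq)) for (b in seq_along(ud)) {
    m[a, b] <- as.numeric(mcs_tanimoto(uq[a], ud[b], time_cap = time_cap))
  }
  m
}

#' Score a full library: likeness, similarity, composite
#'
#' Runs the whole pipeline on id-aligned inputs: likeness profiles (QED,
#' RDL, Ro5, ADMET-score), drug-range scaling and mean Jaccard similarity
#' to the drug cloud, fingerprint + MCS Tanimoto similarity to the drugs,
#' and the composite summed index with quadrant labels for the scored
#' (non-drug, non-reference) compounds — by default the NPs, matching the
#' triage use case.
#'
#' Structural similarity is memoised over unique structures, so libraries
#' that reuse fixture structures (see [assign_fixture_structures()]) scale
#' by the number of distinct structures, not compounds.
#'
#' @param molecules [molecule_set()] with structures for drugs and scored
#'   compounds.
#' @param properties eight-property data frame (computed or synthetic).
#' @param descriptors a [descriptor_table()] (computed or synthetic).
#' @param endpoints a single [endpoint_table()] covering all ids.
#' @param score_category category to rank (default `"np"`).
#' @param reference_category RDL reference (default `"toxin"`).
#' @param bits,time_cap,drug_sample,seed similarity options; see
#'   [mean_tanimoto_to_drugs()].
#' @param thresholds a [quadrant_thresholds()].
#' @return list: `profiles`, `similarity`, `composite`, `report` (ranked).
#' @export
score_library <- function(molecules, properties, descriptors, endpoints,
                          score_category = "np",
                          reference_category = "toxin",
                          bits = 1024, time_cap = 5,
                          drug_sample = NULL, seed = NULL,
                          thresholds = quadrant_thresholds()) {
  profiles <- likeness_profiles(properties, endpoints,
                                reference_category = reference_category)
  scaled <- drug_range_scale(descriptors)
  score_ids <- descriptors$ids[descriptors$categories == score_category]
  jac <- mean_jaccard_to_drugs(scaled, ids = score_ids)

  drugs <- molecules[molecules$category == "drug", , drop = FALSE]
  class(drugs) <- c("molecule_set", "data.frame")
  queries <- molecules[match(score_ids, molecules$id), , drop = FALSE]
  class(queries) <- c("molecule_set", "data.frame")
  if (!is.null(drug_sample) && drug_sample < nrow(drugs)) {
    keep <- withr::with_seed(
      if (is.null(seed)) sample.int(.Machine$integer.max, 1) else seed,
      sample.int(nrow(drugs), drug_sample))
    message("score_library: subsampled ", drug_sample, " of ",
            nrow(drugs), " drugs for structural similarity")
    drugs <- drugs[keep, , drop = FALSE]
    class(drugs) <- c("molecule_set", "data.frame")
  }

  uniq <- unique(c(queries$smiles, drugs$smiles))
  uniq_ms <- molecule_set(paste0("u", seq_along(uniq)), uniq, "np")
  fps <- atom_pair_fingerprints(uniq_ms, bits = bits)
  fp_of <- function(smi) {
    uid <- paste0("u", match(smi, uniq))
    if (uid %in% rownames(fps)) fps[uid, ] else NULL
  }
  mcs_m <- mcs_matrix(queries$smiles, drugs$smiles, time_cap = time_cap)
  fp_cache <- new.env(parent = emptyenv())
  fp_pair <- function(s1, s2) {
    key <- paste(match(s1, uniq), match(s2, uniq))
    if (!is.null(fp_cache[[key]])) return(fp_cache[[key]])
    f1 <- fp_of(s1); f2 <- fp_of(s2)
    v <- if (is.null(f1) || is.null(f2)) NA_real_ else fingerprint_tanimoto(f1, f2)
    fp_cache[[key]] <- v
    v
  }
  sim <- do.call(rbind, lapply(seq_len(nrow(queries)), function(i) {
    fp_t <- vapply(drugs$smiles, function(d) fp_pair(queries$smiles[i], d), 0)
    mcs_t <- mcs_m[queries$smiles[i], drugs$smiles]
    ok <- !is.na(fp_t)
    data.frame(id = queries$id[i],
               mean_fp_tanimoto = mean(fp_t[ok]),
               mean_mcs_tanimoto = mean(mcs_t),
               tanimoto_index = mean(tanimoto_index(fp_t[ok], mcs_t[ok])),
               n_drugs = sum(ok), stringsAsFactors = FALSE)
  }))

  prof_scored <- profiles[match(score_ids, profiles$id), ]
  components <- data.frame(id = score_ids,
                           mean_jaccard = jac$mean_jaccard[match(score_ids, jac$id)],
                           tanimoto_index = sim$tanimoto_index[match(score_ids, sim$id)],
                           rdl = prof_scored$rdl,
                           admet = prof_scored$admet_std,
                           ro5 = prof_scored$ro5,
                           qed = prof_scored$qed,
                           stringsAsFactors = FALSE)
  comp <- composite_scores(components, thresholds = thresholds)
  similarity <- merge(jac, sim, by = "id", sort = FALSE)
  report <- rank_report(profiles, similarity, comp)
  list(profiles = profiles, similarity = similarity,
       composite = comp, report = report)
}
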