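# Chemical-space analyses: drug-range scaling, PCA, PERMANOVA, quantitative
# Jaccard similarity to the drug cloud, fingerprint and MCS Tanimoto.

#' Drug-range scaling of a descriptor table
#'
#' Each variable is rescaled as `(x - drug_min) / (drug_max - drug_min)`
#' using the minimum and maximum over the reference drugs, so drug values
#' span `[0, 1]` while other compound classes may fall outside (the count of
#' out-of-range cells is reported via a message and the `n_out_of_range`
#' attribute). The transform is deliberately not idempotent.
#'
#' @param tab a [descriptor_table()].
#' @param drug_ids ids of the reference drugs; default all rows with
#'   category `"drug"`.
#' @param lenient drop variables that are constant over drugs (with a
#'   warning) instead of erroring.
#' @return A scaled [descriptor_table()].
#' @export
drug_range_scale <- function(tab, drug_ids = NULL, lenient = FALSE) {
  stopifnot(inherits(tab, "descriptor_table"))
  if (is.null(drug_ids)) drug_ids <- tab$ids[tab$categories == "drug"]
  if (!length(drug_ids)) stop("no reference drugs for drug-range scaling")
  dv <- tab$values[match(drug_ids, tab$ids), , drop = FALSE]
  lo <- apply(dv, 2, min)
  hi <- apply(dv, 2, max)
  const <- hi == lo
  if (any(const)) {
    if (!lenient)
      stop("variable(s) constant over drugs: ",
           paste(tab$variables[const], collapse = ", "))
    warning("dropping variable(s) constant over drugs: ",
            paste(tab$variables[const], collapse = ", "))
  }
  keep <- !const
  scaled <- sweep(tab$values[, keep, drop = FALSE], 2, lo[keep], "-")
  scaled <- sweep(scaled, 2, (hi - lo)[keep], "/")
  n_out <- sum(scaled < 0 | scaled > 1)
  if (n_out > 0)
    message("drug_range_scale: ", n_out,
            " scaled cells fall outside [0, 1] (non-drug compounds)")
  out <- descriptor_table(scaled, tab$categories)
  attr(out, "n_out_of_range") <- n_out
  out
}

#' Principal component analysis of a (scaled) descriptor table
#'
#' Eigen-decomposition of the covariance matrix of the supplied data as-is
#' (centred, no re-standardisation, mirroring the drug-range-scale-then-PCA
#' order of operations). Variable contributions per axis are
#' `100 * loading^2 / sum(loading^2)`.
#'
#' @param tab a [descriptor_table()] (typically [drug_range_scale()]d).
#' @param n_axes number of axes to report correlations/contributions for.
#' @return Object of class `pca_result`: `scores`, `axis_variance_pct`
#'   (all axes, sums to 100), `variable_correlations`,
#'   `variable_contributions_pct` (each axis sums to 100), `n_axes`.
#' @export
run_pca <- function(tab, n_axes = 2) {
  stopifnot(inherits(tab, "descriptor_table"))
  if (any(!is.finite(tab$values))) stop("non-finite descriptor values")
  pc <- prcomp(tab$values, center = TRUE, scale. = FALSE)
  var_pct <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  n_axes <- min(n_axes, ncol(pc$rotation))
  ax <- seq_len(n_axes)
  contrib <- 100 * sweep(pc$rotation[, ax, drop = FALSE]^2, 2,
                         colSums(pc$rotation[, ax, drop = FALSE]^2), "/")
  cors <- suppressWarnings(cor(tab$values, pc$x[, ax, drop = FALSE]))
  structure(list(scores = pc$x, axis_variance_pct = var_pct,
                 variable_correlations = cors,
                 variable_contributions_pct = contrib,
                 categories = tab$categories, n_axes = n_axes),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", nrow(x$scores), " molecules; first ", x$n_axes,
      " axes explain ",
      sprintf("%.1f%%", sum(x$axis_variance_pct[seq_len(x$n_axes)])),
      " of variance\n", sep = "")
  invisible(x)
}

# All distinct arrangements of a label multiset (exact permutation null).
multiset_permutations <- function(labels) {
  rec <- function(remaining) {
    if (!length(remaining)) return(list(character(0)))
    out <- list()
    for (u in unique(remaining)) {
      rest <- remaining[-match(u, remaining)]
      out <- c(out, lapply(rec(rest), function(t) c(u, t)))
    }
    out
  }
  rec(labels)
}

# Pseudo-F and R2 from a squared-distance matrix and group labels.
# SS_total = (1/N) sum_{i<j} d2_ij ; SS_within = sum_g (1/n_g) sum_{i<j in g} d2_ij
permanova_stats <- function(d2, labels) {
  n <- length(labels)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  groups <- split(seq_len(n), labels)
  ss_within <- sum(vapply(groups, function(idx) {
    sub <- d2[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]) / length(idx)
  }, 0))
  ss_among <- ss_total - ss_within
  k <- length(groups)
  f <- (ss_among / (k - 1)) / (ss_within / (n - k))
  list(F = f, r2 = ss_among / ss_total, df_among = k - 1, df_within = n - k)
}

#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Partitions squared inter-point distances among and within groups and
#' assesses the pseudo-F statistic by uniform random permutation of the
#' label vector. The p-value uses the `(1 + b) / (1 + m)` estimator (`b` =
#' permuted F >= observed), so it is never 0 and never below
#' `1 / (n_perm + 1)`.
#'
#' @param x a [descriptor_table()], a numeric matrix (rows = molecules, in
#'   which case Euclidean distances are computed), or a `dist` object (use
#'   `as.dist()` on a square distance matrix read from CSV).
#' @param labels group label per molecule (defaults to the table's
#'   categories when `x` is a [descriptor_table()]).
#' @param n_perm number of permutations (default 999; ignored when
#'   `exact = TRUE`).
#' @param seed optional integer seed for the permutation stream.
#' @param exact enumerate all distinct label arrangements instead of
#'   sampling (feasible for small instances only); the p-value is then the
#'   exact proportion of arrangements (identity included) with `F >=`
#'   observed.
#' @return Object of class `permanova_result`: `F`, `r2`, `p`, `df_among`,
#'   `df_within`, `n_perm`.
#' @export
permanova <- function(x, labels = NULL, n_perm = 999, seed = NULL,
                      exact = FALSE) {
  if (inherits(x, "descriptor_table")) {
    if (is.null(labels)) labels <- x$categories
    x <- x$values
  }
  d2 <- if (inherits(x, "dist")) as.matrix(x)^2 else as.matrix(dist(as.matrix(x)))^2
  labels <- as.character(labels)
  n <- length(labels)
  if (n != nrow(d2)) stop("labels length does not match number of molecules")
  sizes <- table(labels)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) stop("every group needs at least 2 members (offending: ",
                           paste(names(sizes)[sizes < 2], collapse = ", "), ")")
  obs <- permanova_stats(d2, labels)
  if (exact) {
    arrangements <- multiset_permutations(labels)
    perm_f <- vapply(arrangements, function(l) permanova_stats(d2, l)$F, 0)
    p <- mean(perm_f >= obs$F - 1e-12)
    n_perm <- length(arrangements)
  } else {
    perm_f <- withr::with_seed(
      if (is.null(seed)) sample.int(.Machine$integer.max, 1) else seed,
      vapply(seq_len(n_perm), function(b) {
        permanova_stats(d2, labels[sample.int(n)])$F
      }, 0))
    p <- (1 + sum(perm_f >= obs$F)) / (1 + n_perm)
  }
  structure(list(F = obs$F, r2 = obs$r2, p = p,
                 df_among = obs$df_among, df_within = obs$df_within,
                 n_perm = n_perm),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("<permanova> F%d,%d = %.3f, r2 = %.4f, p = %.4g (%d permutations)\n",
              x$df_among, x$df_within, x$F, x$r2, x$p, x$n_perm))
  invisible(x)
}

#' Quantitative Jaccard (Ruzicka) similarity of two non-negative vectors
#'
#' `sum_j min(x_j, y_j) / sum_j max(x_j, y_j)`; 1 = identical profiles,
#' towards 0 = little shared structure. A pair of all-zero vectors is
#' defined as identical (similarity 1) and reported via a message.
#'
#' @param x,y non-negative numeric vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
ruzicka <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (any(x < 0) || any(y < 0)) stop("quantitative Jaccard needs non-negative values")
  denom <- sum(pmax(x, y))
  if (denom == 0) {
    message("ruzicka: all-zero pair, similarity defined as 1")
    return(1)
  }
  sum(pmin(x, y)) / denom
}

#' Mean quantitative Jaccard similarity of each compound to the drug cloud
#'
#' Rows are clipped to `[0, 1]` first (drug-range-scaled non-drug values can
#' fall outside; the clipped-cell count is reported), then each non-drug
#' compound's similarity to every drug is averaged.
#'
#' @param tab a drug-range-scaled [descriptor_table()].
#' @param drug_ids reference drug ids; default category `"drug"` rows.
#' @param ids compounds to score; default every non-drug row.
#' @return data frame `id`, `mean_jaccard`.
#' @export
mean_jaccard_to_drugs <- function(tab, drug_ids = NULL, ids = NULL) {
  stopifnot(inherits(tab, "descriptor_table"))
  if (is.null(drug_ids)) drug_ids <- tab$ids[tab$categories == "drug"]
  if (!length(drug_ids)) stop("no reference drugs")
  if (is.null(ids)) ids <- setdiff(tab$ids, drug_ids)
  v <- tab$values
  n_clip <- sum(v < 0 | v > 1)
  if (n_clip > 0)
    message("mean_jaccard_to_drugs: clipping ", n_clip,
            " out-of-range cells to [0, 1]")
  v[v < 0] <- 0
  v[v > 1] <- 1
  drugs <- v[match(drug_ids, tab$ids), , drop = FALSE]
  sims <- vapply(match(ids, tab$ids), function(i) {
    x <- v[i, ]
    mn <- rowSums(pmin(drugs, matrix(x, nrow(drugs), ncol(drugs), byrow = TRUE)))
    mx <- rowSums(pmax(drugs, matrix(x, nrow(drugs), ncol(drugs), byrow = TRUE)))
    zero <- mx == 0
    s <- ifelse(zero, 1, mn / pmax(mx, .Machine$double.eps))
    mean(s)
  }, 0)
  data.frame(id = ids, mean_jaccard = sims, stringsAsFactors = FALSE)
}

#' Tanimoto similarity of two binary fingerprints
#'
#' `c / (a + b - c)` with `a`, `b` the set bits of each fingerprint and `c`
#' the common set bits. Two empty fingerprints are defined as identical
#' (similarity 1, reported via a message).
#'
#' @param fpA,fpB binary (0/1 or logical) vectors from the same fingerprint
#'   scheme; lengths must match.
#' @return similarity in `[0, 1]`.
#' @export
fingerprint_tanimoto <- function(fpA, fpB) {
  fpA <- as.logical(as.numeric(fpA))
  fpB <- as.logical(as.numeric(fpB))
  if (length(fpA) != length(fpB))
    stop("fingerprint length mismatch: ", length(fpA), " vs ", length(fpB))
  a <- sum(fpA); b <- sum(fpB); c <- sum(fpA & fpB)
  if (a + b == 0) {
    message("fingerprint_tanimoto: two empty fingerprints, similarity 1")
    return(1)
  }
  c / (a + b - c)
}

#' Atom-pair substructure fingerprints for a molecule set
#'
#' Atom-pair descriptors folded to a fixed-length binary fingerprint
#' (the `sdf2ap`/`desc2fp` lineage). Molecules whose fingerprint cannot be
#' generated are dropped with a report, mirroring reduced-dataset practice.
#'
#' @param ms a [molecule_set()].
#' @param bits fingerprint length (default 1024).
#' @return binary matrix (rows = molecules that fingerprinted, rownames =
#'   ids) with attribute `failed` listing dropped ids.
#' @export
atom_pair_fingerprints <- function(ms, bits = 1024) {
  conv <- mol_sdfset(ms)
  failed <- conv$skipped
  ap <- suppressWarnings(ChemmineR::sdf2ap(conv$sdf, uniquePairs = TRUE))
  bad <- vapply(seq_along(conv$ids), function(i) {
    length(ChemmineR::ap(ap[i])[[1]]) == 0
  }, TRUE)
  if (any(bad)) {
    failed <- c(failed, conv$ids[bad])
    ap <- ap[!bad]
  }
  if (length(failed))
    message("atom_pair_fingerprints: no fingerprint for ",
            length(failed), " molecule(s): ", paste(failed, collapse = ", "))
  # most frequent atom-pair descriptors used as fingerprint positions; the
  # frequency table ships with ChemmineR (loaded explicitly: the package is
  # imported, not attached)
  e <- new.env()
  utils::data("apfp", package = "ChemmineR", envir = e)
  descnames <- as.character(e$apfp$AP)[seq_len(bits)]
  fp <- ChemmineR::desc2fp(ap, descnames = descnames, type = "matrix")
  rownames(fp) <- conv$ids[!bad]
  storage.mode(fp) <- "integer"
  attr(fp, "failed") <- failed
  fp
}

# ---- maximum common substructure -------------------------------------------

# Molecular graph (heavy atoms): list(elements, adjacency) from SMILES.
mol_graph <- function(smiles, id = "molecule") {
  can <- ob_parse_smiles(smiles)
  if (is.na(can)) stop("unparseable structure for ", id)
  sdf_txt <- ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n"))
  lines <- strsplit(sdf_txt, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  n_atoms <- as.integer(substr(counts, 1, 3))
  n_bonds <- as.integer(substr(counts, 4, 6))
  if (is.na(n_atoms) || n_atoms == 0) stop("empty molecule: ", id)
  atom_lines <- lines[5:(4 + n_atoms)]
  elements <- trimws(substr(atom_lines, 32, 34))
  adj <- matrix(FALSE, n_atoms, n_atoms)
  if (n_bonds > 0) {
    bond_lines <- lines[(5 + n_atoms):(4 + n_atoms + n_bonds)]
    from <- as.integer(substr(bond_lines, 1, 3))
    to <- as.integer(substr(bond_lines, 4, 6))
    adj[cbind(from, to)] <- TRUE
    adj[cbind(to, from)] <- TRUE
  }
  heavy <- elements != "H"
  list(elements = elements[heavy],
       adjacency = adj[heavy, heavy, drop = FALSE])
}

# Maximum clique (branch and bound, Carraghan-Pardalos) with a deadline.
# Returns list(size, exact).
max_clique_size <- function(adj, deadline) {
  n <- nrow(adj)
  if (n == 0) return(list(size = 0L, exact = TRUE))
  best <- 0L
  exact <- TRUE
  ord <- order(rowSums(adj), decreasing = TRUE)
  adj <- adj[ord, ord, drop = FALSE]
  expand <- function(size, cand) {
    if (proc.time()[["elapsed"]] > deadline) {
      exact <<- FALSE
      return(invisible())
    }
    if (size > best) best <<- size
    while (length(cand)) {
      if (size + length(cand) <= best) return(invisible())
      v <- cand[1]
      cand <- cand[-1]
      expand(size + 1L, cand[adj[v, cand]])
    }
  }
  expand(0L, seq_len(n))
  list(size = best, exact = exact)
}

# Modular product graph of two molecular graphs: vertices are element-
# compatible atom pairs; edges connect pairs that agree on adjacency
# (bond/bond or non-bond/non-bond), so cliques are common induced subgraphs.
modular_product <- function(g1, g2) {
  pairs <- expand.grid(i = seq_along(g1$elements), j = seq_along(g2$elements))
  pairs <- pairs[g1$elements[pairs$i] == g2$elements[pairs$j], , drop = FALSE]
  m <- nrow(pairs)
  if (m == 0) return(matrix(FALSE, 0, 0))
  adj <- matrix(FALSE, m, m)
  for (a in seq_len(m)) {
    i1 <- pairs$i[a]; j1 <- pairs$j[a]
    ok <- pairs$i != i1 & pairs$j != j1 &
      (g1$adjacency[i1, pairs$i] == g2$adjacency[j1, pairs$j])
    adj[a, ] <- ok
  }
  adj
}

#' Maximum-common-substructure Tanimoto similarity
#'
#' The MCS is the largest common induced subgraph of the two molecular
#' graphs (atoms matched by element, bonds by order-agnostic connectivity;
#' hydrogens excluded), found exactly by branch-and-bound search on the
#' modular product graph. The similarity is `|MCS| / (|A| + |B| - |MCS|)`
#' with sizes in heavy atoms. If the time cap is hit the best clique found
#' so far is used and the result carries `attr(,"exact") = FALSE` (a lower
#' bound).
#'
#' @param molA,molB SMILES strings (or single-row [molecule_set()]s).
#' @param time_cap seconds allowed for the exact search (default 5).
#' @return similarity in `[0, 1]` with attributes `mcs_size` and `exact`.
#' @export
mcs_tanimoto <- function(molA, molB, time_cap = 5) {
  smi <- function(m) if (inherits(m, "molecule_set")) m$smiles[1] else m
  g1 <- mol_graph(smi(molA), "molA")
  g2 <- mol_graph(smi(molB), "molB")
  prod_adj <- modular_product(g1, g2)
  deadline <- proc.time()[["elapsed"]] + time_cap
  res <- max_clique_size(prod_adj, deadline)
  s <- res$size / (length(g1$elements) + length(g2$elements) - res$size)
  structure(s, mcs_size = res$size, exact = res$exact)
}

#' Combined Tanimoto index
#'
#' Combines the fingerprint and MCS Tanimoto similarities. The default
#' `sum_sq` mode is the squared-sum form `fp^2 + mcs^2`; `euclid` returns
#' its square root (the Euclidean norm of the similarity pair).
#'
#' @param fp_t,mcs_t similarities in `[0, 1]`.
#' @param mode `"sum_sq"` (default) or `"euclid"`.
#' @return index in `[0, 2]` (`sum_sq`) or `[0, sqrt(2)]` (`euclid`).
#' @export
tanimoto_index <- function(fp_t, mcs_t, mode = c("sum_sq", "euclid")) {
  mode <- match.arg(mode)
  if (any(fp_t < 0 | fp_t > 1) || any(mcs_t < 0 | mcs_t > 1))
    stop("tanimoto_index inputs must lie in [0, 1]")
  out <- as.numeric(fp_t)^2 + as.numeric(mcs_t)^2
  if (mode == "euclid") out <- sqrt(out)
  out
}

#' Mean Tanimoto similarity of each compound to a reference drug set
#'
#' For every query compound, the fingerprint Tanimoto, MCS Tanimoto, and
#' combined Tanimoto index against each reference drug are averaged over the
#' drugs. The drug set can be subsampled for tractability on large
#' libraries.
#'
#' @param ms query [molecule_set()] (e.g. the NPs).
#' @param drugs reference drug [molecule_set()].
#' @param bits fingerprint length (default 1024).
#' @param time_cap seconds per MCS pair (default 5).
#' @param mode passed to [tanimoto_index()].
#' @param drug_sample optional number of drugs to subsample.
#' @param seed seed for the subsample.
#' @return data frame: `id`, `mean_fp_tanimoto`, `mean_mcs_tanimoto`,
#'   `tanimoto_index` (mean of per-drug combined indices), `n_drugs`.
#' @export
mean_tanimoto_to_drugs <- function(ms, drugs, bits = 1024, time_cap = 5,
                                   mode = c("sum_sq", "euclid"),
                                   drug_sample = NULL, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(ms, "molecule_set"), inherits(drugs, "molecule_set"))
  if (!nrow(drugs)) stop("empty reference drug set")
  if (!is.null(drug_sample) && drug_sample < nrow(drugs)) {
    keep <- withr::with_seed(
      if (is.null(seed)) sample.int(.Machine$integer.max, 1) else seed,
      sample.int(nrow(drugs), drug_sample))
    message("mean_tanimoto_to_drugs: subsampled ", drug_sample, " of ",
            nrow(drugs), " drugs")
    drugs <- drugs[keep, , drop = FALSE]
    class(drugs) <- c("molecule_set", "data.frame")
  }
  all_fp <- atom_pair_fingerprints(rbind_molsets(ms, drugs), bits = bits)
  drug_fp_ids <- intersect(drugs$id, rownames(all_fp))
  if (!length(drug_fp_ids)) stop("no fingerprintable reference drugs")
  out <- lapply(seq_len(nrow(ms)), function(i) {
    id <- ms$id[i]
    fp_sims <- if (id %in% rownames(all_fp)) {
      vapply(drug_fp_ids, function(d)
        fingerprint_tanimoto(all_fp[id, ], all_fp[d, ]), 0)
    } else rep(NA_real_, length(drug_fp_ids))
    mcs_sims <- vapply(seq_len(nrow(drugs)), function(j)
      as.numeric(mcs_tanimoto(ms$smiles[i], drugs$smiles[j],
                              time_cap = time_cap)), 0)
    idx <- tanimoto_index(fp_sims[!is.na(fp_sims)],
                          mcs_sims[match(drug_fp_ids, drugs$id)][!is.na(fp_sims)],
                          mode = mode)
    data.frame(id = id,
               mean_fp_tanimoto = mean(fp_sims, na.rm = TRUE),
               mean_mcs_tanimoto = mean(mcs_sims),
               tanimoto_index = mean(idx),
               n_drugs = length(drug_fp_ids),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

rbind_molsets <- function(a, b) {
  both <- rbind(as.data.frame(a), as.data.frame(b))
  both <- both[!duplicated(both$id), , drop = FALSE]
  molecule_set(both$id, both$smiles, both$category, both$name)
}
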