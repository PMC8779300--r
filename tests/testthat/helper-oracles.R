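# Independent brute-force oracles and small fixture builders.

# Maximum common induced subgraph size by exhaustive enumeration: all
# subsets of molecule A's atoms (chosen in increasing order) and all
# injective, element- and adjacency/non-adjacency-preserving maps into B.
oracle_mcs_size <- function(smiA, smiB) {
  g1 <- npdrugspace:::mol_graph(smiA)
  g2 <- npdrugspace:::mol_graph(smiB)
  n1 <- length(g1$elements)
  n2 <- length(g2$elements)
  best <- 0L
  rec <- function(selA, mapB) {
    best <<- max(best, length(selA))
    lastA <- if (length(selA)) max(selA) else 0L
    if (lastA >= n1) return()
    for (a in seq(lastA + 1L, n1)) {
      for (b in setdiff(seq_len(n2), mapB)) {
        if (g1$elements[a] != g2$elements[b]) next
        ok <- TRUE
        for (i in seq_along(selA)) {
          if (g1$adjacency[selA[i], a] != g2$adjacency[mapB[i], b]) {
            ok <- FALSE
            break
          }
        }
        if (ok) rec(c(selA, a), c(mapB, b))
      }
    }
  }
  rec(integer(0), integer(0))
  best
}

oracle_mcs_tanimoto <- function(smiA, smiB) {
  s <- oracle_mcs_size(smiA, smiB)
  nA <- length(npdrugspace:::mol_graph(smiA)$elements)
  nB <- length(npdrugspace:::mol_graph(smiB)$elements)
  s / (nA + nB - s)
}

# Exhaustive-permutation PERMANOVA oracle via the coordinate-space ANOVA
# identity (independent of the package's distance-partition route).
# Enumerates label arrangements with combn, two or three groups.
oracle_permanova <- function(x, labels) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- length(unique(labels))
  sst <- sum(sweep(x, 2, colMeans(x))^2)
  f_of <- function(labs) {
    ssw <- sum(vapply(split(seq_len(n), labs), function(idx) {
      xs <- x[idx, , drop = FALSE]
      sum(sweep(xs, 2, colMeans(xs))^2)
    }, 0))
    ((sst - ssw) / (k - 1)) / (ssw / (n - k))
  }
  counts <- table(labels)
  nms <- names(counts)
  arrangements <- list()
  if (k == 2) {
    for (sel in asplit(combn(n, counts[[1]]), 2)) {
      l <- rep(nms[2], n)
      l[sel] <- nms[1]
      arrangements[[length(arrangements) + 1L]] <- l
    }
  } else if (k == 3) {
    for (sel1 in asplit(combn(n, counts[[1]]), 2)) {
      rest <- setdiff(seq_len(n), sel1)
      for (sel2 in asplit(combn(length(rest), counts[[2]]), 2)) {
        l <- rep(nms[3], n)
        l[sel1] <- nms[1]
        l[rest[sel2]] <- nms[2]
        arrangements[[length(arrangements) + 1L]] <- l
      }
    }
  } else stop("oracle supports 2 or 3 groups")
  f_obs <- f_of(labels)
  f_all <- vapply(arrangements, f_of, 0)
  list(F = f_obs, p = mean(f_all >= f_obs - 1e-12),
       n_arrangements = length(arrangements))
}

# Small molecule set from named SMILES.
make_molset <- function(smiles, category = "np") {
  molecule_set(names(smiles), unname(smiles), category)
}

# Minimal descriptor table.
make_desc_table <- function(values, categories) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("m%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("v%02d", seq_len(ncol(values)))
  descriptor_table(values, categories)
}

# Desirability model with prescribed values on [0, 1] (single cell).
flat_model <- function(d, floor = 1e-6) {
  structure(list(property = "toy", breaks = c(0, 1), d = d, floor = floor),
            class = "desirability_model")
}
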