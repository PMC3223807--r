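# Shared fixtures and independent oracles, built in code at test time.

# a tiny biomass table: years in rows, species in columns
toyTable <- function() {
  BiomassTable(cbind(cod = c(5, 3, 8, 1, 9, 2),
                     herring = c(10, 20, 30, 40, 50, 60)),
               2000:2005, c("cod", "herring"), regionId = "toy")
}

# independent K2 family oracle: direct factorial evaluation of
#   prod_j [ (r-1)! / (F_j + r - 1)! * prod_k F_jk! ]
# on explicit count tables, in log space but via a different route
# (lfactorial) than the implementation (lgamma on shifted arguments)
k2OracleFromCounts <- function(F) {
  r <- ncol(F)
  s <- 0
  for (j in seq_len(nrow(F))) {
    Fj <- sum(F[j, ])
    s <- s + lfactorial(r - 1) - lfactorial(Fj + r - 1) +
      sum(lfactorial(F[j, ]))
  }
  s
}

# tally a family's counts by brute force over records
tallyCounts <- function(records, child, parents, arities) {
  q <- prod(arities[parents])
  F <- matrix(0, max(q, 1), arities[[child]])
  for (m in seq_len(nrow(records))) {
    j <- 1L
    stride <- 1L
    for (p in parents) {
      j <- j + (records[m, p] - 1L) * stride
      stride <- stride * arities[[p]]
    }
    F[j, records[m, child]] <- F[j, records[m, child]] + 1
  }
  F
}

# oracle K2 joint score of a DAG: sums the factorial oracle over families
k2OracleNetwork <- function(records, arities, parents, c = 1) {
  log(c) + sum(vapply(names(parents), function(v)
    k2OracleFromCounts(tallyCounts(records, v, parents[[v]], arities)), 0))
}

# all 25 DAGs over 3 labelled nodes, as parent-set lists
allDags3 <- function(nodes = c("x", "y", "z")) {
  out <- list()
  edges <- t(combn(3, 2))
  # enumerate each unordered pair as absent / forward / backward, keep acyclic
  for (a in 0:2) for (b in 0:2) for (d in 0:2) {
    parents <- setNames(list(character(0), character(0), character(0)), nodes)
    add <- function(p, i, j) {
      p[[nodes[j]]] <- c(p[[nodes[j]]], nodes[i])
      p
    }
    if (a == 1) parents <- add(parents, 1, 2)
    if (a == 2) parents <- add(parents, 2, 1)
    if (b == 1) parents <- add(parents, 1, 3)
    if (b == 2) parents <- add(parents, 3, 1)
    if (d == 1) parents <- add(parents, 2, 3)
    if (d == 2) parents <- add(parents, 3, 2)
    if (!is.null(funcEquiv:::topoSort(parents))) {
      out[[length(out) + 1L]] <- parents
    }
  }
  out
}

# random DiscreteDataset with given arities
randomDataset <- function(M, arities, seed) {
  funcEquiv:::withSeed(seed, {
    rec <- matrix(0L, M, length(arities),
                  dimnames = list(NULL, names(arities)))
    for (v in names(arities)) {
      rec[, v] <- sample.int(arities[[v]], M, replace = TRUE)
    }
    DiscreteDataset(rec, arities)
  })
}

# brute-force joint of a parametrized network: full probability table over
# all configurations, by enumerating records one by one
jointEnumeration <- function(dag, cpts) {
  ar <- cpts@arities
  grid <- as.matrix(expand.grid(lapply(ar[dag@nodes], seq_len)))
  colnames(grid) <- dag@nodes
  p <- apply(grid, 1, function(row) {
    prod(vapply(dag@nodes, function(v) {
      pa <- parentSets(dag)[[v]]
      j <- funcEquiv:::configIndex(matrix(row[pa], 1), unname(ar[pa]))
      cpts@tables[[v]][j, row[[v]]]
    }, 0))
  })
  list(grid = grid, p = p)
}

# brute-force hidden-chain inference: enumerate all nH^T latent paths
pathEnumeration <- function(initial, transition, E) {
  P <- nrow(E)
  nH <- ncol(E)
  paths <- as.matrix(expand.grid(rep(list(seq_len(nH)), P)))
  w <- apply(paths, 1, function(h) {
    pr <- initial[h[1]] * E[1, h[1]]
    if (P > 1) for (i in 2:P) pr <- pr * transition[h[i - 1], h[i]] * E[i, h[i]]
    pr
  })
  ll <- log(sum(w))
  smoothed <- sapply(seq_len(P), function(i)
    vapply(seq_len(nH), function(s) sum(w[paths[, i] == s]), 0) / sum(w))
  filtered <- sapply(seq_len(P), function(i) {
    # renormalised joint of the prefix up to i
    wi <- apply(paths, 1, function(h) {
      pr <- initial[h[1]] * E[1, h[1]]
      if (i > 1) for (k in 2:i) pr <- pr * transition[h[k - 1], h[k]] * E[k, h[k]]
      pr
    })
    # collapse identical prefixes: sum over suffix dimensions is implicit
    # because wi ignores them; normalise over the state at i
    vapply(seq_len(nH), function(s) sum(wi[paths[, i] == s]), 0) /
      sum(wi) * (nH^(P - i)) / (nH^(P - i))
  })
  # filtered computed above double-counts suffix paths uniformly, which
  # cancels in the normalisation
  list(ll = ll, smoothed = t(smoothed), filtered = t(filtered))
}

# simulate a latent sticky chain with (near-)deterministic emissions
simHMMSeries <- function(P, transition, emit, seed, nH = 2L) {
  funcEquiv:::withSeed(seed, {
    h <- integer(P)
    h[1] <- sample.int(nH, 1)
    for (i in 2:P) h[i] <- sample.int(nH, 1, prob = transition[h[i - 1], ])
    y <- vapply(h, function(s) sample.int(ncol(emit), 1, prob = emit[s, ]), 0L)
    list(h = h, y = y)
  })
}

# donor problem built from the known core species of a synthetic pair
# (the donor model of the equivalence algorithm is an input: structure
# learned on region A over its core variables, class node anchored,
# donor-parametrized transfer scoring)
donorProblemFromCores <- function(pair, nPool = NULL) {
  tr <- pair$truth
  dA <- discretizeBiomass(pair$regionA, method = "equal_width",
                          transform = "log")
  dB <- discretizeBiomass(pair$regionB, method = "equal_width",
                          transform = "log")
  ordA <- tr$coreA
  dSel <- subsetVariables(dA, ordA)
  dAc <- withClassVariable(labelCollapse(dSel, tr$years, 1988))
  stat <- k2Search(dAc, nodeOrder = c("collapse", ordA), maxParents = 3)
  inter <- revealSearch(makeTransitionDataset(dSel, tr$years),
                        maxParents = 3)
  donor <- DAGStructure(
    c(paste0(ordA, ".lag"), "collapse", ordA),
    setNames(c(list(character(0)),
               lapply(ordA, function(v)
                 c(stat@parents[[v]], funcEquiv:::lagNames(inter[[v]])))),
             c("collapse", ordA)))
  pool <- variableNames(dB)[arities(dB) == 3]
  if (!is.null(nPool)) pool <- union(tr$coreB, pool)[seq_len(nPool)]
  flatA <- flattenTransitions(dAc, tr$years)
  flatB <- flattenTransitions(
    withClassVariable(labelCollapse(subsetVariables(dB, pool), tr$years,
                                    1992)), tr$years)
  EquivalenceProblem(donor, data1 = flatA, data2 = flatB, pool = pool,
                     fixed = c(collapse = "collapse"),
                     scoreKind = "transfer")
}
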