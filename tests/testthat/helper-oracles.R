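# Independent oracles and shared fixtures for the suite.

# Naive constitutional oracle: walks atoms and bonds one by one, no shared
# code with the package implementation beyond the graph accessors.
oracle_constitutional <- function(g) {
  a <- atoms(g); b <- bonds(g)
  tab <- elementTable()
  nH <- 0
  for (i in seq_len(nrow(a))) nH <- nH + a$hcount[i]
  nSK <- nrow(a)
  nAT <- nSK + nH
  count_el <- function(sym) {
    k <- 0
    for (i in seq_len(nrow(a))) if (a$element[i] == sym) k <- k + 1
    k
  }
  sums <- c(mass = 0, en_c = 0, pol_c = 0, ip_c = 0, vdw_c = 0)
  for (i in seq_len(nrow(a))) {
    for (s in names(sums)) sums[s] <- sums[s] + tab[a$element[i], s]
  }
  for (s in names(sums)) sums[s] <- sums[s] + nH * tab["H", s]
  nBO <- nrow(b); nAB <- 0; nDB <- 0; nTB <- 0; SCBO <- 0; RBN <- 0
  deg <- rep(0, nrow(a))
  for (r in seq_len(nrow(b))) {
    deg[b$i[r]] <- deg[b$i[r]] + 1
    deg[b$j[r]] <- deg[b$j[r]] + 1
  }
  for (r in seq_len(nrow(b))) {
    if (b$aromatic[r]) {
      nAB <- nAB + 1; SCBO <- SCBO + 1.5
    } else {
      SCBO <- SCBO + b$order[r]
      if (b$order[r] == 2) nDB <- nDB + 1
      if (b$order[r] == 3) nTB <- nTB + 1
      if (b$order[r] == 1 && !b$ring[r] && deg[b$i[r]] >= 2 && deg[b$j[r]] >= 2) {
        RBN <- RBN + 1
      }
    }
  }
  sp3 <- sp2 <- sp <- 0
  for (i in seq_len(nrow(a))) {
    if (a$element[i] != "C") next
    rows <- c()
    for (r in seq_len(nrow(b))) if (b$i[r] == i || b$j[r] == i) rows <- c(rows, r)
    if (a$aromatic[i] || any(b$aromatic[rows])) { sp2 <- sp2 + 1; next }
    ndbl <- sum(b$order[rows] == 2); ntrp <- sum(b$order[rows] == 3)
    if (ntrp >= 1 || ndbl >= 2) sp <- sp + 1
    else if (ndbl == 1) sp2 <- sp2 + 1
    else sp3 <- sp3 + 1
  }
  nX <- count_el("F") + count_el("Cl") + count_el("Br") + count_el("I")
  nBT <- nBO + nH
  c(MW = unname(sums["mass"]), AMW = unname(sums["mass"]) / nAT,
    Sv = unname(sums["vdw_c"]), Se = unname(sums["en_c"]),
    Sp = unname(sums["pol_c"]), Si = unname(sums["ip_c"]),
    Me = unname(sums["en_c"]) / nAT, Mp = unname(sums["pol_c"]) / nAT,
    Mi = unname(sums["ip_c"]) / nAT,
    nAT = nAT, nSK = nSK, nBT = nBT, nBO = nBO, nBM = nDB + nTB + nAB,
    SCBO = SCBO, ARR = if (nBO > 0) nAB / nBO else 0, RBN = RBN,
    RBF = if (nBT > 0) RBN / nBT else 0, nDB = nDB, nTB = nTB, nAB = nAB,
    nH = nH, nC = count_el("C"), nN = count_el("N"), nO = count_el("O"),
    nP = count_el("P"), nS = count_el("S"), nF = count_el("F"),
    nCl = count_el("Cl"), nBr = count_el("Br"), nI = count_el("I"),
    nX = nX, nHet = nSK - count_el("C"),
    `H%` = 100 * nH / nAT, `C%` = 100 * count_el("C") / nAT,
    `N%` = 100 * count_el("N") / nAT, `O%` = 100 * count_el("O") / nAT,
    `X%` = 100 * nX / nAT, nCsp3 = sp3, nCsp2 = sp2, nCsp = sp)
}

# Naive minimum-variance (Ward) oracle: recomputes the merge cost from the
# actual cluster members' centroids at every step, with the same tie-break.
oracle_ward <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  members <- lapply(seq_len(n), identity)
  node <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  ess <- function(mem) {
    pts <- x[mem, , drop = FALSE]
    cen <- colMeans(pts)
    sum(sweep(pts, 2, cen)^2)
  }
  for (step in seq_len(n - 1L)) {
    best <- NULL; best_cost <- Inf
    for (i in seq_along(members)[-length(members)]) {
      for (j in (i + 1):length(members)) {
        cost <- ess(c(members[[i]], members[[j]])) -
          ess(members[[i]]) - ess(members[[j]])
        mem <- sort(c(min(members[[i]]), min(members[[j]])))
        take <- cost < best_cost - 1e-12 ||
          (abs(cost - best_cost) <= 1e-12 &&
           (mem[1] < best$mem[1] ||
            (mem[1] == best$mem[1] && mem[2] < best$mem[2])))
        if (take) { best <- list(i = i, j = j, mem = mem); best_cost <- cost }
      }
    }
    i <- best$i; j <- best$j
    height[step] <- best_cost
    merge[step, ] <- sort(c(node[i], node[j]))
    members[[i]] <- c(members[[i]], members[[j]])
    node[i] <- step
    members[[j]] <- NULL
    node <- node[-j]
  }
  list(merge = merge, height = height)
}

# a small library of hand-specifiable ions used across files
ion_library <- function() {
  c(chloride = "[Cl-]", bromide = "[Br-]", iodide = "[I-]",
    tetramethylammonium = "C[N+](C)(C)C",
    tetraethylammonium = "CC[N+](CC)(CC)CC",
    butyltrimethylammonium = "CCCC[N+](C)(C)C",
    tetrabutylphosphonium = "CCCC[P+](CCCC)(CCCC)CCCC",
    trimethylsulfonium = "C[S+](C)C",
    emim = "C[n+]1ccn(CC)c1",
    bmim = "C[n+]1ccn(CCCC)c1",
    butylpyridinium = "CCCC[n+]1ccccc1",
    butylmethylpyrrolidinium = "CCCC[N+]1(C)CCCC1",
    tetrafluoroborate = "[B-](F)(F)(F)F",
    hexafluorophosphate = "F[P-](F)(F)(F)(F)F",
    mesylate = "CS(=O)(=O)[O-]",
    hydrogensulfate = "OS(=O)(=O)[O-]",
    triflate = "C(F)(F)(F)S(=O)(=O)[O-]",
    tfsi = "C(F)(F)(F)S(=O)(=O)[N-]S(=O)(=O)C(F)(F)F",
    fsi = "FS(=O)(=O)[N-]S(=O)(=O)F",
    glycinate = "NCC(=O)[O-]",
    alaninate = "CC(N)C(=O)[O-]",
    acetate = "CC(=O)[O-]",
    dca = "N#C[N-]C#N")
}

# one fixture reference set + fitted bundle per test run, built lazily
.fixture_cache <- new.env(parent = emptyenv())

fixture_reference <- function() {
  if (is.null(.fixture_cache$ref)) {
    .fixture_cache$ref <- generateReferenceSet(seed = 1)
  }
  .fixture_cache$ref
}

fixture_bundle <- function() {
  if (is.null(.fixture_cache$bundle)) {
    ref <- fixture_reference()
    .fixture_cache$bundle <- buildReferenceModel(ref$ils, ref$properties)
  }
  .fixture_cache$bundle
}

# hand-rolled adjusted Rand index used when mclust is unavailable
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab)); si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab))); sn <- comb2(sum(tab))
  (sij - si * sj / sn) / ((si + sj) / 2 - si * sj / sn)
}
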