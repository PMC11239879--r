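## Independent oracles and small fixtures used across the suite.

## plain-R Dijkstra over an explicit voxel set (26-connectivity, physical
## edge lengths); quadratic but fine for the small masks used in tests
r_dijkstra_oracle <- function(vox, base, spacing) {
  vox <- matrix(as.integer(vox), ncol = 3L)
  n <- nrow(vox)
  key <- paste(vox[, 1], vox[, 2], vox[, 3])
  start <- match(paste(base[1], base[2], base[3]), key)
  stopifnot(!is.na(start))
  dist <- rep(Inf, n)
  dist[start] <- 0
  visited <- rep(FALSE, n)
  repeat {
    u <- which(!visited & is.finite(dist))
    if (length(u) == 0L) break
    u <- u[which.min(dist[u])]
    visited[u] <- TRUE
    dz <- vox[, 1] - vox[u, 1]
    dy <- vox[, 2] - vox[u, 2]
    dx <- vox[, 3] - vox[u, 3]
    adj <- which(abs(dz) <= 1 & abs(dy) <= 1 & abs(dx) <= 1 & !visited)
    if (length(adj)) {
      w <- sqrt((dz[adj] * spacing[1])^2 + (dy[adj] * spacing[2])^2 +
                  (dx[adj] * spacing[3])^2)
      better <- dist[u] + w < dist[adj]
      dist[adj[better]] <- dist[u] + w[better]
    }
  }
  dist
}

## brute-force Benjamini-Hochberg step-up
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

## exact hypergeometric upper-tail P(X >= k) by direct summation
hyper_tail <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

## a random connected 26-connected voxel blob grown from a seed voxel
random_blob <- function(n, seed, dims = c(12L, 12L, 12L)) {
  set.seed(seed)
  cur <- matrix(c(sample(3:(dims[1] - 2), 1), sample(3:(dims[2] - 2), 1),
                  sample(3:(dims[3] - 2), 1)), 1L)
  seen <- cur
  while (nrow(seen) < n) {
    from <- seen[sample(nrow(seen), 1), ]
    step <- from + sample(c(-1L, 0L, 1L), 3L, replace = TRUE)
    step <- pmin(pmax(step, 1L), dims)
    if (!any(seen[, 1] == step[1] & seen[, 2] == step[2] &
               seen[, 3] == step[3]))
      seen <- rbind(seen, step)
  }
  colnames(seen) <- c("z", "y", "x")
  seen
}

## downsized imaging parameters for fast unit tests (same optics and
## amplitudes as the defaults, smaller field)
small_field_params <- function(...) {
  synth_imaging_params(volume_shape = c(24L, 168L, 168L), n_nuclei = 6L,
                       ...)
}

## 4-group x n_reps LFQ design matching the study layout
make_design <- function(n_reps) {
  grid <- expand.grid(replicate = seq_len(n_reps),
                      genotype = c("WT", "KO"),
                      construct = c("cilia-BioID2", "BioID2"),
                      stringsAsFactors = FALSE)
  data.frame(sample = sprintf("%s_%s_r%d",
                              sub("-", "", grid$construct), grid$genotype,
                              grid$replicate),
             construct = grid$construct, genotype = grid$genotype,
             replicate = grid$replicate)
}

## LFQ matrix with per-(protein, group) constant values, given as a list:
## values[[protein]] = c(cilia_WT, cilia_KO, ctl_WT, ctl_KO)
make_lfq <- function(values, n_reps = 2L) {
  design <- make_design(n_reps)
  m <- t(vapply(values, function(v) {
    g <- paste(design$construct, design$genotype)
    out <- numeric(nrow(design))
    out[g == "cilia-BioID2 WT"] <- v[1]
    out[g == "cilia-BioID2 KO"] <- v[2]
    out[g == "BioID2 WT"] <- v[3]
    out[g == "BioID2 KO"] <- v[4]
    out
  }, numeric(nrow(design))))
  rownames(m) <- names(values)
  colnames(m) <- design$sample
  lfq_matrix(m, design)
}

## small ontology fixture:
##   root -> A -> B -> C (BP chain), root2 -> D (CC)
make_test_dag <- function() {
  parents <- list(root = character(), A = "root", B = "A", C = "B",
                  root2 = character(), D = "root2")
  ns <- c(root = "BP", A = "BP", B = "BP", C = "BP",
          root2 = "CC", D = "CC")
  ontology_dag(parents, ns)
}

## random DAG over n terms: each term may take parents among earlier terms
random_dag <- function(n, seed, p_edge = 0.3) {
  set.seed(seed)
  ids <- sprintf("T%02d", seq_len(n))
  parents <- setNames(vector("list", n), ids)
  parents[[1]] <- character()
  for (i in 2:n) {
    cand <- ids[seq_len(i - 1L)]
    parents[[ids[i]]] <- cand[runif(length(cand)) < p_edge]
  }
  ontology_dag(parents, setNames(rep("BP", n), ids))
}

## igraph-based reflexive-transitive ancestor closure (independent route)
igraph_closure <- function(dag, terms) {
  edges <- do.call(rbind, lapply(names(dag$parents), function(t) {
    ps <- dag$parents[[t]]
    if (length(ps)) cbind(t, ps) else NULL
  }))
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    vertices = names(dag$parents))
  sort(unique(unlist(lapply(terms, function(t)
    names(igraph::subcomponent(g, t, mode = "out"))))))
}

## match detected cilia records to ground-truth cilia by per-object Jaccard
match_cilia <- function(res, truth, dims, min_jaccard = 0.5) {
  tr_idx <- which(truth$cells$has_cilium)
  tr_sets <- lapply(tr_idx, function(i)
    sort(ciliomics:::voxel_linear_index(truth$cilium_voxels[[i]], dims)))
  det_sets <- lapply(res$records, function(r)
    sort(ciliomics:::voxel_linear_index(r$cilium_voxels, dims)))
  matched <- rep(NA_integer_, length(tr_sets))
  used <- logical(length(det_sets))
  for (ti in seq_along(tr_sets)) {
    best <- 0; bj <- NA_integer_
    for (dj in seq_along(det_sets)) {
      if (used[dj]) next
      inter <- length(intersect(tr_sets[[ti]], det_sets[[dj]]))
      if (inter == 0L) next
      J <- inter / (length(tr_sets[[ti]]) + length(det_sets[[dj]]) - inter)
      if (J > best) { best <- J; bj <- dj }
    }
    if (!is.na(bj) && best >= min_jaccard) { matched[ti] <- bj; used[bj] <- TRUE }
  }
  list(truth_idx = tr_idx, matched = matched, n_detected = length(det_sets))
}
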