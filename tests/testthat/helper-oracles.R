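# --- microsynteny oracle: exhaustive chain search ---------------------
# Builds the pair list by explicit loops and finds the best chain by
# depth-first enumeration over all successors, then applies the same
# greedy longest-first (ties: lexicographic (ord_a, ord_b), then
# increasing direction) removal.  Shares no code with the package's
# forward dynamic programme.

oracle_pairs <- function(ann_a, ann_b, table) {
  sa <- ann_a$species_id; sb <- ann_b$species_id
  out <- NULL
  for (og in names(table$entries)) {
    for (a in table$entries[[og]][[sa]]) for (b in table$entries[[og]][[sb]]) {
      ka <- which(ann_a$genes$gene_id == a)
      kb <- which(ann_b$genes$gene_id == b)
      out <- rbind(out, data.frame(
        gene_a = a, gene_b = b, og = og,
        ca = ann_a$genes$chrom[ka], oa = ann_a$genes$ordinal[ka],
        cb = ann_b$genes$chrom[kb], ob = ann_b$genes$ordinal[kb],
        stringsAsFactors = FALSE))
    }
  }
  out
}

oracle_cmp <- function(pr, x, dx, y, dy) {
  # TRUE if chain x beats chain y
  if (is.null(y)) return(TRUE)
  if (length(x) != length(y)) return(length(x) > length(y))
  sx <- as.vector(rbind(pr$oa[x], pr$ob[x]))
  sy <- as.vector(rbind(pr$oa[y], pr$ob[y]))
  d <- which(sx != sy)
  if (length(d)) return(sx[d[1]] < sy[d[1]])
  dx > dy
}

oracle_best_chain <- function(pr, avail, mi) {
  best <- NULL; bdir <- NULL
  dfs <- function(chain, dir) {
    p <- chain[length(chain)]
    extended <- FALSE
    for (s in avail) {
      if (pr$ca[s] != pr$ca[p] || pr$cb[s] != pr$cb[p]) next
      da <- pr$oa[s] - pr$oa[p]
      db <- dir * (pr$ob[s] - pr$ob[p])
      if (da < 1 || da - 1 > mi || db < 1 || db - 1 > mi) next
      extended <- TRUE
      dfs(c(chain, s), dir)
    }
    if (!extended && oracle_cmp(pr, chain, dir, best, bdir)) {
      best <<- chain; bdir <<- dir
    }
  }
  for (dir in c(1L, -1L)) for (p in avail) dfs(p, dir)
  if (is.null(best)) NULL else list(chain = best, dir = bdir)
}

oracle_blocks <- function(ann_a, ann_b, table, mi, min_len) {
  pr <- oracle_pairs(ann_a, ann_b, table)
  if (is.null(pr)) return(list())
  avail <- seq_len(nrow(pr))
  blocks <- list()
  repeat {
    if (length(avail) < min_len) break
    b <- oracle_best_chain(pr, avail, mi)
    if (is.null(b) || length(b$chain) < min_len) break
    blocks[[length(blocks) + 1L]] <-
      list(genes_a = pr$gene_a[b$chain], genes_b = pr$gene_b[b$chain],
           dir = b$dir)
    avail <- avail[!(pr$gene_a[avail] %in% pr$gene_a[b$chain]) &
                     !(pr$gene_b[avail] %in% pr$gene_b[b$chain])]
  }
  blocks
}

# --- modularity oracle: exhaustive partition enumeration --------------
# Q computed directly from the weighted adjacency matrix, independently
# of modularity_score().

all_set_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in all_set_partitions(n - 1L)) {
    for (k in seq_along(p)) {
      q <- p; q[[k]] <- c(q[[k]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

oracle_q <- function(adj, membership) {
  W2 <- sum(adj)              # 2W: every edge counted twice
  if (W2 == 0) return(0)
  q <- 0
  for (c in unique(membership)) {
    inc <- membership == c
    q <- q + sum(adj[inc, inc]) / W2 - (sum(adj[inc, ]) / W2)^2
  }
  q
}

oracle_max_modularity <- function(graph) {
  adj <- igraph::as_adjacency_matrix(graph, attr =
    if ("weight" %in% igraph::edge_attr_names(graph)) "weight" else NULL,
    sparse = FALSE)
  n <- nrow(adj)
  best <- -Inf
  for (p in all_set_partitions(n)) {
    mem <- integer(n)
    for (k in seq_along(p)) mem[p[[k]]] <- k
    best <- max(best, oracle_q(adj, mem))
  }
  best
}

# --- Mann-Whitney oracle: direct pair counting over assignments -------
oracle_mwu <- function(a, b) {
  n <- length(a); m <- length(b)
  ustat <- function(x, y)
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u <- ustat(a, b)
  pooled <- c(a, b)
  combs <- utils::combn(n + m, n)
  us <- apply(combs, 2, function(i) ustat(pooled[i], pooled[-i]))
  p <- 2 * min(mean(us <= u + 1e-9), mean(us >= u - 1e-9))
  list(U = u, p.value = min(1, p))
}
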